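#' Posterior summary of a parameter trace
#'
#' Mean, median and the central 95% credible interval (2.5% and 97.5%
#' quantiles, linear interpolation between order statistics).
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @return Named numeric vector: `mean`, `median`, `sd`, `q2.5`, `q97.5`.
#' @export
summarize_parameter <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 2L) stop_invalid("need at least 2 draws")
  q <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(draws), median = median(draws), sd = sd(draws),
    q2.5 = q[1], q97.5 = q[2])
}

#' Influence classification of a coefficient trace
#'
#' A covariate is *influential* for a taxon if the central 95% credible
#' interval of its species-specific coefficient excludes 0, and
#' *well-supported* if the posterior probability of the coefficient being
#' positive (or negative) exceeds 0.90.
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @return Named list: `mean`, `q2.5`, `q97.5`, `p_positive`,
#'   `influential`, `well_supported`.
#' @export
coefficient_influence <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L) stop_invalid("need at least 100 draws")
  q <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  p_pos <- mean(draws > 0)
  list(mean = mean(draws), q2.5 = q[1], q97.5 = q[2], p_positive = p_pos,
       influential = q[1] > 0 || q[2] < 0,
       well_supported = max(p_pos, 1 - p_pos) > 0.90)
}

#' Summary table for all tracked parameters of a fit
#'
#' One row per hyperparameter and species-level parameter with posterior
#' mean, median, SD, central 95% CrI, posterior probability positive, and
#' the influence flags.
#'
#' @param fit An `msom_fit`.
#' @return Data frame with columns `parameter`, `taxon` (`NA` for
#'   hyperparameters), `term`, `mean`, `median`, `sd`, `q2.5`, `q97.5`,
#'   `p_positive`, `influential`, `well_supported`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "msom_fit"))
  dr <- posterior_draws(fit, "all")
  rows <- lapply(colnames(dr), function(pn) {
    x <- dr[, pn]
    s <- summarize_parameter(x)
    ci <- coefficient_influence(x)
    taxon <- if (grepl("\\[", pn)) sub("^.*\\[(.*)\\]$", "\\1", pn)
             else NA_character_
    term <- sub("\\[.*\\]$", "", pn)
    data.frame(parameter = pn, taxon = taxon, term = term,
               mean = s[["mean"]], median = s[["median"]], sd = s[["sd"]],
               q2.5 = s[["q2.5"]], q97.5 = s[["q97.5"]],
               p_positive = ci$p_positive, influential = ci$influential,
               well_supported = ci$well_supported)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

derived_draw_matrices <- function(fit) {
  zs <- z_draws(fit)
  M <- dim(fit$data$y)[1]; J <- fit$data$layout$n_sites
  rich <- do.call(rbind, lapply(zs, function(a) apply(a, c(1, 3), sum)))
  occ_sites <- do.call(rbind, lapply(zs, function(a) apply(a, c(1, 2), sum)))
  n_present <- rowSums(occ_sites >= 1L)
  w <- w_draws(fit)
  list(site_richness = rich,            # draws x J
       occupied_sites = occ_sites,      # draws x M
       n_present = n_present,           # draws
       supercommunity = rowSums(w))     # draws
}

med_cri <- function(x) {
  q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(median = q[2], q2.5 = q[1], q97.5 = q[3])
}

#' Per-site species richness (alpha diversity)
#'
#' `N_j = sum_i z_ij` at each retained draw; summarized by the posterior
#' median and central 95% CrI (medians because the quantity is
#' integer-valued).
#'
#' @param fit An `msom_fit`.
#' @return Data frame: `site`, `n_detected` (naive count), `median`,
#'   `q2.5`, `q97.5`.
#' @export
site_richness <- function(fit) {
  d <- derived_draw_matrices(fit)
  J <- fit$data$layout$n_sites
  naive <- vapply(seq_len(J), function(j)
    sum(apply(fit$data$y[, j, , drop = FALSE], 1,
              function(v) any(v == 1L, na.rm = TRUE))), numeric(1))
  s <- t(apply(d$site_richness, 2, med_cri))
  data.frame(site = seq_len(J), n_detected = naive,
             median = s[, 1], q2.5 = s[, 2], q97.5 = s[, 3])
}

#' Supercommunity size (gamma diversity, regional pool)
#'
#' The number of taxa in the regional supercommunity, `sum_i w_i`, per
#' draw; bounded above by the augmented total and below by the number of
#' observed taxa.
#'
#' @param fit An `msom_fit`.
#' @return List with `median`, `q2.5`, `q97.5` and the full `draws`
#'   vector.
#' @export
supercommunity_size <- function(fit) {
  d <- derived_draw_matrices(fit)
  out <- as.list(med_cri(d$supercommunity))
  out$draws <- d$supercommunity
  out
}

#' Occupied-site counts per taxon, and taxa present anywhere
#'
#' Per draw and taxon, the number of sites with `z = 1`; and per draw the
#' number of taxa occupying at least one site (the richness measure
#' recommended when inference targets the surveyed sites rather than the
#' hypothetical regional pool). For augmented taxa only one representative
#' row is interpretable since undetected taxa are exchangeable.
#'
#' @param fit An `msom_fit`.
#' @return List with `per_taxon` (data frame: `taxon`, `observed`,
#'   `n_sites_detected`, `median`, `q2.5`, `q97.5`) and `n_present`
#'   (list: `median`, `q2.5`, `q97.5`, `draws`).
#' @export
species_occurrence <- function(fit) {
  d <- derived_draw_matrices(fit)
  M <- dim(fit$data$y)[1]
  naive <- vapply(seq_len(M), function(i)
    sum(apply(fit$data$y[i, , , drop = FALSE], 2,
              function(v) any(v == 1L, na.rm = TRUE))), numeric(1))
  s <- t(apply(d$occupied_sites, 2, med_cri))
  per_taxon <- data.frame(
    taxon = fit$data$taxa,
    observed = seq_len(M) <= fit$data$n_observed,
    n_sites_detected = naive,
    median = s[, 1], q2.5 = s[, 2], q97.5 = s[, 3])
  np <- as.list(med_cri(d$n_present))
  np$draws <- d$n_present
  list(per_taxon = per_taxon, n_present = np)
}

#' All derived diversity summaries of a fit
#'
#' @param fit An `msom_fit`.
#' @return List: `site_richness`, `species_occurrence`, `n_present`,
#'   `supercommunity`.
#' @export
derived_richness <- function(fit) {
  so <- species_occurrence(fit)
  list(site_richness = site_richness(fit),
       species_occurrence = so$per_taxon,
       n_present = so$n_present,
       supercommunity = supercommunity_size(fit))
}

#' Write the summary tables of a fit as CSV files
#'
#' @param fit An `msom_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit_summaries <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(params = file.path(dir, "parameter_summaries.csv"),
             sites = file.path(dir, "site_richness.csv"),
             taxa = file.path(dir, "species_occurrence.csv"))
  write.csv(summarize_fit(fit), paths["params"], row.names = FALSE)
  write.csv(site_richness(fit), paths["sites"], row.names = FALSE)
  write.csv(species_occurrence(fit)$per_taxon, paths["taxa"],
            row.names = FALSE)
  invisible(paths)
}
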