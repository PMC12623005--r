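#' Count taxa for which a term is influential
#'
#' A term is influential for a taxon when the central 95% CrI of its
#' species-specific coefficient excludes 0. By default only observed taxa
#' are counted: augmented all-zero taxa shrink to the community mean and
#' carry no information about individual covariates.
#'
#' @param fit An `msom_fit` whose spec contains the term.
#' @param term Term label, e.g. `"start_time"`, `"plant:start_time"`,
#'   `"I(temperature^2)"`, `"plant"` (the plant shift itself), or an
#'   occupancy term prefixed as in the registry (`"psi_urban_dist"`).
#' @param observed_only Count observed taxa only (default TRUE).
#' @return Integer count of influential taxa.
#' @export
count_influential <- function(fit, term, observed_only = TRUE) {
  stopifnot(inherits(fit, "msom_fit"))
  reg <- fit$registry
  term <- normalize_term(term)
  col <- if (term %in% reg$cols) term
         else if (term == "plant") "p_plant"
         else if (paste0("p_", term) %in% reg$cols) paste0("p_", term)
         else if (paste0("psi_", term) %in% reg$cols) paste0("psi_", term)
         else stop_invalid("term '", term, "' is not in the fitted model")
  taxa <- fit$data$taxa
  if (observed_only) taxa <- taxa[seq_len(fit$data$n_observed)]
  dr <- posterior_draws(fit, "species")
  sum(vapply(taxa, function(tx) {
    ci <- coefficient_influence(dr[, paste0(col, "[", tx, "]")])
    ci$influential
  }, logical(1)))
}

term_sub_model <- function(term) {
  vars <- term_vars(term)
  if (all(vars %in% site_covariate_names()) && !grepl(":", term)) "either"
  else "detection"
}

candidate_eligible <- function(term, base_terms, screen) {
  vars <- term_vars(term)
  # interactions/quadratics only once their mains are in the base
  if (grepl(":", term, fixed = TRUE) || grepl("^I\\(", term)) {
    mains <- setdiff(vars, "plant")
    if (!all(mains %in% base_terms)) return(FALSE)
  }
  if (!is.null(screen)) {
    excl <- screen[screen$excluded, , drop = FALSE]
    base_vars <- unique(unlist(lapply(base_terms, term_vars)))
    for (r in seq_len(nrow(excl))) {
      pair <- c(excl$var1[r], excl$var2[r])
      if (any(pair %in% vars) && any(setdiff(pair, vars) %in% base_vars))
        return(FALSE)
      if (all(pair %in% vars)) return(FALSE)
    }
  }
  TRUE
}

# R-hat over the parameters a retention decision depends on: the
# candidate term's species coefficients and its community mean/SD
candidate_rhat <- function(fit, col) {
  rh <- rhat_all(fit, include_species = TRUE)
  keep <- grepl(paste0("^", gsub("([][^$.|?*+()\\\\])", "\\\\\\1", col)),
                names(rh)) |
    names(rh) %in% paste0(c("mu_", "sd_"), col)
  max(rh[keep])
}

fit_candidate <- function(base, candidate, sub, data, site_covs, survey_covs,
                          priors, config) {
  spec_try <- if (sub == "occupancy")
    model_spec(occupancy = paste(c(base$occupancy, candidate), collapse = " + "),
               detection = paste(c("plant", base$detection), collapse = " + "))
  else
    model_spec(occupancy = if (length(base$occupancy))
                 paste(base$occupancy, collapse = " + ") else "1",
               detection = paste(c("plant", base$detection, candidate),
                                 collapse = " + "))
  col <- paste0(if (sub == "occupancy") "psi_" else "p_",
                normalize_term(candidate))
  fit <- run_mcmc(data, spec_try, config, priors = priors,
                  site_covs = site_covs, survey_covs = survey_covs)
  rh <- candidate_rhat(fit, col)
  if (rh >= 1.05) {
    # flagged non-converged: re-run once with a longer schedule
    cfg2 <- config
    cfg2$n_iter <- config$n_iter * 2L
    cfg2$burn_in <- config$burn_in * 2L
    fit <- run_mcmc(data, spec_try, cfg2, priors = priors,
                    site_covs = site_covs, survey_covs = survey_covs)
    rh <- candidate_rhat(fit, col)
  }
  list(spec = spec_try, fit = fit, rhat = rh)
}

#' One round of heuristic forward selection
#'
#' Fits the base model extended by each eligible candidate term in turn,
#' counts taxa with influential coefficients for the candidate, drops
#' candidates influential for fewer than `min_taxa` taxa, and advances the
#' candidate with the highest count. Ties break deterministically: main
#' effects are preferred over interactions and quadratics, then the
#' configured candidate order. A candidate fit whose decision-relevant
#' parameters (the candidate's coefficients and their community mean/SD)
#' fail the R-hat gate is flagged and re-run once with a doubled
#' schedule.
#'
#' @param base A [model_spec] (the current base model).
#' @param candidates Character vector of candidate term labels.
#' @param sub `"occupancy"` or `"detection"`.
#' @param data Augmented `detection_array`.
#' @param site_covs,survey_covs Covariate objects.
#' @param priors A [prior_spec].
#' @param config An [mcmc_config] (candidate fits may use a reduced
#'   schedule).
#' @param screen Optional [correlation_screen()] output.
#' @param min_taxa Minimum influential-taxon count to retain a candidate
#'   (default 2, operationalizing "influential for multiple species").
#' @return List: `spec` (chosen base for the next round), `round` (data
#'   frame: candidate, count, decision), `stopped` (no candidate
#'   retained), `rhat` (max R-hat per candidate fit).
#' @export
forward_step <- function(base, candidates, sub, data, site_covs = NULL,
                         survey_covs = NULL, priors = prior_spec(),
                         config = mcmc_config(), screen = NULL,
                         min_taxa = 2L) {
  elig <- vapply(candidates, candidate_eligible,
                 base_terms = c(base$occupancy, base$detection),
                 screen = screen, FUN.VALUE = logical(1))
  cand <- candidates[elig]
  if (!length(cand))
    return(list(spec = base, stopped = TRUE,
                round = data.frame(candidate = character(0),
                                   count = integer(0),
                                   decision = character(0))))
  counts <- integer(length(cand)); rhats <- numeric(length(cand))
  for (ci in seq_along(cand)) {
    res <- fit_candidate(base, cand[ci], sub, data, site_covs, survey_covs,
                         priors, config)
    counts[ci] <- count_influential(res$fit, cand[ci])
    rhats[ci] <- res$rhat
  }
  keep <- counts >= min_taxa
  decision <- ifelse(keep, "retainable", "drop")
  if (!any(keep)) {
    rnd <- data.frame(candidate = cand, count = counts, decision = decision,
                      max_rhat = rhats)
    return(list(spec = base, stopped = TRUE, round = rnd))
  }
  is_main <- !grepl("[:^]", cand)
  ord <- order(-counts, !is_main, seq_along(cand))
  pick <- ord[which(keep[ord])[1]]
  decision[pick] <- "advance"
  chosen <- fit_candidate(base, cand[pick], sub, data, site_covs,
                          survey_covs, priors, config)$spec
  list(spec = chosen, stopped = FALSE,
       round = data.frame(candidate = cand, count = counts,
                          decision = decision, max_rhat = rhats))
}

#' Heuristic forward stepwise covariate selection
#'
#' Mirrors a credible-interval driven selection procedure: site covariates
#' are tried in the occupancy sub-model first; then detection candidates
#' (the plant term is always included). Each round tests every remaining
#' eligible candidate on top of the current base, retains only candidates
#' influential for at least `min_taxa` taxa, advances the best one, and
#' re-evaluates previously retained detection main effects, dropping any
#' that are no longer influential for at least `min_taxa` taxa in the new
#' base (unless a retained interaction still needs them). Candidate fits
#' may use a reduced MCMC schedule since only CrI-versus-0 decisions are
#' needed; refit the winning model at a full schedule afterwards.
#'
#' @param data Augmented `detection_array`.
#' @param site_covs,survey_covs Covariate objects.
#' @param occupancy_candidates,detection_candidates Character vectors of
#'   term labels.
#' @param priors A [prior_spec].
#' @param config An [mcmc_config] for the candidate fits.
#' @param screen Optional [correlation_screen()] output; excluded pairs are
#'   never co-fit.
#' @param min_taxa Retention threshold (default 2).
#' @param max_rounds Safety cap on selection rounds.
#' @return List: `spec` (final [model_spec]), `trace` (data frame: round,
#'   sub-model, base formula, candidate, count, decision).
#' @export
select_model <- function(data, site_covs = NULL, survey_covs = NULL,
                         occupancy_candidates = character(0),
                         detection_candidates = character(0),
                         priors = prior_spec(), config = mcmc_config(),
                         screen = NULL, min_taxa = 2L, max_rounds = 10L) {
  base <- model_spec()  # psi ~ 1, p ~ plant
  trace <- list()
  round_no <- 0L
  record <- function(sub, rnd) {
    if (!nrow(rnd$round)) return()
    trace[[length(trace) + 1L]] <<- data.frame(
      round = round_no, sub = sub, base = format(base), rnd$round)
  }
  # occupancy phase
  pool <- occupancy_candidates
  while (length(pool) && round_no < max_rounds) {
    round_no <- round_no + 1L
    st <- forward_step(base, pool, "occupancy", data, site_covs, survey_covs,
                       priors, config, screen, min_taxa)
    record("occupancy", st)
    if (st$stopped) break
    added <- setdiff(st$spec$occupancy, base$occupancy)
    base <- st$spec
    pool <- setdiff(pool, added)
  }
  # detection phase
  pool <- detection_candidates
  while (length(pool) && round_no < max_rounds) {
    round_no <- round_no + 1L
    st <- forward_step(base, pool, "detection", data, site_covs, survey_covs,
                       priors, config, screen, min_taxa)
    record("detection", st)
    if (st$stopped) break
    added <- setdiff(st$spec$detection, base$detection)
    base <- st$spec
    pool <- setdiff(pool, added)
    # re-evaluate previously retained detection mains in the new base
    refit <- run_mcmc(data, base, config, priors = priors,
                      site_covs = site_covs, survey_covs = survey_covs)
    needed <- unique(unlist(lapply(
      base$detection[grepl("[:^]", base$detection)], term_vars)))
    for (tm in setdiff(base$detection[!grepl("[:^]", base$detection)],
                       c(added, needed))) {
      cnt <- count_influential(refit, tm)
      if (cnt < min_taxa) {
        base <- model_spec(
          occupancy = if (length(base$occupancy))
            paste(base$occupancy, collapse = " + ") else "1",
          detection = paste(c("plant", setdiff(base$detection, tm)),
                            collapse = " + "))
        trace[[length(trace) + 1L]] <- data.frame(
          round = round_no, sub = "detection", base = format(base),
          candidate = tm, count = cnt, decision = "drop_retained",
          max_rhat = NA_real_)
      }
    }
  }
  list(spec = base,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame())
}
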