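#' Conditional Bernoulli deviance of a detection array
#'
#' `D = -2 * sum log Bernoulli(y | z * p)` over surveyed cells,
#' conditional on the current occupancy state: cells at unoccupied sites
#' (`z = 0`) contribute 0 when `y = 0` and are invalid when `y = 1`.
#'
#' @param y M x J x K binary array with `NA` at unsurveyed cells.
#' @param z M x J binary occupancy matrix.
#' @param p M x J x K detection-probability array (`NA` allowed at
#'   unsurveyed cells).
#' @return The deviance (numeric scalar).
#' @seealso [deviance_contributions()] for the per-site and per-taxon
#'   decomposition.
#' @export
conditional_deviance <- function(y, z, p) {
  sum(deviance_contributions(y, z, p)$by_site)
}

#' Per-site and per-taxon deviance contributions
#'
#' @inheritParams conditional_deviance
#' @return List with `by_site` (length J) and `by_taxon` (length M);
#'   each sums to the total deviance.
#' @export
deviance_contributions <- function(y, z, p) {
  stopifnot(length(dim(y)) == 3L, is.matrix(z))
  M <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  stopifnot(all(dim(z) == c(M, J)), all(dim(p) == dim(y)))
  zexp <- array(rep(z, times = K), dim = c(M, J, K))
  obs <- !is.na(y)
  if (any(y[obs] == 1L & zexp[obs] == 0))
    stop_invalid("invalid state: detection recorded where z = 0")
  ll <- array(0, dim = dim(y))
  occ <- obs & zexp == 1
  ll[occ] <- dbinom(y[occ], 1, p[occ], log = TRUE)
  d <- -2 * ll
  list(by_site = apply(d, 2, sum), by_taxon = apply(d, 1, sum))
}

#' Draw a replicate dataset from one posterior draw
#'
#' `y_rep ~ Bernoulli(z * p)` cell-wise on surveyed cells; unsurveyed
#' cells stay missing.
#'
#' @inheritParams conditional_deviance
#' @param mask J x K logical matrix of surveyed cells.
#' @return M x J x K binary array with `NA` at unsurveyed cells.
#' @export
replicate_dataset <- function(z, p, mask) {
  stopifnot(is.matrix(z), length(dim(p)) == 3L)
  M <- dim(p)[1]; J <- dim(p)[2]; K <- dim(p)[3]
  zexp <- array(rep(z, times = K), dim = c(M, J, K))
  maskexp <- aperm(array(rep(mask, times = M), dim = c(J, K, M)), c(3, 1, 2))
  pr <- zexp * p
  out <- array(NA_integer_, dim = c(M, J, K))
  idx <- which(maskexp)
  out[idx] <- rbinom(length(idx), 1L, pr[idx])
  out
}

#' Posterior predictive check: deviance Bayesian p-value
#'
#' At each (sub-sampled) retained draw, computes the conditional deviance
#' of the observed data and of a fresh replicate simulated at the same
#' draw, then reports the fraction of draws where the replicate deviance
#' is at least the observed deviance (ties count). Values above 0.9 or
#' below 0.1 indicate unacceptable fit.
#'
#' @param fit An `msom_fit` (latent-state traces are stored by
#'   [run_mcmc()]).
#' @param n_draws Number of evenly spaced retained draws to evaluate
#'   (`NULL` = all).
#' @param seed Seed for the replicate simulations.
#' @return Object of class `gof_result`: list with `p_value`, `D_obs`,
#'   `D_rep` (per-draw vectors), `by_site` and `by_taxon` mean observed
#'   contributions, and `acceptable`.
#' @export
bayesian_p_value <- function(fit, n_draws = NULL, seed = 1L) {
  stopifnot(inherits(fit, "msom_fit"))
  set.seed(as.integer(seed))
  mi <- fit$inputs
  reg <- fit$registry
  M <- dim(fit$data$y)[1]; J <- fit$data$layout$n_sites
  Dall <- length(reg$cols)
  det_cols <- (reg$n_occ + 1L):Dall
  theta <- posterior_draws(fit, "species")
  zs <- z_draws(fit)
  zpool <- do.call(rbind, lapply(zs, function(a)
    matrix(a, nrow = dim(a)[1])))  # draws x (M*J), i fastest
  n_total <- nrow(theta)
  keep <- if (is.null(n_draws) || n_draws >= n_total) seq_len(n_total)
          else unique(round(seq(1, n_total, length.out = n_draws)))
  ncell <- ncol(mi$ycell)
  cell_site1 <- mi$cell_site + 1L
  Xdet_t <- t(mi$Xdet)
  yobs <- mi$ycell
  D_obs <- D_rep <- numeric(length(keep))
  by_site_acc <- numeric(J); by_taxon_acc <- numeric(M)
  for (t_i in seq_along(keep)) {
    t <- keep[t_i]
    th <- matrix(theta[t, ], M, Dall)
    pm <- inv_logit(th[, det_cols, drop = FALSE] %*% Xdet_t)  # M x ncell
    zmat <- matrix(zpool[t, ], M, J)
    zc <- zmat[, cell_site1, drop = FALSE]
    # observed deviance (z = 1 cells only contribute)
    llo <- ifelse(zc == 1,
                  ifelse(yobs == 1, log(pm), log1p(-pm)), 0)
    dev_cells <- -2 * llo
    D_obs[t_i] <- sum(dev_cells)
    by_taxon_acc <- by_taxon_acc + rowSums(dev_cells)
    by_site_acc <- by_site_acc +
      as.numeric(rowsum(colSums(dev_cells), cell_site1))
    # replicate at the same draw
    yr <- matrix(rbinom(M * ncell, 1L, as.numeric(zc * pm)), M, ncell)
    llr <- ifelse(zc == 1, ifelse(yr == 1, log(pm), log1p(-pm)), 0)
    D_rep[t_i] <- -2 * sum(llr)
  }
  structure(
    list(p_value = mean(D_rep >= D_obs),
         D_obs = D_obs, D_rep = D_rep,
         by_site = by_site_acc / length(keep),
         by_taxon = setNames(by_taxon_acc / length(keep), fit$data$taxa),
         n_draws = length(keep),
         acceptable = {
           p <- mean(D_rep >= D_obs); p >= 0.1 && p <= 0.9
         }),
    class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Deviance posterior predictive check (", x$n_draws, " draws)\n",
      "  Bayesian p-value: ", round(x$p_value, 3),
      if (x$acceptable) "  (acceptable fit)" else "  (UNACCEPTABLE fit)",
      "\n", sep = "")
  invisible(x)
}

#' Write goodness-of-fit tables as CSV
#'
#' @param gof A `gof_result`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_gof <- function(gof, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(draws = file.path(dir, "gof_deviance_draws.csv"),
             site = file.path(dir, "gof_by_site.csv"),
             taxon = file.path(dir, "gof_by_taxon.csv"))
  write.csv(data.frame(D_obs = gof$D_obs, D_rep = gof$D_rep),
            paths["draws"], row.names = FALSE)
  write.csv(data.frame(site = seq_along(gof$by_site),
                       mean_deviance = gof$by_site),
            paths["site"], row.names = FALSE)
  write.csv(data.frame(taxon = names(gof$by_taxon),
                       mean_deviance = gof$by_taxon),
            paths["taxon"], row.names = FALSE)
  invisible(paths)
}
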