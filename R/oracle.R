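# Exact posterior computation on tiny instances, by brute-force
# enumeration of the latent (w, z) configurations and quadrature over
# gridded continuous parameters. Used as an independent oracle for the
# MCMC sampler; deliberately shares no code with it.

# per-taxon detection summaries: detections and trials per site
taxon_site_counts <- function(data, i) {
  lay <- data$layout
  cells <- layout_cells(lay)
  yv <- taxon_slice(data$y, i)[cells]
  list(det = as.numeric(tapply(yv, cells[, 1], sum)),
       n = as.numeric(tapply(yv, cells[, 1], length)))
}

# enumerate (w, z) for one taxon at fixed psi (length J) and p (scalar or
# length J); returns total prob, P(w=1), P(z_j=1)
enumerate_taxon <- function(det, n, psi, p, omega) {
  J <- length(det)
  psi <- rep_len(psi, J); p <- rep_len(p, J)
  site_lik_occ <- p^det * (1 - p)^(n - det)     # P(y_j | z_j = 1)
  site_lik_emp <- as.numeric(det == 0)          # P(y_j | z_j = 0)
  total <- 0; pw <- 0; pz <- numeric(J)
  # w = 0: z forced 0
  pr0 <- (1 - omega) * prod(site_lik_emp)
  total <- total + pr0
  # w = 1: all 2^J z configurations
  for (cfg in 0:(2^J - 1)) {
    zc <- as.integer(intToBits(cfg))[seq_len(J)]
    pr <- omega * prod(ifelse(zc == 1, psi * site_lik_occ,
                              (1 - psi) * site_lik_emp))
    total <- total + pr
    pw <- pw + pr
    pz <- pz + pr * zc
  }
  list(total = total, pw = pw, pz = pz)
}

#' Exact posterior for tiny occupancy instances
#'
#' Brute-force oracle for validating the sampler. Occupancy and detection
#' probabilities are held fixed (scalar, or per taxon, or per taxon x
#' site); the supercommunity inclusion probability omega is either fixed
#' or integrated over its Beta prior by grid quadrature. All latent
#' `(w, z)` configurations are enumerated per taxon.
#'
#' @param data A `detection_array` with at most 3 taxa, 4 sites, 3 slots
#'   per plant.
#' @param psi Occupancy probability: scalar, length-M vector, or M x J
#'   matrix.
#' @param p Detection probability: scalar, length-M vector, or M x J matrix
#'   (per-site value applied to all that site's slots).
#' @param omega Fixed inclusion probability, or `NULL` to integrate over
#'   `Beta(omega_prior)` on a grid of `n_grid` midpoints.
#' @param omega_prior Beta shape parameters used when `omega` is `NULL`.
#' @param n_grid Number of quadrature nodes for omega.
#' @return List with `z_prob` (M x J posterior occupancy probabilities),
#'   `w_prob` (length M), `omega_mean` (posterior mean of omega; equals the
#'   input when fixed), and `log_marginal`.
#' @export
exact_posterior_tiny <- function(data, psi, p, omega = NULL,
                                 omega_prior = c(0.001, 1), n_grid = 512L) {
  stopifnot(inherits(data, "detection_array"))
  M <- dim(data$y)[1]; J <- data$layout$n_sites
  K <- data$layout$n_slots
  if (M > 3L || J > 4L || K > 6L)
    stop_invalid("instance too large for exact enumeration (M <= 3, J <= 4)")
  as_mj <- function(x) {
    if (is.matrix(x)) { stopifnot(dim(x) == c(M, J)); x }
    else matrix(rep_len(x, M), M, J)
  }
  psi <- as_mj(psi); p <- as_mj(p)
  counts <- lapply(seq_len(M), function(i) taxon_site_counts(data, i))

  eval_at_omega <- function(om) {
    per <- lapply(seq_len(M), function(i)
      enumerate_taxon(counts[[i]]$det, counts[[i]]$n,
                      psi[i, ], p[i, ], om))
    lik <- prod(vapply(per, `[[`, numeric(1), "total"))
    list(lik = lik, per = per)
  }

  if (!is.null(omega)) {
    ev <- eval_at_omega(omega)
    w_prob <- vapply(seq_len(M), function(i)
      ev$per[[i]]$pw / ev$per[[i]]$total, numeric(1))
    z_prob <- t(vapply(seq_len(M), function(i)
      ev$per[[i]]$pz / ev$per[[i]]$total, numeric(J)))
    return(list(z_prob = matrix(z_prob, M, J), w_prob = w_prob,
                omega_mean = omega, log_marginal = log(ev$lik)))
  }

  # midpoint quadrature over the Beta prior
  grid <- (seq_len(n_grid) - 0.5) / n_grid
  wts <- stats::dbeta(grid, omega_prior[1], omega_prior[2])
  wts <- wts / sum(wts)
  evs <- lapply(grid, eval_at_omega)
  liks <- vapply(evs, `[[`, numeric(1), "lik")
  post <- wts * liks
  Zc <- sum(post)
  post <- post / Zc
  omega_mean <- sum(post * grid)
  w_prob <- vapply(seq_len(M), function(i)
    sum(post * vapply(evs, function(e)
      e$per[[i]]$pw / e$per[[i]]$total, numeric(1))), numeric(1))
  z_prob <- matrix(0, M, J)
  for (i in seq_len(M)) {
    zmat <- vapply(evs, function(e)
      e$per[[i]]$pz / e$per[[i]]$total, numeric(J))
    z_prob[i, ] <- as.numeric(matrix(zmat, nrow = J) %*% post)
  }
  list(z_prob = z_prob, w_prob = w_prob, omega_mean = omega_mean,
       log_marginal = log(Zc))
}

#' Exact single-taxon posterior under the hierarchical priors
#'
#' For a one-taxon instance, the community level can be integrated out:
#' the marginal prior of the species occupancy (or detection) intercept is
#' the logit-uniform hypermean convolved with the Normal species effect
#' whose SD is uniform. This function computes that induced marginal by
#' 2-D quadrature and then the joint posterior of (occupancy intercept,
#' detection intercept, omega) on a 3-D grid — an independent check of the
#' full Metropolis-within-Gibbs machinery on an intercept-only,
#' single-plant model.
#'
#' @param data A `detection_array` with exactly 1 taxon and <= 4 sites.
#' @param priors A [prior_spec].
#' @param n_grid Nodes per dimension for the (logit psi, logit p) grid.
#' @param grid_range Half-width of the logit-scale grid.
#' @return List with posterior means `psi_mean`, `p_mean`, `omega_mean`,
#'   `w_prob`, `z_prob` (length J).
#' @export
exact_posterior_hier1 <- function(data, priors = prior_spec(),
                                  n_grid = 161L, grid_range = 16) {
  stopifnot(inherits(data, "detection_array"))
  M <- dim(data$y)[1]; J <- data$layout$n_sites
  if (M != 1L || J > 4L)
    stop_invalid("hierarchical oracle requires exactly 1 taxon, <= 4 sites")

  induced_marginal <- function(lgrid, sd_upper) {
    # density of l = mu + e, mu ~ logistic, e ~ N(0, sd), sd ~ U(0, upper)
    mu_g <- seq(-14, 14, length.out = 281L)
    mu_w <- stats::dlogis(mu_g); mu_w <- mu_w / sum(mu_w)
    sd_g <- (seq_len(61L) - 0.5) / 61L * sd_upper
    dens <- vapply(lgrid, function(l) {
      # average over sd and mu
      m <- outer(mu_g, sd_g, function(m0, s0) dnorm(l, m0, s0))
      sum((mu_w %*% m) / length(sd_g))
    }, numeric(1))
    dens / sum(dens)
  }

  lg <- seq(-grid_range, grid_range, length.out = n_grid)
  w_psi <- induced_marginal(lg, priors$sd_intercept_upper)
  w_p <- induced_marginal(lg, priors$sd_intercept_upper)
  psi_g <- inv_logit(lg); p_g <- inv_logit(lg)

  cnt <- taxon_site_counts(data, 1L)
  det <- cnt$det; n <- cnt$n
  # f(psi, p) = P(y | w = 1, psi, p); emp = indicator all-zero
  f <- matrix(1, n_grid, n_grid)
  site_occ <- lapply(seq_len(J), function(j)
    p_g^det[j] * (1 - p_g)^(n[j] - det[j]))
  for (j in seq_len(J))
    f <- f * (outer(psi_g, site_occ[[j]]) +
              outer(1 - psi_g, rep(as.numeric(det[j] == 0), n_grid)))
  I0 <- as.numeric(all(det == 0))

  og <- (seq_len(512L) - 0.5) / 512L
  ow <- stats::dbeta(og, priors$omega_shape1, priors$omega_shape2)
  ow <- ow / sum(ow)

  # posterior mass m(psi, p, omega) = w_psi w_p ow [(1 - om) I0 + om f]
  S_om1 <- sum(ow * og); S_om0 <- sum(ow * (1 - og))
  Wpp <- outer(w_psi, w_p)
  Z <- I0 * S_om0 + S_om1 * sum(Wpp * f)
  # marginals
  psi_mass <- (I0 * S_om0 * w_psi +
               S_om1 * rowSums(Wpp * f) ) / Z
  p_mass <- (I0 * S_om0 * w_p + S_om1 * colSums(Wpp * f)) / Z
  om_mass <- (ow * (1 - og) * I0 + ow * og * sum(Wpp * f)) / Z
  # P(w = 1 | y)
  w_prob <- S_om1 * sum(Wpp * f) / Z
  # P(z_j = 1 | y): omega * prod_{j' != j} terms * psi * site_occ_j
  z_prob <- numeric(J)
  for (j in seq_len(J)) {
    fj <- matrix(1, n_grid, n_grid)
    for (jj in setdiff(seq_len(J), j))
      fj <- fj * (outer(psi_g, site_occ[[jj]]) +
                  outer(1 - psi_g, rep(as.numeric(det[jj] == 0), n_grid)))
    numer <- fj * outer(psi_g, site_occ[[j]])
    z_prob[j] <- S_om1 * sum(Wpp * numer) / Z
  }
  list(psi_mean = sum(psi_mass * psi_g), p_mean = sum(p_mass * p_g),
       omega_mean = sum(om_mass * og), w_prob = w_prob, z_prob = z_prob)
}
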