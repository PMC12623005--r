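as_species_params <- function(params, spec) {
  reg <- param_registry(spec)
  if (is.null(names(params)))
    stop_invalid("species parameters must be a named numeric vector")
  miss <- setdiff(reg$cols, names(params))
  if (length(miss))
    stop_invalid("missing species parameter(s): ", paste(miss, collapse = ", "))
  v <- as.numeric(params[reg$cols])
  if (any(!is.finite(v))) stop_invalid("non-finite species parameter")
  names(v) <- reg$cols
  v
}

#' Per-site occupancy probability for one taxon
#'
#' `psi_j = inv_logit(intercept + sum of occupancy terms)`, covariates on
#' the standardized scale. With an intercept-only spec the same probability
#' applies at every site.
#'
#' @param params Named numeric vector of species parameters; must contain
#'   `psi_int` and `psi_<term>` for every occupancy term in `spec` (it may
#'   also carry detection parameters, which are ignored here).
#' @param site_covs A [site_covariates] object, or `NULL` for
#'   intercept-only specs.
#' @param spec A [model_spec].
#' @param layout A [study_layout] giving the number of sites.
#' @return Numeric vector of occupancy probabilities, one per site.
#' @examples
#' sp <- model_spec()
#' lay <- study_layout(c("both", "pm_only"))
#' occupancy_probability(c(psi_int = 0, p_int = 0, p_plant = 0), NULL, sp, lay)
#' @export
occupancy_probability <- function(params, site_covs, spec, layout) {
  v <- as_species_params(params, spec)
  X <- occupancy_design(spec, layout, site_covs)
  as.numeric(inv_logit(X %*% v[colnames(X)]))
}

#' Per-cell detection probability for one taxon
#'
#' `logit p_jk = intercept + plant_coef * plant_jk + sum of detection
#' terms` on surveyed (site, slot) cells; structurally missing cells yield
#' `NA`.
#'
#' @inheritParams occupancy_probability
#' @param survey_covs A [survey_covariates] object (or `NULL` if the model
#'   uses no survey covariates beyond plant).
#' @return J x K matrix of detection probabilities with `NA` at missing
#'   slots.
#' @export
detection_probability <- function(params, survey_covs, spec, layout,
                                  site_covs = NULL) {
  v <- as_species_params(params, spec)
  dd <- detection_design(spec, layout, site_covs, survey_covs)
  lin <- as.numeric(dd$X %*% v[colnames(dd$X)])
  out <- matrix(NA_real_, layout$n_sites, layout$n_slots)
  out[dd$cells] <- inv_logit(lin)
  out
}

#' Joint log density of the hierarchical occupancy model
#'
#' Sums, over whatever levels are supplied: the Bernoulli terms for
#' supercommunity membership `w`, site occupancy `z` given `w`, and
#' detections `y` given `z` (surveyed cells only); the species-level
#' Normal densities given community hyperparameters; and the hyperpriors.
#' Returns `-Inf` for impossible states (a detection where `z = 0`, or
#' `z = 1` where `w = 0`).
#'
#' @param data A `detection_array`.
#' @param w Binary vector (length M): supercommunity membership.
#' @param z Binary M x J matrix: site occupancy.
#' @param species M x D matrix of species parameters (columns as in the
#'   parameter registry for `spec`).
#' @param spec A [model_spec].
#' @param omega Supercommunity inclusion probability.
#' @param site_covs,survey_covs Covariate objects (may be `NULL` for
#'   intercept-only/plant-only specs).
#' @param hyper Optional named list with elements `mu` and `sd` (numeric
#'   vectors over species-parameter columns); if supplied the species-level
#'   Normal densities are included.
#' @param priors Optional [prior_spec]; if supplied the hyperprior terms
#'   are included (requires `hyper`).
#' @return The log joint density (possibly `-Inf`).
#' @export
joint_log_density <- function(data, w, z, species, spec, omega,
                              site_covs = NULL, survey_covs = NULL,
                              hyper = NULL, priors = NULL) {
  stopifnot(inherits(data, "detection_array"))
  M <- dim(data$y)[1]
  lay <- data$layout
  if (length(w) != M || nrow(z) != M)
    stop_invalid("latent-state dimensions do not match the data")
  if (!all(w %in% c(0, 1)) || !all(z %in% c(0, 1)))
    stop_invalid("w and z must be binary")
  if (!is.matrix(species)) species <- matrix(species, nrow = M,
                                             dimnames = list(NULL, names(species)))
  if (any(!is.finite(species))) stop_invalid("non-finite species parameter")
  reg <- param_registry(spec)
  if (is.null(colnames(species))) {
    if (ncol(species) != length(reg$cols))
      stop_invalid("species parameter matrix has wrong number of columns")
    colnames(species) <- reg$cols
  } else {
    species <- species[, reg$cols, drop = FALSE]
  }
  if (!is.finite(omega) || omega < 0 || omega > 1)
    stop_invalid("omega must be a probability")
  if (any(z == 1 & matrix(w == 0, M, ncol(z))))
    return(-Inf)
  lp <- sum(dbinom(w, 1, omega, log = TRUE))
  cells <- layout_cells(lay)
  for (i in seq_len(M)) {
    pars <- species[i, ]
    psi <- occupancy_probability(pars, site_covs, spec, lay)
    if (w[i] == 1) {
      lp <- lp + sum(dbinom(z[i, ], 1, psi, log = TRUE))
    }
    yi <- taxon_slice(data$y, i)[cells]
    zi <- z[i, cells[, 1]]
    if (any(yi == 1 & zi == 0)) return(-Inf)
    occ <- zi == 1
    if (any(occ)) {
      p <- detection_probability(pars, survey_covs, spec, lay,
                                 site_covs)[cells][occ]
      lp <- lp + sum(dbinom(yi[occ], 1, p, log = TRUE))
    }
    # cells with z = 0 and y = 0 contribute log(1) = 0
  }
  if (!is.null(hyper)) {
    mu <- hyper$mu[reg$cols]; sdv <- hyper$sd[reg$cols]
    if (anyNA(mu) || anyNA(sdv))
      stop_invalid("hyper must supply mu and sd for every parameter column")
    if (any(sdv <= 0)) return(-Inf)
    for (c_i in seq_along(reg$cols))
      lp <- lp + sum(dnorm(species[, c_i], mu[c_i], sdv[c_i], log = TRUE))
    if (!is.null(priors)) {
      lp <- lp + stats::dbeta(omega, priors$omega_shape1,
                              priors$omega_shape2, log = TRUE)
      for (c_i in seq_along(reg$cols)) {
        pr <- prior_for_type(priors, reg$type[c_i])
        lp <- lp + if (pr$mu_kind == "logit_uniform")
          stats::dlogis(mu[c_i], log = TRUE)
        else dnorm(mu[c_i], 0, sqrt(pr$mu_var), log = TRUE)
        lp <- lp + if (sdv[c_i] <= pr$sd_upper) -log(pr$sd_upper) else -Inf
      }
    }
  }
  lp
}
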