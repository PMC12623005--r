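#' Prior specification for the community hyperparameters
#'
#' Minimally informative priors for the hierarchical occupancy model.
#' The supercommunity inclusion probability gets a Beta(0.001, 1) prior,
#' which keeps the estimated number of taxa close to the number observed
#' unless the data argue otherwise. Community mean intercepts are the logit
#' of a Uniform(0, 1) variate (flat on the probability scale); community
#' mean coefficients are Normal with mean 0 and *variance* `coef_mean_var`
#' (BUGS-style parameterization); community standard deviations are
#' Uniform(0, upper). The plant-species coefficient, being categorical,
#' has its own (slightly wider) SD bound.
#'
#' @param omega_shape1,omega_shape2 Beta shape parameters for the
#'   supercommunity inclusion probability.
#' @param coef_mean_var Variance of the Normal prior on community mean
#'   coefficients (and the plant coefficient mean).
#' @param sd_intercept_upper Upper bound of the Uniform prior on community
#'   SDs of intercepts.
#' @param sd_coef_upper Upper bound for community SDs of covariate
#'   coefficients.
#' @param sd_plant_upper Upper bound for the community SD of the plant
#'   coefficient.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(omega_shape1 = 0.001, omega_shape2 = 1,
                       coef_mean_var = 10,
                       sd_intercept_upper = 4,
                       sd_coef_upper = 4,
                       sd_plant_upper = 5) {
  vals <- c(omega_shape1, omega_shape2, coef_mean_var,
            sd_intercept_upper, sd_coef_upper, sd_plant_upper)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all prior parameters must be positive and finite")
  structure(list(omega_shape1 = omega_shape1, omega_shape2 = omega_shape2,
                 coef_mean_var = coef_mean_var,
                 sd_intercept_upper = sd_intercept_upper,
                 sd_coef_upper = sd_coef_upper,
                 sd_plant_upper = sd_plant_upper),
            class = "prior_spec")
}

# (mu prior logpdf, sd upper bound) for a species-parameter column type
prior_for_type <- function(priors, type) {
  switch(type,
    intercept = list(mu_kind = "logit_uniform", mu_var = NA_real_,
                     sd_upper = priors$sd_intercept_upper),
    coefficient = list(mu_kind = "normal", mu_var = priors$coef_mean_var,
                       sd_upper = priors$sd_coef_upper),
    plant = list(mu_kind = "normal", mu_var = priors$coef_mean_var,
                 sd_upper = priors$sd_plant_upper),
    stop_invalid("unknown parameter type: ", type))
}

#' Monte-Carlo draws from an induced species-level prior
#'
#' Reproduces the empty-dataset prior calibration: draw the community mean
#' and SD from their hyperpriors, then a species-level effect, and (for
#' intercepts) transform to the probability scale. Used to check that
#' intercept priors are near-flat on (0, 1) and that coefficient priors
#' give a central 95% interval at least as wide as (-5, 5) on the logit
#' scale.
#'
#' @param priors A [prior_spec].
#' @param component One of `"occupancy_intercept"`, `"detection_intercept"`,
#'   `"coefficient"`, `"coefficient_mean"`, `"plant_coefficient"`.
#' @param n_draws Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed.
#' @return List with `draws` (species-level scale; probability scale for
#'   intercepts in `prob`), and `interval`, the central 95% interval of the
#'   species-level draws.
#' @export
sample_induced_prior <- function(priors, component, n_draws = 10000L,
                                 seed = 1L) {
  stopifnot(inherits(priors, "prior_spec"))
  if (n_draws < 1000L) stop_invalid("n_draws must be >= 1000")
  component <- match.arg(component,
    c("occupancy_intercept", "detection_intercept", "coefficient",
      "coefficient_mean", "plant_coefficient"))
  set.seed(as.integer(seed))
  n <- as.integer(n_draws)
  out <- switch(component,
    occupancy_intercept = ,
    detection_intercept = {
      mu <- logit(runif(n))
      sdv <- runif(n, 0, priors$sd_intercept_upper)
      x <- rnorm(n, mu, sdv)
      list(draws = x, prob = inv_logit(x))
    },
    coefficient = {
      mu <- rnorm(n, 0, sqrt(priors$coef_mean_var))
      sdv <- runif(n, 0, priors$sd_coef_upper)
      list(draws = rnorm(n, mu, sdv), prob = NULL)
    },
    coefficient_mean = {
      list(draws = rnorm(n, 0, sqrt(priors$coef_mean_var)), prob = NULL)
    },
    plant_coefficient = {
      mu <- rnorm(n, 0, sqrt(priors$coef_mean_var))
      sdv <- runif(n, 0, priors$sd_plant_upper)
      list(draws = rnorm(n, mu, sdv), prob = NULL)
    })
  out$interval <- unname(quantile(out$draws, c(0.025, 0.975)))
  out
}
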