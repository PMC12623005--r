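test_that("inverse logit matches published logit-probability pairs", {
  expect_equal(round(inv_logit(-1.37), 2), 0.20)
  expect_equal(round(inv_logit(1.84), 2), 0.86)
  expect_equal(inv_logit(0), 0.5)
  # monotone, antisymmetric, inverse of logit
  x <- seq(-6, 6, by = 0.5)
  expect_true(all(diff(inv_logit(x)) > 0))
  expect_equal(inv_logit(-x), 1 - inv_logit(x))
  p <- seq(0.01, 0.99, by = 0.07)
  expect_equal(inv_logit(logit(p)), p)
})

test_that("occupancy and detection probabilities follow the linear predictors", {
  lay <- tiny_layout(r = 2L)
  sp0 <- model_spec()
  pars0 <- c(psi_int = -3.08, p_int = 0, p_plant = 0)
  # intercept-only: one value for all sites; -3.08 -> 0.04
  psi <- occupancy_probability(pars0, NULL, sp0, lay)
  expect_length(psi, 3)
  expect_equal(round(psi[1], 2), 0.04)
  expect_equal(psi, rep(psi[1], 3))
  # all parameters zero -> one half everywhere
  p05 <- detection_probability(c(psi_int = 0, p_int = 0, p_plant = 0),
                               NULL, sp0, lay)
  expect_equal(unique(p05[lay$mask]), 0.5)
  expect_true(all(is.na(p05[!lay$mask])))
  # a covariate effect: logit 0 + 1 * 1 -> 0.7311
  site <- site_covariates(data.frame(urban_dist = c(-1, 0, 1)),
                          moments = data.frame(covariate = "urban_dist",
                                               mean = 0, sd = 1))
  sp1 <- model_spec(occupancy = "urban_dist")
  pars1 <- c(psi_int = 0, psi_urban_dist = 1, p_int = 0, p_plant = 0)
  expect_equal(occupancy_probability(pars1, site, sp1, lay)[3],
               1 / (1 + exp(-1)), tolerance = 1e-12)
  # plant shift: logit(-1 + 2.94) on L. spicata slots
  pars2 <- c(psi_int = 0, p_int = -1, p_plant = 2.94)
  pm <- detection_probability(pars2, NULL, sp0, lay)
  expect_equal(pm[1, 3], inv_logit(1.94), tolerance = 1e-12)  # LS slot
  expect_equal(pm[1, 1], inv_logit(-1), tolerance = 1e-12)    # PM slot
  # missing covariate in spec errors
  expect_error(occupancy_probability(pars1, NULL, sp1, lay), "absent")
})

test_that("plant-by-time interaction vanishes at the covariate mean", {
  lay <- study_layout(c("both", "both"), replicates_per_plant = 1L)
  tmat <- matrix(c(0, 1.5), 2, 2)  # site 1 at the mean, site 2 at +1.5
  svy <- survey_covariates(list(start_time = tmat), lay,
                           moments = data.frame(covariate = "start_time",
                                                mean = 0, sd = 1))
  sp <- model_spec(detection = "plant * start_time")
  pars <- c(psi_int = 0, p_int = -0.4, p_plant = 0.8,
            `p_start_time` = 0.3, `p_plant:start_time` = -0.6)
  p <- detection_probability(pars, svy, sp, lay)
  # site 1 has time = 0: logit p on LS = p_int + p_plant exactly
  expect_equal(logit(p[1, 2]), -0.4 + 0.8, tolerance = 1e-12)
  # site 2, LS slot: all four terms
  expect_equal(logit(p[2, 2]), -0.4 + 0.8 + 0.3 * 1.5 - 0.6 * 1.5,
               tolerance = 1e-12)
})

test_that("joint log density sums the hierarchical Bernoulli layers", {
  # single taxon, site and slot with omega = psi = p = 0.5
  lay <- study_layout("pm_only", replicates_per_plant = 1L)
  arr <- array_from_matrices(list(matrix(c(1L, NA), 1, 2)), lay, "A")
  sp <- model_spec()
  pars <- matrix(c(0, 0, 0), 1, dimnames = list(NULL,
                 c("psi_int", "p_int", "p_plant")))
  ld <- joint_log_density(arr, w = 1, z = matrix(1, 1, 1), species = pars,
                          spec = sp, omega = 0.5)
  expect_equal(ld, 3 * log(0.5), tolerance = 1e-12)
  # detection without occupancy is impossible
  expect_identical(joint_log_density(arr, w = 1, z = matrix(0, 1, 1),
                                     species = pars, spec = sp, omega = 0.5),
                   -Inf)
  # z = 1 requires w = 1
  expect_identical(joint_log_density(arr, w = 0, z = matrix(1, 1, 1),
                                     species = pars, spec = sp, omega = 0.5),
                   -Inf)
  expect_error(joint_log_density(arr, w = 1, z = matrix(1, 1, 1),
                                 species = matrix(NA_real_, 1, 3),
                                 spec = sp, omega = 0.5), "non-finite")
})

test_that("adding one detection changes the log density by the odds term", {
  lay <- tiny_layout(r = 2L)
  arr0 <- assemble_detection_array(
    data.frame(site = integer(0), slot = integer(0), taxon = character(0),
               detected = integer(0)), lay, "A")
  arr1 <- assemble_detection_array(
    data.frame(site = 2, slot = 1, taxon = "A", detected = 1), lay, "A")
  sp <- model_spec()
  pars <- matrix(c(0.3, -0.7, 0.2), 1,
                 dimnames = list(NULL, c("psi_int", "p_int", "p_plant")))
  z <- matrix(1, 1, 3)
  d0 <- joint_log_density(arr0, 1, z, pars, sp, omega = 0.6)
  d1 <- joint_log_density(arr1, 1, z, pars, sp, omega = 0.6)
  p <- detection_probability(pars[1, ], NULL, sp, lay)[2, 1]
  expect_equal(d1 - d0, log(p) - log(1 - p), tolerance = 1e-12)
  # when no site is occupied the observation layer contributes exactly
  # zero: only the w and z layers remain
  z0 <- matrix(0, 1, 3)
  dd <- joint_log_density(arr0, 1, z0, pars, sp, omega = 0.6)
  psi <- occupancy_probability(pars[1, ], NULL, sp, lay)
  expect_equal(dd, log(0.6) + sum(log(1 - psi)), tolerance = 1e-12)
})

test_that("induced priors match their analytic calibration", {
  pr <- prior_spec()
  # community mean coefficient: Normal(0, var 10), central 95% ~ +/- 6.20
  cm <- sample_induced_prior(pr, "coefficient_mean", n_draws = 200000,
                             seed = 11)
  expect_equal(cm$interval[1], -6.20, tolerance = 0.05)
  expect_equal(cm$interval[2], 6.20, tolerance = 0.05)
  expect_true(cm$interval[1] < -5 && cm$interval[2] > 5)
  # species-level coefficient interval is wider than the mean's
  co <- sample_induced_prior(pr, "coefficient", n_draws = 200000, seed = 11)
  expect_true(co$interval[2] > cm$interval[2])
  # intercept prior is near-uniform on the probability scale at sd -> 0
  pr0 <- prior_spec(sd_intercept_upper = 1e-6)
  ip <- sample_induced_prior(pr0, "occupancy_intercept", n_draws = 100000,
                             seed = 2)
  ks <- suppressWarnings(stats::ks.test(ip$prob, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_induced_prior(pr, "nope"), "arg")
  expect_error(sample_induced_prior(pr, "coefficient", n_draws = 10),
               ">= 1000")
})
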