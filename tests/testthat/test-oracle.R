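test_that("exact enumeration reproduces hand-computed tiny posteriors", {
  lay <- study_layout("pm_only", replicates_per_plant = 1L)  # 1 site, 1 slot
  arr1 <- assemble_detection_array(
    data.frame(site = 1, slot = 1, taxon = "A", detected = 1), lay, "A")
  # detection implies occupancy with certainty
  ex1 <- exact_posterior_tiny(arr1, psi = 0.5, p = 0.5, omega = 1)
  expect_equal(ex1$z_prob[1, 1], 1)
  expect_equal(ex1$w_prob[1], 1)
  # all-zero history: psi (1 - p) / (psi (1 - p) + 1 - psi) = 1/3
  arr0 <- assemble_detection_array(
    data.frame(site = integer(0), slot = integer(0), taxon = character(0),
               detected = integer(0)), lay, "A")
  ex0 <- exact_posterior_tiny(arr0, psi = 0.5, p = 0.5, omega = 1)
  expect_equal(ex0$z_prob[1, 1], 1 / 3, tolerance = 1e-12)
  # and the oracle must agree with the closed-form full conditional
  expect_equal(ex0$z_prob[1, 1], cond_prob_z(1, 0.5, 0.5, 0))
  # size guard
  big <- assemble_detection_array(
    data.frame(site = integer(0), slot = integer(0), taxon = character(0),
               detected = integer(0)),
    garden_layout(), paste0("s", 1:4))
  expect_error(exact_posterior_tiny(big, 0.5, 0.5, 0.5), "too large")
})

test_that("enumeration probabilities are a normalized distribution", {
  # the per-taxon configuration sum must match the factored closed form
  lay <- study_layout(c("both", "pm_only"), replicates_per_plant = 1L)
  arr <- assemble_detection_array(
    data.frame(site = c(1, 1), slot = c(1, 2), taxon = "A",
               detected = c(1, 0)), lay, c("A", "B"))
  psi <- c(0.3, 0.6); p <- c(0.4, 0.2); om <- 0.7
  ex <- exact_posterior_tiny(arr, psi = psi, p = p, omega = om)
  # closed form for taxon A: detected at site 1 -> z11 = 1, w = 1
  expect_equal(ex$w_prob[1], 1)
  expect_equal(ex$z_prob[1, 1], 1)
  # taxon B all-zero: per-site conditional from Bayes, given w = 1
  # P(w=1|y) via the marginal likelihoods
  L1 <- prod((0.6 * c((1 - 0.2)^2, (1 - 0.2))) + 0.4)
  pw <- om * L1 / (om * L1 + (1 - om))
  expect_equal(ex$w_prob[2], pw, tolerance = 1e-12)
  # probabilities lie in [0, 1]
  expect_true(all(ex$z_prob >= 0 & ex$z_prob <= 1))
})

test_that("the hierarchical quadrature oracle is internally consistent", {
  # on an all-zero one-taxon instance the site-occupancy posteriors are
  # exchangeable across sites and bounded by the membership posterior
  lay <- study_layout(rep("pm_only", 3), replicates_per_plant = 1L)
  arr0 <- assemble_detection_array(
    data.frame(site = integer(0), slot = integer(0), taxon = character(0),
               detected = integer(0)), lay, "A")
  ex <- exact_posterior_hier1(arr0, prior_spec(), n_grid = 161L)
  expect_equal(ex$z_prob[1], ex$z_prob[2], tolerance = 1e-10)
  expect_equal(ex$z_prob[2], ex$z_prob[3], tolerance = 1e-10)
  expect_true(all(ex$z_prob <= ex$w_prob))
  expect_true(ex$omega_mean > 0 && ex$omega_mean < 1)
  # a detection forces membership and occupancy at that site
  arr1 <- assemble_detection_array(
    data.frame(site = 2, slot = 1, taxon = "A", detected = 1), lay, "A")
  ex1 <- exact_posterior_hier1(arr1, prior_spec(), n_grid = 161L)
  expect_equal(ex1$w_prob, 1, tolerance = 1e-10)
  expect_equal(ex1$z_prob[2], 1, tolerance = 1e-10)
  expect_gt(ex1$omega_mean, ex$omega_mean)
})

# The direct sampler-versus-oracle equivalence checks (fixed-parameter
# two-taxon instance with omega integrated over its prior, and the full
# hierarchical machinery on a one-taxon instance against 3-D quadrature)
# run in test-acceptance.R.
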