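test_that("generated covariates honour layout, truncation and determinism", {
  lay <- garden_layout()
  c1 <- generate_covariates(lay, seed = 5)
  c2 <- generate_covariates(lay, seed = 5)
  expect_identical(c1$site$raw, c2$site$raw)
  expect_identical(c1$survey$raw, c2$survey$raw)
  # distances and areas are nonnegative always
  expect_true(all(c1$site$raw$urban_dist >= 0))
  expect_true(all(c1$site$raw$garden_area >= 0))
  # standardized columns have sample mean ~0, sd ~1
  for (v in names(c1$survey$std)) {
    vals <- c1$survey$std[[v]][lay$mask]
    expect_equal(mean(vals), 0, tolerance = 1e-10)
    expect_equal(sd(vals), 1, tolerance = 1e-10)
  }
  # survey values are constant within a visit (broadcast to its slots)
  both_site <- which(lay$availability == "both")[1]
  tv <- c1$survey$raw$temperature[both_site, ]
  expect_equal(length(unique(tv[1:5])), 1L)
  expect_equal(length(unique(tv[6:10])), 1L)
  # missing slots carry no raw values
  pm_site <- which(lay$availability == "pm_only")[1]
  expect_true(all(is.na(c1$survey$raw$temperature[pm_site, 6:10])))
})

test_that("degenerate scenarios produce the forced outcomes", {
  lay <- tiny_layout(r = 2L)
  # certainty everywhere: every surveyed cell is a detection
  sc1 <- scenario_config(layout = lay, n_taxa = 3, omega = 1,
                         mu = c(psi_int = 20, p_int = 20, p_plant = 0),
                         sd = c(psi_int = 0, p_int = 0, p_plant = 0),
                         seed = 2)
  g1 <- generate_dataset(sc1)
  expect_equal(g1$data$n_observed, 3L)
  expect_true(all(g1$data$y == 1L, na.rm = TRUE))
  # an empty supercommunity yields an all-zero (empty) observed array
  sc0 <- scenario_config(layout = lay, n_taxa = 3, omega = 0, seed = 2)
  g0 <- generate_dataset(sc0)
  expect_equal(g0$data$n_observed, 0L)
  expect_true(all(g0$truth$w == 0L))
  # truth always satisfies z <= w and detections only where z = 1
  sc <- scenario_config(layout = lay, n_taxa = 6, omega = 0.7, seed = 9)
  g <- generate_dataset(sc)
  expect_true(all(g$truth$z <= matrix(g$truth$w, 6, lay$n_sites)))
  validate_detection_array(g$data)
})

test_that("generated arrays are reproducible and augmentable", {
  sc <- scenario_config(layout = tiny_layout(r = 2L), n_taxa = 5,
                        omega = 0.8, seed = 31)
  g1 <- generate_dataset(sc)
  g2 <- generate_dataset(sc)
  expect_identical(g1$data$y, g2$data$y)
  aug <- augment_detection_array(g1$data, 4L)
  expect_silent(validate_detection_array(aug))
})

test_that("empirical detection frequency tracks the generating surfaces", {
  # with many sites the per-taxon detection frequency approaches the
  # marginal probability implied by the generating psi and p surfaces
  lay <- study_layout(rep("pm_only", 400), replicates_per_plant = 2L)
  sc <- scenario_config(layout = lay, n_taxa = 2, omega = 1,
                        mu = c(psi_int = 0.8, p_int = 0.2, p_plant = 0),
                        sd = c(psi_int = 0, p_int = 0, p_plant = 0),
                        seed = 77)
  g <- generate_dataset(sc)
  psi <- inv_logit(0.8); p <- inv_logit(0.2)
  ncell <- sum(lay$mask)
  exp_freq <- psi * p
  for (i in seq_len(g$data$n_observed)) {
    obs_freq <- sum(g$data$y[i, , ], na.rm = TRUE) / ncell
    se <- sqrt(exp_freq * (1 - exp_freq) / ncell)
    expect_lt(abs(obs_freq - exp_freq), 4 * se + 0.01)
  }
})

test_that("study-scale preset yields observation volumes like the survey", {
  # under the garden preset (49 potential taxa, published hyperparameter
  # truth) the number of detected taxa is typically in the low teens
  detected <- vapply(1:6, function(s)
    generate_dataset(garden_scenario(seed = 100 + s))$data$n_observed,
    integer(1))
  expect_true(median(detected) >= 8 && median(detected) <= 25)
  expect_true(all(detected >= 4 & detected <= 35))
})
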