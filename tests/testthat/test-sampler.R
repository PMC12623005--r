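test_that("closed-form latent-state conditionals match hand computation", {
  # detection implies presence
  expect_equal(cond_prob_z(1, 0.3, c(0.2, 0.9), c(0, 1)), 1)
  # out of the supercommunity implies absence
  expect_equal(cond_prob_z(0, 0.5, c(0.5, 0.5), c(0, 0)), 0)
  # Bayes on an all-zero history: 0.5 * 0.25 / (0.5 * 0.25 + 0.5) = 0.2
  expect_equal(cond_prob_z(1, 0.5, c(0.5, 0.5), c(0, 0)), 0.2)
  # membership forced by occupancy anywhere
  expect_equal(cond_prob_w(0.1, c(0.5, 0.5), c(1, 0)), 1)
  # same 0.2 arithmetic at the community level
  expect_equal(cond_prob_w(0.5, c(0.5, 0.5), c(0, 0)), 0.2)
  # vanishing prior inclusion
  expect_equal(cond_prob_w(0, c(0.5, 0.5), c(0, 0)), 0)
})

test_that("omega draw uses the conjugate Beta full conditional", {
  w <- c(rep(1, 21), rep(0, 28))  # M = 49, sum = 21
  set.seed(9); d <- draw_omega(w, 0.001, 1)
  expect_equal(attr(d, "shape1"), 21.001)
  expect_equal(attr(d, "shape2"), 29)
  set.seed(9); ref <- rbeta(1, 21.001, 29)
  expect_equal(as.numeric(d), ref)
  # all-out case has posterior mean near zero
  d0 <- draw_omega(rep(0, 49), 0.001, 1)
  expect_equal(attr(d0, "shape1") / (attr(d0, "shape1") + attr(d0, "shape2")),
               0.001 / (0.001 + 50), tolerance = 1e-12)
})

test_that("retained-draw arithmetic and determinism hold", {
  expect_equal(n_retained(mcmc_config(3, 450000, 100000, 10)), 105000L)
  expect_equal(n_retained(mcmc_config(2, 1000, 500, 5)), 200L)
  expect_error(mcmc_config(3, 1000, 1000, 1), "burn_in")
  expect_error(mcmc_config(3, 1000, 100, 0), "thin")

  f <- shared_small_fit()
  cfg <- mcmc_config(2L, 600L, 200L, 2L, seed = 5L)
  fit1 <- run_mcmc(f$aug, f$scenario$spec, cfg,
                   site_covs = f$sim$site_covs,
                   survey_covs = f$sim$survey_covs)
  fit2 <- run_mcmc(f$aug, f$scenario$spec, cfg,
                   site_covs = f$sim$site_covs,
                   survey_covs = f$sim$survey_covs)
  expect_identical(posterior_draws(fit1, "all"), posterior_draws(fit2, "all"))
  expect_equal(nrow(posterior_draws(fit1, "hyper")), 400L)
})

test_that("latent draws respect the structural invariants at every draw", {
  f <- shared_small_fit()
  fit <- f$fit
  M <- dim(f$aug$y)[1]; J <- f$aug$layout$n_sites
  det_sites <- matrix(FALSE, M, J)
  for (i in seq_len(M)) for (j in seq_len(J))
    det_sites[i, j] <- any(f$aug$y[i, j, ] == 1L, na.rm = TRUE)
  for (ch in seq_along(fit$chains)) {
    w <- fit$chains[[ch]]$w
    zarr <- msomaug:::z_draws(fit, ch)[[1]]
    n <- nrow(w)
    # z <= w everywhere
    wexp <- array(rep(w, times = J), dim = c(n, M, J))
    expect_true(all(zarr <= wexp))
    # z = 1 wherever the taxon was detected at the site
    dexp <- aperm(array(rep(det_sites, each = n), dim = c(n, M, J)),
                  c(1, 2, 3))
    expect_true(all(zarr[dexp] == 1L))
  }
})

test_that("gelman_rubin detects convergence and disjoint chains", {
  set.seed(21)
  # same stationary normal: R-hat near 1
  tr <- matrix(rnorm(10000), 5000, 2)
  gr <- gelman_rubin(tr)
  expect_lt(gr$rhat, 1.05)
  expect_true(gr$converged)
  # disjoint chains: far above threshold
  gr2 <- gelman_rubin(cbind(rep(0, 100), rep(10, 100)))
  expect_gt(gr2$rhat, 10)
  expect_false(gr2$converged)
  # threshold boundary semantics
  expect_true(gelman_rubin(tr, threshold = gr$rhat + 1e-9)$converged)
  expect_false(gelman_rubin(tr, threshold = gr$rhat - 1e-9)$converged)
  # degenerate traces warn and return 1
  expect_warning(gr3 <- gelman_rubin(cbind(rep(2, 50), rep(2, 50))),
                 "degenerate")
  expect_equal(gr3$rhat, 1)
  expect_error(gelman_rubin(matrix(1:10, 10, 1)), "two chains")
})

test_that("gelman_rubin agrees with the coda reference implementation", {
  set.seed(31)
  x1 <- as.numeric(arima.sim(list(ar = 0.6), 2000))
  x2 <- as.numeric(arima.sim(list(ar = 0.6), 2000)) + 0.2
  ours <- gelman_rubin(cbind(x1, x2))$rhat
  ml <- coda::mcmc.list(coda::mcmc(x1), coda::mcmc(x2))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE, transform = FALSE)
  expect_equal(ours, as.numeric(ref$psrf[1, 1]), tolerance = 0.02)
})

test_that("hyperparameters the data cannot inform reproduce their prior", {
  # an empty-dataset calibration: on a single-plant layout the plant
  # coefficient never enters the likelihood, so the sampler's marginal
  # for its community mean must reproduce the Normal(0, 10) prior
  lay <- study_layout(c("pm_only", "pm_only"), replicates_per_plant = 1L)
  arr <- assemble_detection_array(
    data.frame(site = integer(0), slot = integer(0), taxon = character(0),
               detected = integer(0)), lay, "A")
  aug <- augment_detection_array(arr, 1L)
  fit <- run_mcmc(aug, model_spec(), mcmc_config(2L, 12000L, 2000L, 2L, 61L))
  dr <- posterior_draws(fit, "hyper")
  # plant covariate never varies (PM only), so mu_p_plant stays at its
  # Normal(0, 10) prior
  mu_pl <- dr[, "mu_p_plant"]
  expect_equal(mean(mu_pl), 0, tolerance = 3 * mcse(mu_pl))
  expect_equal(sd(mu_pl), sqrt(10), tolerance = 0.35)
  thin_idx <- seq(1, length(mu_pl), by = 25)
  ks <- suppressWarnings(stats::ks.test(mu_pl[thin_idx], pnorm, 0, sqrt(10)))
  expect_gt(ks$p.value, 0.001)
})
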