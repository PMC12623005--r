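# A shared simulated dataset with a known strong start-time effect on
# detection, a plant preference, and null occupancy covariates.
selection_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lay <- study_layout(rep(c("both", "pm_only", "ls_only"),
                            times = c(12, 12, 6)),
                        replicates_per_plant = 3L)
    sc <- scenario_config(
      layout = lay, n_taxa = 10L, omega = 0.9,
      spec = model_spec(detection = "plant + start_time"),
      mu = c(psi_int = 0.7, p_int = -0.6, p_plant = -1.2,
             p_start_time = 1.2),
      sd = c(psi_int = 0.8, p_int = 0.8, p_plant = 1.0,
             p_start_time = 0.5),
      seed = 302L)
    sim <- generate_dataset(sc)
    aug <- augment_detection_array(sim$data, 10L - sim$data$n_observed)
    cache <<- list(sc = sc, sim = sim, aug = aug,
                   cfg = mcmc_config(2L, 4000L, 1500L, 2L, seed = 11L))
    cache
  }
})

test_that("influential-coefficient counting matches the CrI rule", {
  s <- selection_sim()
  fit <- run_mcmc(s$aug, s$sc$spec, s$cfg, site_covs = s$sim$site_covs,
                  survey_covs = s$sim$survey_covs)
  dr <- posterior_draws(fit, "species")
  obs_taxa <- s$aug$taxa[seq_len(s$aug$n_observed)]
  manual <- sum(vapply(obs_taxa, function(tx) {
    q <- quantile(dr[, paste0("p_start_time[", tx, "]")], c(0.025, 0.975))
    q[1] > 0 || q[2] < 0
  }, logical(1)))
  expect_equal(count_influential(fit, "start_time"), manual)
  # the strong simulated effect is influential for multiple taxa
  expect_gte(count_influential(fit, "start_time"), 2L)
  expect_error(count_influential(fit, "light"), "not in the fitted model")
})

test_that("candidate eligibility enforces hierarchy and the screen", {
  elig <- msomaug:::candidate_eligible
  # interaction needs its (non-plant) mains in the base
  expect_false(elig("plant:start_time", character(0), NULL))
  expect_true(elig("plant:start_time", "start_time", NULL))
  expect_false(elig("I(temperature^2)", character(0), NULL))
  expect_true(elig("I(temperature^2)", "temperature", NULL))
  # screened pairs never co-fit
  scr <- data.frame(var1 = "urban_dist", var2 = "garden_area",
                    r = 0.65, excluded = TRUE)
  expect_false(elig("garden_area", "urban_dist", scr))
  expect_true(elig("garden_area", "start_time", scr))
})

test_that("a forward step advances the strongest candidate and can stop", {
  s <- selection_sim()
  base <- model_spec()
  st <- forward_step(base, c("start_time", "light"), "detection", s$aug,
                     site_covs = s$sim$site_covs,
                     survey_covs = s$sim$survey_covs, config = s$cfg)
  expect_false(st$stopped)
  expect_true("start_time" %in% st$spec$detection)
  expect_equal(st$round$decision[st$round$candidate == "start_time"],
               "advance")
  # counts recorded for every candidate
  expect_setequal(st$round$candidate, c("start_time", "light"))
  # with only null candidates the step stops
  st0 <- forward_step(base, "garden_area", "occupancy", s$aug,
                      site_covs = s$sim$site_covs,
                      survey_covs = s$sim$survey_covs, config = s$cfg)
  expect_true(st0$stopped)
})

test_that("selection is reproducible and never fits screened pairs", {
  s <- selection_sim()
  run <- function() select_model(
    s$aug, s$sim$site_covs, s$sim$survey_covs,
    occupancy_candidates = "urban_dist",
    detection_candidates = c("start_time", "light"),
    config = s$cfg)
  s1 <- run(); s2 <- run()
  expect_identical(s1$trace, s2$trace)
  expect_identical(format(s1$spec), format(s2$spec))
  expect_true("start_time" %in% s1$spec$detection)
})
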