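test_that("parameter summaries and influence flags follow their definitions", {
  expect_equal(summarize_parameter(1:5)[["mean"]], 3)
  expect_equal(summarize_parameter(1:5)[["median"]], 3)
  s <- summarize_parameter(rep(4.2, 10))
  expect_equal(unname(s[c("q2.5", "q97.5")]), c(4.2, 4.2))
  expect_error(summarize_parameter(numeric(0)), "2 draws")
  set.seed(8)
  big <- rnorm(100000)
  sb <- summarize_parameter(big)
  expect_equal(unname(sb[c("q2.5", "q97.5")]), c(-1.96, 1.96),
               tolerance = 0.02)

  # influence classification
  ci_pos <- coefficient_influence(runif(500, 0.1, 2))
  expect_true(ci_pos$influential)
  expect_equal(ci_pos$p_positive, 1)
  ci_mix <- coefficient_influence(rep(c(-1, 1, 1, 1), 50))
  expect_equal(ci_mix$p_positive, 0.75)
  expect_false(ci_mix$well_supported)
  # CrI barely excluding zero is influential regardless of p_positive
  x <- c(rep(-0.5, 12), seq(0.01, 1, length.out = 488))
  ci_edge <- coefficient_influence(x)
  expect_equal(ci_edge$influential, ci_edge$q2.5 > 0 || ci_edge$q97.5 < 0)
  expect_error(coefficient_influence(rnorm(50)), "100 draws")
})

test_that("derived richness quantities respect their structural bounds", {
  f <- shared_small_fit()
  fit <- f$fit
  M <- dim(f$aug$y)[1]; J <- f$aug$layout$n_sites
  d <- msomaug:::derived_draw_matrices(fit)
  # richness never exceeds the augmented taxon count
  expect_true(all(d$site_richness <= M))
  # richness at least the number of taxa detected at the site
  sr <- site_richness(fit)
  expect_true(all(sr$q2.5 >= sr$n_detected))
  # taxa-present-anywhere <= supercommunity size at every draw
  expect_true(all(d$n_present <= d$supercommunity))
  # supercommunity size bounded below by observed taxa, above by M
  expect_true(all(d$supercommunity >= f$aug$n_observed))
  expect_true(all(d$supercommunity <= M))
  sc <- supercommunity_size(fit)
  expect_equal(sc$median, median(d$supercommunity))
  # per-taxon occupied sites at least naive, at most J
  so <- species_occurrence(fit)
  expect_true(all(so$per_taxon$q2.5 >= so$per_taxon$n_sites_detected))
  expect_true(all(so$per_taxon$median <= J))
})

test_that("undetected augmented taxa have exchangeable posteriors", {
  f <- shared_small_fit()
  fit <- f$fit
  d <- msomaug:::derived_draw_matrices(fit)
  aug_idx <- which(seq_len(dim(f$aug$y)[1]) > f$aug$n_observed)
  expect_gte(length(aug_idx), 2)  # the seeded scenario leaves several
  means <- colMeans(d$occupied_sites[, aug_idx, drop = FALSE])
  ses <- apply(d$occupied_sites[, aug_idx, drop = FALSE], 2, mcse)
  # all pairwise differences within Monte-Carlo error
  for (a in seq_along(aug_idx)[-1])
    expect_lt(abs(means[1] - means[a]),
              4 * sqrt(ses[1]^2 + ses[a]^2) + 0.02)
})

test_that("fit summary table is complete and typed", {
  f <- shared_small_fit()
  tab <- summarize_fit(f$fit)
  reg <- f$fit$registry
  M <- dim(f$aug$y)[1]
  expect_equal(nrow(tab), (1 + 2 * length(reg$cols)) + M * length(reg$cols))
  expect_true(all(tab$q2.5 <= tab$median & tab$median <= tab$q97.5))
  expect_true(all(tab$p_positive >= 0 & tab$p_positive <= 1))
  # influential implies well-supported
  expect_true(all(!tab$influential | tab$well_supported))
  # hyperparameters carry no taxon label
  expect_true(all(is.na(tab$taxon[tab$parameter == "omega"])))
  # CSV export writes the three tables
  dir <- withr::local_tempdir()
  paths <- write_fit_summaries(f$fit, dir)
  expect_true(all(file.exists(unlist(paths))))
})
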