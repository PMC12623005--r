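# Shared fixtures built in code.

tiny_layout <- function(avail = c("both", "pm_only", "ls_only"),
                        r = 2L) {
  study_layout(avail, replicates_per_plant = r)
}

# detection array from explicit per-taxon J x K matrices (NA = missing)
array_from_matrices <- function(mats, layout, taxa = NULL) {
  taxa <- taxa %||% paste0("t", seq_along(mats))
  recs <- do.call(rbind, lapply(seq_along(mats), function(i) {
    idx <- which(mats[[i]] == 1L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(site = idx[, 1], slot = idx[, 2], taxon = taxa[i],
               detected = 1L)
  }))
  if (is.null(recs)) recs <- data.frame(site = integer(0), slot = integer(0),
                                        taxon = character(0),
                                        detected = integer(0))
  assemble_detection_array(recs, layout, taxa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte-Carlo standard error via batch means
mcse <- function(x, n_batch = 50L) {
  n <- length(x)
  bs <- n %/% n_batch
  if (bs < 2L) return(stats::sd(x) / sqrt(n))
  m <- colMeans(matrix(x[seq_len(bs * n_batch)], nrow = bs))
  stats::sd(m) / sqrt(n_batch)
}

# a small fitted model shared across summary/gof tests (computed once)
shared_small_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- scenario_config(
      layout = study_layout(rep(c("both", "pm_only", "ls_only"),
                                times = c(6, 6, 3)),
                            replicates_per_plant = 3L),
      n_taxa = 8L, omega = 0.8,
      mu = c(psi_int = 0.5, p_int = -0.5, p_plant = -0.5),
      sd = c(psi_int = 1, p_int = 1, p_plant = 1),
      seed = 42L)
    sim <- generate_dataset(sc)
    aug <- augment_detection_array(sim$data, 8L - sim$data$n_observed)
    fit <- run_mcmc(aug, sc$spec, mcmc_config(2L, 3000L, 1000L, 2L, seed = 7L),
                    site_covs = sim$site_covs, survey_covs = sim$survey_covs)
    cache <<- list(scenario = sc, sim = sim, aug = aug, fit = fit)
    cache
  }
})
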