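#' MCMC configuration
#'
#' @param n_chains Number of chains (default 3).
#' @param n_iter Iterations per chain, including burn-in.
#' @param burn_in Iterations discarded as burn-in (< `n_iter`). Proposal
#'   adaptation runs during burn-in only.
#' @param thin Keep every `thin`-th post-burn-in iteration (>= 1); thinning
#'   only reduces output size.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @return Object of class `mcmc_config`.
#' @examples
#' n_retained(mcmc_config(3, 450000, 100000, 10))  # 105000
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 20000L, burn_in = 10000L,
                        thin = 5L, seed = 1L) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (n_chains < 1L) stop_invalid("need at least one chain")
  if (burn_in >= n_iter) stop_invalid("burn_in must be < n_iter")
  if (thin < 1L) stop_invalid("thin must be >= 1")
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Total retained posterior draws for a configuration
#'
#' `n_chains * floor((n_iter - burn_in) / thin)`.
#'
#' @param config An [mcmc_config].
#' @return Integer count of retained draws across chains.
#' @export
n_retained <- function(config) {
  stopifnot(inherits(config, "mcmc_config"))
  config$n_chains * ((config$n_iter - config$burn_in) %/% config$thin)
}

# Internal: shared geometry between the sampler, GOF and summaries
model_inputs <- function(data, spec, site_covs, survey_covs) {
  lay <- data$layout
  Xpsi <- occupancy_design(spec, lay, site_covs)
  dd <- detection_design(spec, lay, site_covs, survey_covs)
  cells <- dd$cells
  M <- dim(data$y)[1]
  ycell <- matrix(0L, M, nrow(cells))
  for (i in seq_len(M))
    ycell[i, ] <- taxon_slice(data$y, i)[cells]
  counts <- tabulate(cells[, 1], nbins = lay$n_sites)
  site_start <- c(0L, cumsum(counts))
  list(Xpsi = Xpsi, Xdet = dd$X, cells = cells, ycell = ycell,
       cell_site = cells[, 1] - 1L, site_start = as.integer(site_start))
}

#' Fit the multispecies occupancy model by MCMC
#'
#' Draws from the posterior of the hierarchical occupancy model with
#' Metropolis-within-Gibbs: closed-form Bernoulli full conditionals for
#' supercommunity membership `w` and site occupancy `z`, a conjugate Beta
#' update for the inclusion probability omega, and adaptive Gaussian
#' random-walk Metropolis for species-level parameters (blocked per taxon
#' into occupancy and detection blocks) and community means/SDs (scalar
#' updates; SDs proposed on the log scale). Runs are reproducible given
#' the configuration seed.
#'
#' @param data A `detection_array` (typically augmented with
#'   [augment_detection_array()]).
#' @param spec A [model_spec].
#' @param config An [mcmc_config].
#' @param priors A [prior_spec].
#' @param site_covs,survey_covs Covariate objects matching the model
#'   specification (may be `NULL` for intercept/plant-only models).
#' @param fix_species_params Optional M x D matrix of species parameters
#'   (registry column order) to hold fixed; used for exact-oracle
#'   validation of the latent-state updates.
#' @param fix_omega Optional fixed value for omega.
#' @return Object of class `msom_fit`: per-chain draws of hyperparameters,
#'   species parameters, and latent `w`/`z` states, plus model metadata.
#' @export
run_mcmc <- function(data, spec, config, priors = prior_spec(),
                     site_covs = NULL, survey_covs = NULL,
                     fix_species_params = NULL, fix_omega = NULL) {
  stopifnot(inherits(data, "detection_array"), inherits(spec, "model_spec"),
            inherits(config, "mcmc_config"), inherits(priors, "prior_spec"))
  validate_detection_array(data)
  reg <- param_registry(spec)
  mi <- model_inputs(data, spec, site_covs, survey_covs)
  M <- dim(data$y)[1]; J <- data$layout$n_sites
  Dall <- length(reg$cols)
  stopifnot(ncol(mi$Xpsi) + ncol(mi$Xdet) == Dall)

  pr <- lapply(reg$type, prior_for_type, priors = priors)
  mu_kind <- vapply(pr, function(x) if (x$mu_kind == "logit_uniform") 0L else 1L,
                    integer(1))
  mu_var <- vapply(pr, function(x) ifelse(is.na(x$mu_var), 1, x$mu_var),
                   numeric(1))
  sd_upper <- vapply(pr, function(x) x$sd_upper, numeric(1))

  fix_species <- !is.null(fix_species_params)
  if (fix_species) {
    fix_species_params <- as.matrix(fix_species_params)
    stopifnot(nrow(fix_species_params) == M,
              ncol(fix_species_params) == Dall)
  }

  # naive initialization quantities
  ncell <- ncol(mi$ycell)
  det_rate <- rowMeans(mi$ycell)
  site_det <- matrix(0L, M, J)
  for (i in seq_len(M))
    site_det[i, ] <- as.integer(tabulate(mi$cell_site[mi$ycell[i, ] == 1L] + 1L,
                                         nbins = J) > 0L)
  naive_occ <- rowMeans(site_det)
  clamp <- function(x, lim = 3) pmin(pmax(x, -lim), lim)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    theta0 <- matrix(0, M, Dall)
    theta0[, 1] <- clamp(logit(pmin(pmax(naive_occ, 0.05), 0.95)))
    theta0[, reg$n_occ + 1L] <- clamp(logit(pmin(pmax(det_rate, 0.02), 0.98)))
    theta0 <- theta0 + matrix(rnorm(M * Dall, 0, 0.5), M, Dall)
    if (fix_species) theta0 <- fix_species_params
    w0 <- ifelse(det_rate > 0, 1L,
                 as.integer(rbinom(M, 1L, 0.5)))
    z0 <- site_det
    und <- z0 == 0L & matrix(w0 == 1L, M, J)
    z0[und] <- rbinom(sum(und), 1L, 0.5)
    omega0 <- if (!is.null(fix_omega)) fix_omega else
      (sum(w0) + 0.5) / (M + 1)
    mu0 <- rnorm(Dall, 0, 0.5)
    mu0[c(1L, reg$n_occ + 1L)] <- c(mean(theta0[, 1]),
                                    mean(theta0[, reg$n_occ + 1L]))
    sd0 <- pmin(rep(1, Dall), sd_upper * 0.9)

    raw <- msom_chain_cpp(mi$ycell, mi$cell_site, mi$site_start,
                          mi$Xpsi, mi$Xdet,
                          mu_kind, mu_var, sd_upper,
                          priors$omega_shape1, priors$omega_shape2,
                          config$n_iter, config$burn_in, config$thin,
                          theta0, w0, z0, omega0, mu0, sd0,
                          fix_species, !is.null(fix_omega), !fix_species)
    colnames(raw$hyper) <- c("omega", paste0("mu_", reg$cols),
                             paste0("sd_", reg$cols))
    colnames(raw$theta) <- paste0(rep(reg$cols, each = M), "[",
                                  rep(data$taxa, Dall), "]")
    colnames(raw$w) <- data$taxa
    chains[[ch]] <- raw
  }

  structure(
    list(chains = chains, spec = spec, priors = priors, config = config,
         data = data, site_covs = site_covs, survey_covs = survey_covs,
         registry = reg, inputs = mi,
         fixed = list(species = fix_species, omega = !is.null(fix_omega))),
    class = "msom_fit")
}

#' Fit by MCMC, re-running with longer chains until converged
#'
#' Applies the convergence protocol used throughout the package: fit,
#' check the Gelman-Rubin statistic of every tracked parameter, and on
#' non-convergence re-run with the iteration count and burn-in doubled
#' (up to `max_refits` times). The final fit is returned with attributes
#' `max_rhat` and `refits`.
#'
#' @inheritParams run_mcmc
#' @param threshold R-hat convergence threshold (default 1.05).
#' @param max_refits Maximum number of doubled re-runs (default 2).
#' @param ... Passed on to [run_mcmc()].
#' @return An `msom_fit` with attributes `max_rhat` and `refits`.
#' @export
run_mcmc_converged <- function(data, spec, config, ..., threshold = 1.05,
                               max_refits = 2L) {
  cfg <- config
  refits <- 0L
  repeat {
    fit <- run_mcmc(data, spec, cfg, ...)
    rh <- rhat_all(fit, include_species = TRUE)
    if (max(rh) < threshold || refits >= max_refits) break
    refits <- refits + 1L
    cfg$n_iter <- cfg$n_iter * 2L
    cfg$burn_in <- cfg$burn_in * 2L
  }
  attr(fit, "max_rhat") <- max(rh)
  attr(fit, "refits") <- refits
  fit
}

#' @export
print.msom_fit <- function(x, ...) {
  cat("msom_fit:", dim(x$data$y)[1], "taxa,", x$data$layout$n_sites,
      "sites;", format(x$spec), "\n")
  cat("  ", x$config$n_chains, "chains x",
      nrow(x$chains[[1]]$hyper), "retained draws\n")
  invisible(x)
}

#' Pooled posterior draws as a matrix
#'
#' @param fit An `msom_fit`.
#' @param which `"hyper"`, `"species"`, or `"all"`.
#' @return Matrix with one column per parameter, chains stacked in order.
#' @export
posterior_draws <- function(fit, which = c("hyper", "species", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "msom_fit"))
  get <- function(ch) switch(which,
    hyper = ch$hyper, species = ch$theta,
    all = cbind(ch$hyper, ch$theta))
  do.call(rbind, lapply(fit$chains, get))
}

# per-chain draws of the latent z for taxon i: list of (draws x J) matrices
z_draws <- function(fit, chain = NULL) {
  M <- dim(fit$data$y)[1]; J <- fit$data$layout$n_sites
  chs <- if (is.null(chain)) seq_along(fit$chains) else chain
  lapply(fit$chains[chs], function(ch) {
    array(ch$z, dim = c(nrow(ch$z), M, J))
  })
}

w_draws <- function(fit) do.call(rbind, lapply(fit$chains, `[[`, "w"))

#' Write posterior draws as columnar CSV files
#'
#' One file per chain (`draws_chain<c>.csv`, hyperparameters and species
#' parameters side by side) plus a `parameters.csv` sidecar describing
#' each column (name, level, taxon, term).
#'
#' @param fit An `msom_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_posterior_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "msom_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in seq_along(fit$chains)) {
    p <- file.path(dir, sprintf("draws_chain%d.csv", ch))
    write.csv(cbind(fit$chains[[ch]]$hyper, fit$chains[[ch]]$theta),
              p, row.names = FALSE)
    paths <- c(paths, p)
  }
  nm <- c(colnames(fit$chains[[1]]$hyper), colnames(fit$chains[[1]]$theta))
  reg_path <- file.path(dir, "parameters.csv")
  write.csv(data.frame(
    parameter = nm,
    level = ifelse(grepl("\\[", nm), "species", "community"),
    taxon = ifelse(grepl("\\[", nm), sub("^.*\\[(.*)\\]$", "\\1", nm),
                   NA_character_),
    term = sub("\\[.*\\]$", "", nm)), reg_path, row.names = FALSE)
  invisible(c(paths, reg_path))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF comparing between- and within-chain variance for a single
#' parameter: `sqrt(((n - 1)/n * W + B/n) / W)`. Chains whose traces are
#' all identical and constant return 1 with a warning (degenerate trace).
#'
#' @param traces A numeric matrix (draws x chains) or a list of equal-length
#'   numeric vectors, one per chain (>= 2 chains, >= 10 draws).
#' @param threshold Convergence threshold (default 1.05).
#' @return List with `rhat` and logical `converged` (`rhat < threshold`).
#' @export
gelman_rubin <- function(traces, threshold = 1.05) {
  if (is.list(traces)) traces <- do.call(cbind, traces)
  traces <- as.matrix(traces)
  n <- nrow(traces); m <- ncol(traces)
  if (m < 2L) stop_invalid("need at least two chains")
  if (n < 10L) stop_invalid("need at least 10 draws per chain")
  W <- mean(apply(traces, 2, stats::var))
  B_n <- stats::var(colMeans(traces))  # B/n
  if (W == 0) {
    if (B_n == 0) {
      warning("degenerate traces: zero within- and between-chain variance",
              call. = FALSE)
      return(list(rhat = 1, converged = TRUE))
    }
    return(list(rhat = Inf, converged = FALSE))
  }
  rhat <- sqrt(((n - 1) / n * W + B_n) / W)
  list(rhat = rhat, converged = rhat < threshold)
}

#' R-hat for every tracked parameter of a fit
#'
#' @param fit An `msom_fit`.
#' @param include_species Include species-level parameters (default TRUE).
#' @return Named numeric vector of R-hat values.
#' @export
rhat_all <- function(fit, include_species = TRUE) {
  stopifnot(inherits(fit, "msom_fit"))
  nm <- colnames(fit$chains[[1]]$hyper)
  if (fit$fixed$omega) nm <- setdiff(nm, "omega")
  if (fit$fixed$species) nm <- character(0)
  vals <- vapply(nm, function(p) {
    tr <- vapply(fit$chains, function(ch) ch$hyper[, p],
                 numeric(nrow(fit$chains[[1]]$hyper)))
    gelman_rubin(tr)$rhat
  }, numeric(1))
  if (include_species && !fit$fixed$species) {
    nms <- colnames(fit$chains[[1]]$theta)
    sv <- vapply(nms, function(p) {
      tr <- vapply(fit$chains, function(ch) ch$theta[, p],
                   numeric(nrow(fit$chains[[1]]$theta)))
      gelman_rubin(tr)$rhat
    }, numeric(1))
    vals <- c(vals, sv)
  }
  vals
}
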