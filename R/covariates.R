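#' Standardize a covariate
#'
#' Centres and scales values as `(x - mean) / sd`. Missing entries pass
#' through as missing. The (mean, sd) pair may be the sample moments or a
#' fixed pair injected for exact replication of a published analysis.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param mean,sd Standardization moments; `sd` must be > 0.
#' @return Standardized numeric vector.
#' @examples
#' standardize_covariate(c(202, NA), mean = 193.2, sd = 8.8)
#' @export
standardize_covariate <- function(values, mean, sd) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd <= 0)
    stop_invalid("sd must be a single positive number")
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean))
    stop_invalid("mean must be a single number")
  (values - mean) / sd
}

#' Standardization moments of the garden-survey covariates
#'
#' The published (mean, SD) pairs for the seven site and survey covariates,
#' usable to standardize new data on exactly the study's scale.
#'
#' @return Data frame with columns `covariate`, `type` (`"site"` or
#'   `"survey"`), `mean`, `sd`.
#' @export
study_moments <- function() {
  data.frame(
    covariate = c("urban_dist", "garden_area", "start_time", "julian_date",
                  "temperature", "light", "bloom_richness"),
    type = c("site", "site", "survey", "survey", "survey", "survey", "survey"),
    mean = c(15124.1, 464.7, 12.9, 193.2, 32.4, 42160.6, 19.6),
    sd = c(12355.9, 430.7, 1.9, 8.8, 5.0, 25340.9, 8.5),
    stringsAsFactors = FALSE)
}

site_covariate_names <- function() c("urban_dist", "garden_area")
survey_covariate_names <- function()
  c("start_time", "julian_date", "temperature", "light", "bloom_richness")

#' Site-level covariates
#'
#' Stores raw and standardized site covariates (one row per site). By
#' default moments are the sample moments of the supplied values; a fixed
#' moments table (as from [study_moments()]) can be injected instead.
#'
#' @param data Data frame with one row per site and numeric covariate
#'   columns (any subset of `urban_dist`, `garden_area`, or others).
#' @param moments Optional data frame `covariate, mean, sd`.
#' @return Object of class `site_covariates` with `raw`, `std` (both data
#'   frames) and `moments`.
#' @export
site_covariates <- function(data, moments = NULL) {
  data <- as.data.frame(data)
  vars <- names(data)
  mom <- resolve_moments(data, vars, moments)
  std <- data
  for (v in vars) {
    m <- mom[mom$covariate == v, ]
    std[[v]] <- standardize_covariate(data[[v]], m$mean, m$sd)
  }
  structure(list(raw = data, std = std, moments = mom),
            class = "site_covariates")
}

resolve_moments <- function(values_by_var, vars, moments) {
  rows <- lapply(vars, function(v) {
    x <- if (is.data.frame(values_by_var)) values_by_var[[v]]
         else values_by_var[[v]]
    if (!is.null(moments) && v %in% moments$covariate) {
      m <- moments[moments$covariate == v, , drop = FALSE]
      data.frame(covariate = v, mean = m$mean[1], sd = m$sd[1])
    } else {
      x <- as.numeric(x)
      s <- sd(x, na.rm = TRUE)
      if (!is.finite(s) || s <= 0)
        stop_invalid("covariate '", v, "' is constant; cannot standardize")
      data.frame(covariate = v, mean = mean(x, na.rm = TRUE), sd = s)
    }
  })
  do.call(rbind, rows)
}

#' Survey-level covariates on the (site, slot) grid
#'
#' Stores raw and standardized survey covariates as J x K matrices aligned
#' with a [study_layout]. Slots missing from the layout carry the fill
#' value 0 on the standardized scale (the standardized mean); such cells
#' are flagged by the layout mask and never enter the likelihood.
#'
#' @param vars Named list of J x K numeric matrices (raw scale); values at
#'   layout-missing slots may be `NA`.
#' @param layout A [study_layout].
#' @param moments Optional moments table (`covariate, mean, sd`); defaults
#'   to sample moments over surveyed cells.
#' @return Object of class `survey_covariates` with `raw`, `std`,
#'   `moments`, `layout`.
#' @export
survey_covariates <- function(vars, layout, moments = NULL) {
  stopifnot(inherits(layout, "study_layout"), is.list(vars))
  if (is.null(names(vars)) || any(names(vars) == ""))
    stop_invalid("vars must be a named list of matrices")
  J <- layout$n_sites; K <- layout$n_slots
  raw <- lapply(vars, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(J, K)))
      stop_invalid("survey covariate matrices must be ", J, " x ", K)
    m[!layout$mask] <- NA_real_
    m
  })
  obs_values <- lapply(raw, function(m) m[layout$mask])
  mom <- resolve_moments(obs_values, names(raw), moments)
  std <- lapply(names(raw), function(v) {
    m <- mom[mom$covariate == v, ]
    s <- standardize_covariate(raw[[v]], m$mean, m$sd)
    s[!layout$mask] <- 0  # fill value at structurally missing slots
    s
  })
  names(std) <- names(raw)
  structure(list(raw = raw, std = std, moments = mom, layout = layout),
            class = "survey_covariates")
}

#' Screen covariate pairs for collinearity
#'
#' Computes pairwise Pearson correlations on pairwise-complete observations
#' and reports every unordered pair at or above the exclusion threshold;
#' such pairs should not be entered in the same model. A constant covariate
#' yields an undefined correlation, reported with a warning but not
#' excluded.
#'
#' @param covariates Data frame or matrix of numeric covariate columns
#'   (>= 2 columns).
#' @param threshold Absolute-correlation exclusion threshold, inclusive
#'   (default 0.6).
#' @return Data frame with columns `var1`, `var2`, `r`, `excluded`;
#'   one row per unordered pair.
#' @examples
#' correlation_screen(data.frame(a = 1:10, b = (1:10) * 2, c = rnorm(10)))
#' @export
correlation_screen <- function(covariates, threshold = 0.6) {
  x <- as.data.frame(covariates)
  vars <- names(x)
  if (length(vars) < 2L) stop_invalid("need at least two covariates")
  pairs <- utils::combn(vars, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    pr <- pairs[, p]
    a <- as.numeric(x[[pr[1]]]); b <- as.numeric(x[[pr[2]]])
    ok <- complete.cases(a, b)
    if (sum(ok) < 3L)
      stop_invalid("pair (", pr[1], ", ", pr[2],
                   ") has fewer than 3 complete observations")
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      warning("undefined correlation for pair (", pr[1], ", ", pr[2],
              "): constant covariate", call. = FALSE)
      r <- NA_real_
    } else {
      r <- cor(a[ok], b[ok])
    }
    data.frame(var1 = pr[1], var2 = pr[2], r = r,
               excluded = !is.na(r) && abs(r) >= threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read site / survey covariate CSV files
#'
#' Site covariates: one row per site with a `site` column plus covariate
#' columns. Survey covariates: keyed by (`site`, `slot`) with covariate
#' columns; cells absent from the file or empty are missing.
#'
#' @param path CSV path.
#' @param layout A [study_layout] (survey covariates only).
#' @param moments Optional moments table passed through.
#' @return A [site_covariates] or [survey_covariates] object.
#' @export
read_site_covariates <- function(path, moments = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df <- df[order(df$site), , drop = FALSE]
  site_covariates(df[setdiff(names(df), "site")], moments = moments)
}

#' @rdname read_site_covariates
#' @export
read_survey_covariates <- function(path, layout, moments = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  vars <- setdiff(names(df), c("site", "slot"))
  J <- layout$n_sites; K <- layout$n_slots
  mats <- lapply(vars, function(v) {
    m <- matrix(NA_real_, J, K)
    m[cbind(as.integer(df$site), as.integer(df$slot))] <- as.numeric(df[[v]])
    m
  })
  names(mats) <- vars
  survey_covariates(mats, layout, moments = moments)
}

#' Write survey covariates as long-format CSV
#'
#' @param covs A [survey_covariates] object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_covariates <- function(covs, path) {
  lay <- covs$layout
  cells <- which(lay$mask, arr.ind = TRUE)
  df <- data.frame(site = cells[, 1], slot = cells[, 2])
  for (v in names(covs$raw)) df[[v]] <- covs$raw[[v]][cells]
  df <- df[order(df$site, df$slot), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
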