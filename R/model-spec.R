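canonical_covariates <- function() {
  c("plant", "start_time", "julian_date", "temperature", "light",
    "bloom_richness", "urban_dist", "garden_area")
}

covariate_aliases <- function() {
  c(time = "start_time", jday = "julian_date", julian = "julian_date",
    temp = "temperature", bloom = "bloom_richness", urban = "urban_dist",
    light_level = "light", plant_species = "plant", area = "garden_area")
}

apply_aliases <- function(s) {
  al <- covariate_aliases()
  for (k in names(al))
    s <- gsub(paste0("\\b", k, "\\b"), al[[k]], s, perl = TRUE)
  s
}

# canonical form of a single term label (alias substitution + fixed
# variable order inside interactions)
normalize_term <- function(label) {
  label <- apply_aliases(trimws(label))
  if (grepl(":", label, fixed = TRUE)) {
    vs <- strsplit(label, ":", fixed = TRUE)[[1]]
    vs <- vs[order(match(vs, canonical_covariates()))]
    label <- paste(vs, collapse = ":")
  }
  label
}

term_vars <- function(label) {
  # variables a term label depends on: "a:b" -> a, b ; "I(a^2)" -> a
  if (grepl("^I\\(", label)) {
    sub("^I\\(([^^]+)\\^2\\)$", "\\1", label)
  } else {
    strsplit(label, ":", fixed = TRUE)[[1]]
  }
}

parse_side <- function(rhs) {
  rhs <- apply_aliases(rhs)
  f <- as.formula(paste("~", rhs))
  tt <- terms(f, keep.order = FALSE)
  labels <- attr(tt, "term.labels")
  # normalize interaction labels to a fixed variable order
  vapply(labels, function(l) {
    if (grepl(":", l, fixed = TRUE)) {
      vs <- strsplit(l, ":", fixed = TRUE)[[1]]
      ord <- order(match(vs, canonical_covariates()))
      paste(vs[ord], collapse = ":")
    } else l
  }, character(1), USE.NAMES = FALSE)
}

#' Specify the occupancy and detection sub-models
#'
#' A `model_spec` declares which covariate terms enter the occupancy
#' (site-level) and detection (survey-level) linear predictors on the logit
#' scale. Terms are named by covariate: `urban_dist`, `garden_area` (site);
#' `start_time`, `julian_date`, `temperature`, `light`, `bloom_richness`
#' (survey); `plant` is the binary plant-species indicator (0 =
#' *P. muticum*, 1 = *L. spicata*). Interactions use `:` or `*`, quadratics
#' `I(x^2)`. The plant main effect is always part of the detection
#' sub-model and is added automatically if omitted. A formula string such
#' as `"psi ~ 1, p ~ (plant * start_time) + (urban_dist * julian_date) +
#' light"` can be parsed with [parse_model_formula()].
#'
#' @param occupancy Right-hand side of the occupancy sub-model as a string,
#'   `"1"` for intercept-only (the default). Only site covariates allowed.
#' @param detection Right-hand side of the detection sub-model; `"plant"`
#'   at minimum.
#' @param screen Optional output of [correlation_screen()]; excluded pairs
#'   may not co-occur in a sub-model.
#' @return Object of class `model_spec` with character vectors `occupancy`
#'   (term labels, empty = intercept-only) and `detection` (term labels
#'   excluding the structural plant main effect).
#' @examples
#' model_spec(detection = "plant * start_time + light")
#' @export
model_spec <- function(occupancy = "1", detection = "plant", screen = NULL) {
  occ <- parse_side(occupancy)
  det <- parse_side(detection)
  if (!"plant" %in% det) det <- c("plant", det)
  bad_occ <- setdiff(unlist(lapply(occ, term_vars)),
                     c("urban_dist", "garden_area"))
  if (length(bad_occ))
    stop_invalid("occupancy sub-model may only use site covariates; got: ",
                 paste(unique(bad_occ), collapse = ", "))
  all_det_vars <- unlist(lapply(det, term_vars))
  bad_det <- setdiff(all_det_vars, canonical_covariates())
  if (length(bad_det))
    stop_invalid("unknown detection covariate(s): ",
                 paste(unique(bad_det), collapse = ", "))
  check_hierarchy <- function(labels, side) {
    mains <- labels[!grepl("[:^]", labels)]
    for (l in labels) {
      if (grepl(":", l, fixed = TRUE)) {
        vs <- term_vars(l)
        if (!all(vs %in% mains))
          stop_invalid("interaction ", l, " in ", side,
                       " requires both main effects")
      }
      if (grepl("^I\\(", l) && !term_vars(l) %in% mains)
        stop_invalid("quadratic ", l, " in ", side,
                     " requires its linear term")
    }
  }
  check_hierarchy(occ, "occupancy")
  check_hierarchy(det, "detection")
  if (!is.null(screen)) {
    excl <- screen[screen$excluded, , drop = FALSE]
    for (labels in list(unique(unlist(lapply(occ, term_vars))),
                        unique(all_det_vars))) {
      for (r in seq_len(nrow(excl))) {
        if (all(c(excl$var1[r], excl$var2[r]) %in% labels))
          stop_invalid("covariates ", excl$var1[r], " and ", excl$var2[r],
                       " are excluded as collinear (|r| >= threshold) and ",
                       "may not co-occur")
      }
    }
  }
  structure(list(occupancy = occ, detection = setdiff(det, "plant")),
            class = "model_spec")
}

#' Parse a combined occupancy/detection formula string
#'
#' @param x String of the form `"psi ~ <terms>, p ~ <terms>"`.
#' @param screen Optional [correlation_screen()] output.
#' @return A [model_spec].
#' @examples
#' parse_model_formula(
#'   "psi ~ 1, p ~ (plant * start_time) + (urban_dist * julian_date) + light")
#' @export
parse_model_formula <- function(x, screen = NULL) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop_invalid("expected \"psi ~ ..., p ~ ...\"")
  get_rhs <- function(part, lhs) {
    part <- trimws(part)
    m <- regmatches(part, regexec(paste0("^", lhs, "\\s*~\\s*(.+)$"), part))[[1]]
    if (length(m) != 2L)
      stop_invalid("could not parse \"", part, "\" as ", lhs, " ~ ...")
    m[2]
  }
  model_spec(occupancy = get_rhs(parts[1], "psi"),
             detection = get_rhs(parts[2], "p"))
}

#' @export
print.model_spec <- function(x, ...) {
  occ <- if (length(x$occupancy)) paste(x$occupancy, collapse = " + ") else "1"
  det <- paste(c("plant", x$detection), collapse = " + ")
  cat("psi ~", occ, "\np   ~", det, "\n")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  occ <- if (length(x$occupancy)) paste(x$occupancy, collapse = " + ") else "1"
  paste0("psi ~ ", occ, ", p ~ ",
         paste(c("plant", x$detection), collapse = " + "))
}

# --- design matrices ---------------------------------------------------

layout_cells <- function(layout) {
  cells <- which(layout$mask, arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  dimnames(cells) <- NULL
  cells
}

eval_term_matrix <- function(label, env) {
  # env: named list of J x K matrices (standardized scale)
  vs <- term_vars(label)
  miss <- setdiff(vs, names(env))
  if (length(miss))
    stop_invalid("covariate '", miss[1], "' named in the model but absent ",
                 "from the supplied covariates")
  if (grepl("^I\\(", label)) return(env[[vs]]^2)
  Reduce(`*`, env[vs])
}

covariate_env <- function(layout, site_covs = NULL, survey_covs = NULL) {
  J <- layout$n_sites; K <- layout$n_slots
  env <- list()
  plant <- layout$plant
  plant[!layout$mask] <- 0
  env$plant <- plant
  if (!is.null(survey_covs)) {
    stopifnot(inherits(survey_covs, "survey_covariates"))
    env <- c(env, survey_covs$std)
  }
  if (!is.null(site_covs)) {
    stopifnot(inherits(site_covs, "site_covariates"))
    for (v in names(site_covs$std))
      env[[v]] <- matrix(site_covs$std[[v]], J, K)
  }
  env
}

# Occupancy design: J x (1 + Q); col 1 = intercept
occupancy_design <- function(spec, layout, site_covs = NULL) {
  J <- layout$n_sites
  X <- matrix(1, J, 1L)
  colnames(X) <- "psi_int"
  for (l in spec$occupancy) {
    vs <- term_vars(l)
    miss <- setdiff(vs, names(site_covs$std %||% list()))
    if (length(miss))
      stop_invalid("site covariate '", miss[1],
                   "' named in the model but absent")
    col <- if (grepl("^I\\(", l)) site_covs$std[[vs]]^2
           else Reduce(`*`, lapply(vs, function(v) site_covs$std[[v]]))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0("psi_", l)
  }
  X
}

# Detection design on surveyed cells: ncell x (2 + P);
# cols: intercept, plant, then spec$detection terms
detection_design <- function(spec, layout, site_covs = NULL,
                             survey_covs = NULL) {
  cells <- layout_cells(layout)
  env <- covariate_env(layout, site_covs, survey_covs)
  n <- nrow(cells)
  X <- matrix(0, n, 2L + length(spec$detection))
  X[, 1L] <- 1
  X[, 2L] <- env$plant[cells]
  cn <- c("p_int", "p_plant")
  for (idx in seq_along(spec$detection)) {
    l <- spec$detection[idx]
    X[, 2L + idx] <- eval_term_matrix(l, env)[cells]
    cn <- c(cn, paste0("p_", l))
  }
  colnames(X) <- cn
  list(X = X, cells = cells)
}

# Full parameter registry for a spec: species-level column names and the
# prior class of each column (intercept / coefficient / plant)
param_registry <- function(spec) {
  cols <- c("psi_int",
            if (length(spec$occupancy)) paste0("psi_", spec$occupancy),
            "p_int", "p_plant",
            if (length(spec$detection)) paste0("p_", spec$detection))
  type <- c("intercept",
            rep("coefficient", length(spec$occupancy)),
            "intercept", "plant",
            rep("coefficient", length(spec$detection)))
  n_occ <- 1L + length(spec$occupancy)
  list(cols = cols, type = type, n_occ = n_occ,
       n_det = length(cols) - n_occ)
}
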