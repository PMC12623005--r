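#' Survey layout: sites, plants, and replicate slots
#'
#' A `study_layout` describes which plant species were surveyed at each
#' site and how replicate observation slots map onto plants. Each site has
#' `replicates_per_plant` slots per plant surveyed there. Slots are indexed
#' so that at a site with both plants, slots `1..r` are *P. muticum* and
#' slots `r+1..2r` are *L. spicata*; single-plant sites use slots `1..r`
#' and the remaining slots are structurally missing. The plant indicator is
#' 0 for *P. muticum* and 1 for *L. spicata*.
#'
#' @param availability Character vector, one entry per site, each one of
#'   `"both"`, `"pm_only"`, `"ls_only"`.
#' @param replicates_per_plant Number of replicate inflorescences monitored
#'   per plant per site (default 5).
#' @return An object of class `study_layout` with fields `n_sites`,
#'   `availability`, `replicates_per_plant`, `n_slots` (array depth K),
#'   `mask` (J x K logical, `TRUE` = surveyed) and `plant` (J x K numeric,
#'   0/1 on surveyed slots, `NA` on missing slots).
#' @examples
#' lay <- study_layout(c("both", "pm_only", "ls_only"))
#' sum(lay$mask)  # 20 surveyed slots
#' @export
study_layout <- function(availability, replicates_per_plant = 5L) {
  availability <- as.character(availability)
  bad <- setdiff(unique(availability), c("both", "pm_only", "ls_only"))
  if (length(bad))
    stop_invalid("unknown plant availability class(es): ",
                 paste(bad, collapse = ", "))
  r <- as.integer(replicates_per_plant)
  if (r < 1L) stop_invalid("replicates_per_plant must be >= 1")
  J <- length(availability)
  if (J < 1L) stop_invalid("layout needs at least one site")
  K <- 2L * r
  mask <- matrix(FALSE, J, K)
  plant <- matrix(NA_real_, J, K)
  for (j in seq_len(J)) {
    switch(availability[j],
      both = {
        mask[j, ] <- TRUE
        plant[j, seq_len(r)] <- 0
        plant[j, r + seq_len(r)] <- 1
      },
      pm_only = {
        mask[j, seq_len(r)] <- TRUE
        plant[j, seq_len(r)] <- 0
      },
      ls_only = {
        mask[j, seq_len(r)] <- TRUE
        plant[j, seq_len(r)] <- 1
      })
  }
  structure(
    list(n_sites = J, availability = availability,
         replicates_per_plant = r, n_slots = K,
         mask = mask, plant = plant),
    class = "study_layout")
}

#' The garden-survey layout of the motivating study
#'
#' Fifty sites: 20 with both focal plants, 20 with *P. muticum* only and 10
#' with *L. spicata* only, five replicate inflorescences per plant per site,
#' giving 350 surveyed replicate slots in all.
#'
#' @return A [study_layout] with 50 sites and 10 replicate slots.
#' @examples
#' lay <- garden_layout()
#' sum(lay$mask)  # 350
#' @export
garden_layout <- function() {
  study_layout(rep(c("both", "pm_only", "ls_only"), times = c(20L, 20L, 10L)),
               replicates_per_plant = 5L)
}

#' @export
print.study_layout <- function(x, ...) {
  cat("study_layout:", x$n_sites, "sites,",
      x$replicates_per_plant, "replicates per plant,",
      sum(x$mask), "surveyed slots\n")
  print(table(x$availability))
  invisible(x)
}

#' Count surveyed replicate slots in a layout
#'
#' @param layout A [study_layout].
#' @return Integer: total number of non-missing (site, slot) cells.
#' @export
n_surveyed_slots <- function(layout) {
  stopifnot(inherits(layout, "study_layout"))
  sum(layout$mask)
}
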