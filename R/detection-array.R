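#' Assemble a taxa x sites x slots detection array
#'
#' Builds the binary detection array `y[i, j, k]` from long-format
#' detection-event records. Cells surveyed under the layout but with no
#' matching record are 0; cells absent from the layout (the plant was not
#' surveyed at that site) are `NA`, and the missing pattern is identical
#' across taxa. Duplicate records for the same (taxon, site, slot) collapse
#' to a single 1 with a warning, since the response is detection /
#' non-detection.
#'
#' @param records A data frame with columns `site` (integer site index),
#'   `slot` (integer replicate slot), `taxon` (character), `detected` (0/1).
#'   An optional `plant` column (`"PM"`/`"LS"`) is cross-checked against the
#'   layout. May have zero rows.
#' @param layout A [study_layout].
#' @param taxa Character vector of taxon labels (the registry); records may
#'   only reference these.
#' @return A `detection_array`: list with `y` (M x J x K array, `NA` =
#'   missing), `taxa`, `n_observed`, `n_augmented` (0 here), and `layout`.
#' @export
assemble_detection_array <- function(records, layout, taxa) {
  stopifnot(inherits(layout, "study_layout"))
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop_invalid("duplicate taxon labels in registry")
  M <- length(taxa)
  J <- layout$n_sites
  K <- layout$n_slots
  y <- array(0L, dim = c(M, J, K), dimnames = list(taxon = taxa, NULL, NULL))
  na_cells <- which(!layout$mask, arr.ind = TRUE)
  for (i in seq_len(M))
    if (nrow(na_cells))
      y[cbind(i, na_cells)] <- NA_integer_
  if (nrow(records)) {
    req <- c("site", "slot", "taxon", "detected")
    if (!all(req %in% names(records)))
      stop_invalid("records must have columns: ", paste(req, collapse = ", "))
    site <- as.integer(records$site)
    slot <- as.integer(records$slot)
    tx <- match(as.character(records$taxon), taxa)
    det <- as.integer(records$detected)
    if (anyNA(tx))
      stop_invalid("records reference unknown taxa: ",
                   paste(unique(records$taxon[is.na(tx)]), collapse = ", "))
    if (any(site < 1L | site > J | slot < 1L | slot > K, na.rm = TRUE) ||
        anyNA(site) || anyNA(slot))
      stop_invalid("record site/slot indices outside the layout")
    if (!all(det %in% c(0L, 1L)))
      stop_invalid("detected must be 0 or 1")
    absent <- !layout$mask[cbind(site, slot)]
    if (any(absent))
      stop_invalid("record(s) address slot(s) not surveyed under the layout ",
                   "(e.g., site ", site[which(absent)[1]], " slot ",
                   slot[which(absent)[1]], ")")
    if ("plant" %in% names(records)) {
      want <- ifelse(layout$plant[cbind(site, slot)] == 1, "LS", "PM")
      got <- toupper(as.character(records$plant))
      if (any(got != want))
        stop_invalid("record plant labels disagree with the layout")
    }
    hit <- det == 1L
    if (any(hit)) {
      idx <- cbind(tx[hit], site[hit], slot[hit])
      if (anyDuplicated(idx))
        warning("duplicate detection records collapsed to single detections")
      y[idx] <- 1L
    }
  }
  new_detection_array(y, taxa, n_observed = M, n_augmented = 0L,
                      layout = layout)
}

new_detection_array <- function(y, taxa, n_observed, n_augmented, layout) {
  out <- structure(
    list(y = y, taxa = taxa, n_observed = as.integer(n_observed),
         n_augmented = as.integer(n_augmented), layout = layout),
    class = "detection_array")
  validate_detection_array(out)
  out
}

#' Validate the structural invariants of a detection array
#'
#' Checks that values are 0/1 on surveyed cells, that the missing pattern
#' matches the layout identically for every taxon slice, and that augmented
#' slices are all-zero where surveyed.
#'
#' @param x A `detection_array`.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_detection_array <- function(x) {
  stopifnot(inherits(x, "detection_array"))
  y <- x$y
  M <- dim(y)[1]
  if (M != x$n_observed + x$n_augmented)
    stop_invalid("taxon count does not equal observed + augmented")
  if (length(x$taxa) != M) stop_invalid("taxon labels do not match array")
  mask <- x$layout$mask
  for (i in seq_len(M)) {
    sl <- taxon_slice(y, i)
    if (!identical(unname(is.na(sl)), unname(!mask)))
      stop_invalid("missing pattern of taxon slice ", i,
                   " differs from the layout")
    v <- sl[mask]
    if (!all(v %in% c(0L, 1L)))
      stop_invalid("non-binary detection values for taxon ", i)
    if (i > x$n_observed && any(v != 0L))
      stop_invalid("augmented taxon slice ", i, " has nonzero detections")
  }
  invisible(x)
}

#' Augment a detection array with all-zero detection histories
#'
#' Appends `n_aug` hypothetical taxa that were never detected, so the model
#' can estimate how many taxa escaped detection entirely. The missing-data
#' pattern of the surveyed layout is propagated into the augmented slices:
#' a slot not surveyed for the observed taxa is `NA` for the augmented taxa
#' too.
#'
#' @param array A `detection_array`.
#' @param n_aug Number of all-zero taxa to append (>= 0).
#' @param labels Optional labels for augmented taxa; default `"aug1"`, ...
#' @return A `detection_array` with `n_observed + n_aug` taxa.
#' @examples
#' lay <- study_layout(c("both", "pm_only"))
#' arr <- assemble_detection_array(
#'   data.frame(site = 1, slot = 1, taxon = "A", detected = 1), lay, "A")
#' dim(augment_detection_array(arr, 3)$y)[1]  # 4
#' @export
augment_detection_array <- function(array, n_aug, labels = NULL) {
  stopifnot(inherits(array, "detection_array"))
  n_aug <- as.integer(n_aug)
  if (n_aug < 0L) stop_invalid("n_aug must be >= 0")
  if (n_aug == 0L) return(array)
  J <- dim(array$y)[2]; K <- dim(array$y)[3]
  labels <- labels %||% paste0("aug", seq_len(n_aug) + array$n_augmented)
  if (length(labels) != n_aug) stop_invalid("need one label per augmented taxon")
  zero <- matrix(0L, J, K)
  zero[!array$layout$mask] <- NA_integer_
  M0 <- dim(array$y)[1]
  y <- array(NA_integer_, dim = c(M0 + n_aug, J, K))
  y[seq_len(M0), , ] <- array$y
  for (i in seq_len(n_aug)) y[M0 + i, , ] <- zero
  taxa <- c(array$taxa, labels)
  dimnames(y) <- list(taxon = taxa, NULL, NULL)
  new_detection_array(y, taxa, n_observed = array$n_observed,
                      n_augmented = array$n_augmented + n_aug,
                      layout = array$layout)
}

#' @export
print.detection_array <- function(x, ...) {
  d <- dim(x$y)
  cat("detection_array:", d[1], "taxa (", x$n_observed, "observed +",
      x$n_augmented, "augmented ) x", d[2], "sites x", d[3], "slots\n")
  cat("  surveyed cells per taxon:", sum(x$layout$mask),
      "; detections:", sum(x$y == 1L, na.rm = TRUE), "\n")
  invisible(x)
}

#' Convert a detection array to long-format records
#'
#' One row per surveyed (taxon, site, slot) cell, suitable for
#' [write_detection_records()] and round-tripping through
#' [assemble_detection_array()]. Augmented slices are omitted (they carry
#' no data).
#'
#' @param array A `detection_array`.
#' @return Data frame with columns `site`, `slot`, `plant`, `taxon`,
#'   `detected`.
#' @export
detection_records <- function(array) {
  stopifnot(inherits(array, "detection_array"))
  lay <- array$layout
  cells <- which(lay$mask, arr.ind = TRUE)
  obs <- seq_len(array$n_observed)
  if (!length(obs))
    return(data.frame(site = integer(0), slot = integer(0),
                      plant = character(0), taxon = character(0),
                      detected = integer(0)))
  out <- do.call(rbind, lapply(obs, function(i) {
    data.frame(site = cells[, 1], slot = cells[, 2],
               plant = ifelse(lay$plant[cells] == 1, "LS", "PM"),
               taxon = array$taxa[i],
               detected = array$y[cbind(i, cells[, 1], cells[, 2])])
  }))
  out[order(out$taxon, out$site, out$slot), , drop = FALSE]
}

#' Write / read long-format detection records
#'
#' Plain CSV with columns `site, slot, plant, taxon, detected`; empty
#' strings are read as missing.
#'
#' @param array A `detection_array`.
#' @param path File path.
#' @return `write_detection_records` returns `path` invisibly;
#'   `read_detection_records` returns a `detection_array`.
#' @export
write_detection_records <- function(array, path) {
  write.csv(detection_records(array), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_records
#' @param layout A [study_layout] describing the survey design.
#' @param taxa Optional taxon registry; defaults to the taxa present in the
#'   file, sorted.
#' @export
read_detection_records <- function(path, layout, taxa = NULL) {
  rec <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  taxa <- taxa %||% sort(unique(rec$taxon))
  assemble_detection_array(rec, layout, taxa)
}
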