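#' Inverse-logit (logistic) link
#'
#' Maps a logit-scale value to a probability, `1 / (1 + exp(-x))`.
#' Strictly increasing and antisymmetric: `inv_logit(-x) = 1 - inv_logit(x)`.
#'
#' @param x Numeric vector on the logit scale.
#' @return Probabilities in (0, 1).
#' @examples
#' inv_logit(0)      # 0.5
#' inv_logit(-1.37)  # ~0.20
#' @export
inv_logit <- function(x) {
  stopifnot(is.numeric(x))
  plogis(x)
}

#' Logit link
#'
#' @param p Probabilities in (0, 1).
#' @return Logit-scale values, `log(p / (1 - p))`.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  qlogis(p)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# J x K matrix slice of a taxa-first 3-D array (robust to dropped dims)
taxon_slice <- function(y, i) {
  matrix(y[i, , ], dim(y)[2], dim(y)[3])
}
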