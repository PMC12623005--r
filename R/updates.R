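# Reference R implementations of the closed-form full-conditional
# updates used by the sampler. The C++ kernel mirrors these; the exact
# enumeration oracle validates both.

#' Full conditional probability of site occupancy
#'
#' Probability that `z = 1` for one (taxon, site) given supercommunity
#' membership `w`, occupancy probability `psi`, per-slot detection
#' probabilities and observations at the site's surveyed slots. A
#' detection forces `z = 1`; `w = 0` forces `z = 0`; otherwise Bayes'
#' rule on the all-zero detection history:
#' `psi * prod(1 - p) / (psi * prod(1 - p) + 1 - psi)`.
#'
#' @param w Binary membership indicator.
#' @param psi Occupancy probability.
#' @param p Detection probabilities over the site's surveyed slots.
#' @param y Observations (0/1) at those slots.
#' @return `Pr(z = 1 | ...)`.
#' @export
cond_prob_z <- function(w, psi, p, y) {
  stopifnot(w %in% c(0, 1), length(p) == length(y))
  if (any(y == 1)) return(1)
  if (w == 0) return(0)
  num <- psi * prod(1 - p)
  num / (num + 1 - psi)
}

#' Full conditional probability of supercommunity membership
#'
#' Probability that `w = 1` for one taxon given its site occupancy states
#' and occupancy probabilities. Any occupied site forces `w = 1`;
#' otherwise `omega * prod_j(1 - psi_j) / (omega * prod_j(1 - psi_j) +
#' 1 - omega)`.
#'
#' @param omega Supercommunity inclusion probability.
#' @param psi Occupancy probabilities over sites.
#' @param z Binary occupancy states over sites.
#' @return `Pr(w = 1 | ...)`.
#' @export
cond_prob_w <- function(omega, psi, z) {
  stopifnot(length(psi) == length(z))
  if (any(z == 1)) return(1)
  num <- omega * prod(1 - psi)
  num / (num + 1 - omega)
}

#' Conjugate draw of the supercommunity inclusion probability
#'
#' With a Beta(a, b) prior and `M` Bernoulli membership indicators, the
#' full conditional is `Beta(a + sum(w), b + M - sum(w))`.
#'
#' @param w Binary membership vector (length M >= 1).
#' @param shape1,shape2 Beta prior shapes.
#' @return One draw; the conditional shapes are attached as attributes
#'   `shape1` and `shape2`.
#' @export
draw_omega <- function(w, shape1 = 0.001, shape2 = 1) {
  stopifnot(length(w) >= 1, all(w %in% c(0, 1)))
  a <- shape1 + sum(w)
  b <- shape2 + length(w) - sum(w)
  structure(rbeta(1, a, b), shape1 = a, shape2 = b)
}
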