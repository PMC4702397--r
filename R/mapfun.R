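#' Kosambi mapping function
#'
#' Convert a meiotic recombination fraction to a map distance in centiMorgans
#' using the Kosambi mapping function, d = 25 ln((1+2r)/(1-2r)), which allows
#' for partial crossover interference.
#'
#' @param r Numeric vector of meiotic recombination fractions in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @seealso [kosambi_r()] for the inverse, [ril_rf_expand()] for the
#'   selfing-RIL correction applied before distances are computed.
#' @examples
#' kosambi_d(0.25)  # 25 * log(3) ~ 27.47 cM
#' @export
kosambi_d <- function(r) {
  stopifnot(is.numeric(r), all(is.na(r) | (r >= 0 & r < 0.5)))
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' @param d Map distance(s) in cM, non-negative.
#' @return Meiotic recombination fraction(s), r = tanh(2d/100)/2.
#' @export
kosambi_r <- function(d) {
  stopifnot(is.numeric(d), all(is.na(d) | d >= 0))
  0.5 * tanh(2 * d / 100)
}

#' Haldane map distance from a recombination fraction
#'
#' No-interference (Poisson crossover) mapping function,
#' d = -50 ln(1 - 2r).  Used by the cross simulator to place marker pairs at
#' an exact meiotic recombination fraction.
#'
#' @param r Meiotic recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
haldane_d <- function(r) {
  stopifnot(is.numeric(r), all(is.na(r) | (r >= 0 & r < 0.5)))
  -50 * log(1 - 2 * r)
}

#' Expected RIL recombinant fraction from a meiotic fraction
#'
#' For recombinant inbred lines produced by repeated selfing, recombinant
#' haplotypes accumulate over the generations, so the observed fraction of
#' recombinant lines R exceeds the per-meiosis fraction r.  At the selfing
#' limit the Haldane-Waddington relation holds: R = 2r/(1+2r).
#'
#' @param r Meiotic recombination fraction(s) in `[0, 0.5]`.
#' @return Expected observed RIL recombinant fraction(s).
#' @export
ril_rf_expand <- function(r) {
  stopifnot(is.numeric(r), all(is.na(r) | (r >= 0 & r <= 0.5)))
  2 * r / (1 + 2 * r)
}

#' Meiotic recombination fraction from an observed RIL fraction
#'
#' Inverts the Haldane-Waddington relation: r = R/(2(1-R)).  Applied to
#' two-point estimates from RIL genotypes before the Kosambi function is
#' used, mirroring the population-type correction linkage-mapping software
#' applies internally.
#'
#' @param R Observed RIL recombinant fraction(s) in `[0, 2/3]`.
#' @return Meiotic recombination fraction(s).
#' @export
ril_rf_shrink <- function(R) {
  stopifnot(is.numeric(R), all(is.na(R) | (R >= 0 & R <= 1)))
  pmin(R / (2 * (1 - R)), 0.5)
}
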