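#' Kosambi mapping function
#'
#' Converts a recombination fraction to a Kosambi map distance,
#' \eqn{d = 25 \ln((1+2r)/(1-2r))} centimorgans, and back,
#' \eqn{r = \tanh(d/50)/2}. The Kosambi function allows for moderate
#' crossover interference and is the distance used throughout the package.
#'
#' @param r recombination fraction(s) in \code{[0, 0.5)}.
#' @param d map distance(s) in centimorgans, \code{>= 0}.
#' @return \code{kosambiCM}: distances in cM; \code{inverseKosambi}:
#'   recombination fractions.
#' @examples
#' kosambiCM(0.2)            # 21.18 cM
#' inverseKosambi(kosambiCM(0.3))
#' @export
kosambiCM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambiCM
#' @export
inverseKosambi <- function(d) {
  if (any(d < 0)) stop("d must be >= 0")
  0.5 * tanh(d / 50)
}
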