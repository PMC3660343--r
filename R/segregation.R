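#' Chi-square test of Mendelian segregation
#'
#' Tests each marker's observed genotype-class frequencies against the
#' Mendelian expectation of its segregation type (1:1 for lmxll and nnxnp,
#' 1:2:1 for hkxhk, 1:1:1:1 for efxeg and abxcd), the "locus genotype
#' frequency" check applied before map construction. Missing genotypes are
#' excluded from the counts.
#'
#' @param gt a \linkS4class{CPGenotypes} object.
#' @param markers optional marker ids to test (default: all).
#' @return data.frame with columns \code{marker_id}, \code{chi2}, \code{df},
#'   \code{p}.
#' @examples
#' gt <- simulateCPFamily(simulateTrueGenome(simConfig(nLgs = 2L,
#'   markersPerLg = 4L)), simConfig(nLgs = 2L, markersPerLg = 4L))
#' head(segregationTest(gt))
#' @export
segregationTest <- function(gt, markers = NULL) {
  stopifnot(is(gt, "CPGenotypes"))
  ids <- if (is.null(markers)) markerIds(gt) else markers
  idx <- match(ids, markerIds(gt))
  if (anyNA(idx)) stop("unknown marker id: ", ids[is.na(idx)][1])
  out <- data.frame(marker_id = ids, chi2 = NA_real_, df = NA_integer_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    i <- idx[k]
    type <- gt@info$segregation_type[i]
    alpha <- .CP_ALPHABET[[type]]
    obs <- gt@codes[i, ]
    obs <- obs[obs != .MISSING_CODE]
    if (!length(obs))
      stop("marker ", ids[k], ": all genotypes missing, test undefined")
    counts <- table(factor(obs, levels = alpha))
    expd <- .CP_EXPECTED[[type]] * length(obs)
    chi2 <- sum((counts - expd)^2 / expd)
    df <- length(alpha) - 1L
    out$chi2[k] <- chi2
    out$df[k] <- df
    out$p[k] <- stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  out
}
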