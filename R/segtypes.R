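# Internal tables for the five CP segregation types.
#
# A CP (cross-pollinator style) full-sib family descends from two outbred
# parents; each marker falls into one of five segregation types named by the
# parental genotypes, e.g. "lmxll" = first parent lm, second parent ll.

.CP_TYPES <- c("lmxll", "nnxnp", "hkxhk", "efxeg", "abxcd")

.MISSING_CODE <- "--"

# Legal offspring genotype codes per type (alleles sorted alphabetically).
.CP_ALPHABET <- list(
  lmxll = c("ll", "lm"),
  nnxnp = c("nn", "np"),
  hkxhk = c("hh", "hk", "kk"),
  efxeg = c("ee", "ef", "eg", "fg"),
  abxcd = c("ac", "ad", "bc", "bd")
)

# Ordered parental allele pairs (phase 0 order).
.CP_PARENTS <- list(
  lmxll = list(p1 = c("l", "m"), p2 = c("l", "l")),
  nnxnp = list(p1 = c("n", "n"), p2 = c("n", "p")),
  hkxhk = list(p1 = c("h", "k"), p2 = c("h", "k")),
  efxeg = list(p1 = c("e", "f"), p2 = c("e", "g")),
  abxcd = list(p1 = c("a", "b"), p2 = c("c", "d"))
)

# Mendelian expected proportions over the alphabet, same order as .CP_ALPHABET.
.CP_EXPECTED <- list(
  lmxll = c(0.5, 0.5),
  nnxnp = c(0.5, 0.5),
  hkxhk = c(0.25, 0.5, 0.25),
  efxeg = c(0.25, 0.25, 0.25, 0.25),
  abxcd = c(0.25, 0.25, 0.25, 0.25)
)

.checkSegType <- function(type) {
  if (!all(type %in% .CP_TYPES)) {
    stop("unknown segregation type(s): ",
         paste(unique(setdiff(type, .CP_TYPES)), collapse = ", "))
  }
  invisible(type)
}

# Offspring code for one maternal + one paternal transmitted allele.
.offspringCode <- function(a1, a2) {
  ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
}
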