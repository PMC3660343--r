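# Shared builders and the independent brute-force oracle.

# Two-marker genotype table from raw code vectors.
mkPairGT <- function(codesA, codesB, typeA = "lmxll", typeB = "lmxll",
                     ids = c("A", "B")) {
  info <- data.frame(marker_id = ids, marker_type = "SSR",
                     segregation_type = c(typeA, typeB), phase = "--",
                     stringsAsFactors = FALSE)
  codes <- rbind(codesA, codesB)
  rownames(codes) <- ids
  new("CPGenotypes", familyName = "test", info = info, codes = codes)
}

# Independent grid-search oracle for the two-point MLE: enumerates the 16
# parental strand combinations per offspring class by brute force (no code
# shared with the package's EM engine; every combination carries a factor
# r or (1-r) per parent, counted as an exponent so the grid evaluation can
# be vectorized) and maximizes the log-likelihood over r on a fixed grid
# and over the four phase combinations. Returns list(rf, maximized loglik,
# flat = TRUE when the likelihood does not depend on r).
oracleRF <- function(codesA, codesB, typeA, typeB, step = 1e-4) {
  pars <- list(lmxll = list(c("l", "m"), c("l", "l")),
               nnxnp = list(c("n", "n"), c("n", "p")),
               hkxhk = list(c("h", "k"), c("h", "k")),
               efxeg = list(c("e", "f"), c("e", "g")),
               abxcd = list(c("a", "b"), c("c", "d")))
  pA <- pars[[typeA]]; pB <- pars[[typeB]]
  code <- function(x, y) paste0(min(x, y), max(x, y))
  ok <- codesA != "--" & codesB != "--"
  obs <- table(paste(codesA[ok], codesB[ok]))
  grid <- seq(0, 0.5, by = step)
  rk <- cbind((1 - grid)^2, grid * (1 - grid), grid^2)  # r-exponent 0,1,2
  best <- -Inf; bestr <- 0.5; flat <- TRUE
  for (ph1 in 0:1) for (ph2 in 0:1) {
    b1 <- if (ph1 == 1) rev(pB[[1]]) else pB[[1]]
    b2 <- if (ph2 == 1) rev(pB[[2]]) else pB[[2]]
    coefs <- list()
    for (s1A in 1:2) for (s1B in 1:2) for (s2A in 1:2) for (s2B in 1:2) {
      k <- (s1A != s1B) + (s2A != s2B)
      key <- paste(code(pA[[1]][s1A], pA[[2]][s2A]),
                   code(b1[s1B], b2[s2B]))
      if (is.null(coefs[[key]])) coefs[[key]] <- numeric(3)
      coefs[[key]][k + 1] <- coefs[[key]][k + 1] + 0.25
    }
    C <- do.call(rbind, coefs[names(obs)])     # nclass x 3
    P <- rk %*% t(C)                           # ngrid x nclass
    ll <- as.numeric(log(pmax(P, 1e-300)) %*% as.numeric(obs))
    if (max(ll) - min(ll) > 1e-9) flat <- FALSE
    i <- which.max(ll)
    if (ll[i] > best + 1e-12) { best <- ll[i]; bestr <- grid[i] }
  }
  list(rf = bestr, loglik = best, flat = flat)
}

# Small simulation settings used across tests (2 linkage groups keeps the
# homology invariant satisfiable).
tinySimConfig <- function(seed, ...) {
  simConfig(nLgs = 2L, markersPerLg = 6L, nContigs = 4L,
            nSingletonBacs = 2L, dupMarkerCount = 0L, seed = seed, ...)
}

# Rebuild a GeneticMap with evenly spaced markers from a per-group summary
# (marker counts and genetic lengths), for statistics that depend only on
# endpoints and counts.
gmapFromSummary <- function(lg_id, n_markers, length_cm) {
  rows <- do.call(rbind, lapply(seq_along(lg_id), function(i) {
    n <- n_markers[i]
    pos <- if (n == 1) 0 else seq(0, length_cm[i], length.out = n)
    data.frame(lg_id = lg_id[i],
               marker_id = sprintf("%s_M%02d", lg_id[i], seq_len(n)),
               position_cM = round(pos, 3), stringsAsFactors = FALSE)
  }))
  new("GeneticMap", lgs = rows,
      excluded = data.frame(marker_id = character(),
                            reason = character()))
}

# Order equality up to reversal.
sameOrder <- function(a, b) identical(a, b) || identical(a, rev(b))
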