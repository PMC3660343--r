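# Joint likelihood of a marker order for one linkage group.
#
# The transmitted parental strands along a group form, per parent, a
# two-state Markov chain whose switch probability between adjacent markers
# is that interval's recombination fraction. The observed genotype codes
# are emissions of the joint (maternal, paternal) strand state given each
# marker's segregation type and linkage phase; codes such as "hk" that do
# not identify the transmitting parent simply match several states. The
# forward algorithm gives the exact likelihood; a short EM (expected strand
# switches per interval via forward-backward) profiles out the interval
# recombination fractions. Used to score candidate window permutations in
# the final ordering ripple.

# Emission array for a group: n x 4 x m (individuals, joint strand states
# s = (s1-1)*2+s2, order positions). Missing codes match every state.
.emissionArray <- function(codes, types, phaseBits) {
  m <- nrow(codes); n <- ncol(codes)
  E <- array(0, dim = c(n, 4, m))
  for (j in seq_len(m)) {
    pa1 <- .CP_PARENTS[[types[j]]]$p1
    pa2 <- .CP_PARENTS[[types[j]]]$p2
    for (s1 in 1:2) for (s2 in 1:2) {
      a1 <- if (phaseBits[j, 1] == 1) pa1[3 - s1] else pa1[s1]
      a2 <- if (phaseBits[j, 2] == 1) pa2[3 - s2] else pa2[s2]
      code <- .offspringCode(a1, a2)
      E[, (s1 - 1) * 2 + s2, j] <-
        as.numeric(codes[j, ] == code | codes[j, ] == .MISSING_CODE)
    }
  }
  E
}

# Forward-backward loglik of one order with per-interval r profiled by EM.
# E: emission array from .emissionArray (already in ORIGINAL row order);
# ord: permutation of rows; rInit: initial per-interval r (length m-1).
.jointLoglik <- function(E, ord, rInit, iters = 8L) {
  m <- length(ord); n <- dim(E)[1]
  r <- pmin(pmax(rInit, 1e-4), 0.4999)
  s1of <- c(1L, 1L, 2L, 2L); s2of <- c(1L, 2L, 1L, 2L)
  swMat <- outer(seq_len(4), seq_len(4), function(a, b)
    (s1of[a] != s1of[b]) + (s2of[a] != s2of[b]))
  ttOf <- function(rr) {
    T1 <- matrix(c(1 - rr, rr, rr, 1 - rr), 2, 2)
    T1 %x% T1  # joint transition, parents independent
  }
  ll <- -Inf
  for (it in seq_len(iters)) {
    A <- array(0, dim = c(n, 4, m)); sc <- matrix(0, n, m)
    a <- E[, , ord[1]] * 0.25
    s <- rowSums(a); s[s == 0] <- 1e-300
    A[, , 1] <- a / s; sc[, 1] <- log(s)
    TT <- lapply(r, ttOf)
    for (p in 2:m) {
      a <- (A[, , p - 1] %*% TT[[p - 1]]) * E[, , ord[p]]
      s <- rowSums(a); s[s == 0] <- 1e-300
      A[, , p] <- a / s; sc[, p] <- log(s)
    }
    llNew <- sum(sc)
    B <- matrix(1, n, 4)
    rNew <- numeric(m - 1)
    for (p in (m - 1):1) {
      EB <- E[, , ord[p + 1]] * B
      # xi: expected switch count over the 16 state pairs
      num <- rowSums((A[, , p] %*% (TT[[p]] * swMat)) * EB)
      den <- rowSums((A[, , p] %*% TT[[p]]) * EB)
      rNew[p] <- sum(num / pmax(den, 1e-300)) / (2 * n)
      B <- (EB %*% t(TT[[p]]))
      bs <- rowSums(B); bs[bs == 0] <- 1e-300
      B <- B / bs
    }
    conv <- abs(llNew - ll) < 1e-6
    ll <- llNew
    r <- pmin(pmax(rNew, 1e-6), 0.4999)
    if (conv) break
  }
  list(loglik = ll, r = r)
}

# Likelihood polish of the group-wide phase assignment: flip each marker's
# phase bit(s) and keep flips that decisively raise the joint likelihood of
# the current order. Fixes the rare propagation errors on weakly linked
# markers that would otherwise mislead the likelihood ripple.
.refinePhasesLik <- function(E, ord, rInit, codes, types, ph, minGain = 2) {
  cur <- .jointLoglik(E, ord, rInit)
  for (j in seq_along(ord)) {
    pa <- .CP_PARENTS[[types[j]]]
    flips <- list()
    if (pa$p1[1] != pa$p1[2]) flips <- c(flips, list(c(1L, 0L)))
    if (pa$p2[1] != pa$p2[2]) flips <- c(flips, list(c(0L, 1L)))
    if (length(flips) == 2) flips <- c(flips, list(c(1L, 1L)))
    for (f in flips) {
      ph2 <- ph
      ph2[j, ] <- as.integer(xor(ph[j, ], f))
      E2 <- E
      E2[, , j] <- .emissionArray(codes[j, , drop = FALSE],
                                  types[j], ph2[j, , drop = FALSE])[, , 1]
      fit <- .jointLoglik(E2, ord, rInit)
      if (fit$loglik > cur$loglik + minGain) {
        E <- E2; ph <- ph2; cur <- fit
      }
    }
  }
  list(E = E, ph = ph)
}

# One pass of likelihood-scored window-3 ripple over an order. Positions
# pos (aligned with ord) supply initial interval r values. Returns the
# improved order, or ord unchanged.
.likRipple <- function(E, ord, pos, minGain = 2) {
  m <- length(ord)
  if (m < 3) return(ord)
  posOf <- numeric(m)
  posOf[ord] <- pos   # position by original row index
  rFromPos <- function(o) {
    # implied adjacent r from the fitted positions, kept off the r = 0
    # boundary where the EM cannot escape
    pmin(pmax(inverseKosambi(pmin(abs(diff(posOf[o])), 200)), 0.03), 0.45)
  }
  cur <- .jointLoglik(E, ord, rFromPos(ord))
  improved <- TRUE
  sweeps <- 0L
  while (improved && sweeps < 4L) {
    improved <- FALSE
    sweeps <- sweeps + 1L
    # window-of-three permutations
    for (p in seq_len(m - 2)) {
      for (q in 2:6) {
        cand <- ord
        cand[p:(p + 2)] <- ord[p:(p + 2)][.PERM3[q, ]]
        fit <- .jointLoglik(E, cand, rFromPos(cand))
        if (fit$loglik > cur$loglik + minGain) {
          ord <- cand; cur <- fit; improved <- TRUE
        }
      }
    }
    # single-marker relocations by up to three slots
    for (p in seq_len(m)) {
      for (q in setdiff(max(1, p - 3):min(m, p + 3), p)) {
        cand <- append(ord[-p], ord[p], after = q - 1)
        fit <- .jointLoglik(E, cand, rFromPos(cand))
        if (fit$loglik > cur$loglik + minGain) {
          ord <- cand; cur <- fit; improved <- TRUE
        }
      }
    }
    # segment reversals and block rotations (escape the reversed-segment
    # local optima that window moves cannot undo); bounded for large
    # groups where the regression construction is already reliable
    maxSeg <- if (m <= 12L) m else 8L
    for (p in seq_len(m - 1)) {
      for (q in (p + 1):min(m, p + maxSeg - 1L)) {
        cand <- ord
        cand[p:q] <- rev(ord[p:q])
        fit <- .jointLoglik(E, cand, rFromPos(cand))
        if (fit$loglik > cur$loglik + minGain) {
          ord <- cand; cur <- fit; improved <- TRUE
        }
      }
    }
    if (m <= 12L) for (p in seq_len(m - 1)) {
      cand <- c(ord[(p + 1):m], ord[seq_len(p)])
      fit <- .jointLoglik(E, cand, rFromPos(cand))
      if (fit$loglik > cur$loglik + minGain) {
        ord <- cand; cur <- fit; improved <- TRUE
      }
    }
  }
  ord
}
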