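# Two-point recombination-fraction and LOD estimation for CP families.
#
# For a marker pair, each parent that is heterozygous at both loci
# contributes one informative meiosis per offspring; the offspring's joint
# genotype class is generated by transmitting one of two parental strands at
# the first locus and switching strands with probability r at the second.
# The class probabilities are polynomials in r of degree <= 2,
#   P(class) = sum_k c_k r^k (1-r)^(m-k),
# where m is the number of informative parents and the coefficients c_k
# depend on the segregation-type pair and the (unknown) parental linkage
# phases. The MLE of r is found by EM over the ambiguous classes (genotype
# codes such as "hk" that do not identify which parent transmitted which
# allele), maximized over the <= 4 phase combinations.

# Build the class-probability model for an ordered segregation-type pair.
# Returns list(classesA, classesB, phases = list of list(label, m, coef)),
# coef a (nA*nB) x 3 matrix of c_k for k = 0, 1, 2.
.pairModel <- function(typeA, typeB) {
  pA <- .CP_PARENTS[[typeA]]; pB <- .CP_PARENTS[[typeB]]
  alA <- .CP_ALPHABET[[typeA]]; alB <- .CP_ALPHABET[[typeB]]
  nA <- length(alA); nB <- length(alB)

  # gamete table of one parent: data.frame(aA, aB, const, k) where the
  # contribution is const * r^k (1-r)^(1-k) for an informative parent and
  # just const otherwise.
  gametes <- function(aAll, bAll, phase) {
    if (phase == 1) bAll <- rev(bAll)
    hetA <- aAll[1] != aAll[2]; hetB <- bAll[1] != bAll[2]
    if (hetA && hetB) {
      g <- expand.grid(sA = 1:2, sB = 1:2)
      data.frame(aA = aAll[g$sA], aB = bAll[g$sB], const = 0.5,
                 k = as.integer(g$sA != g$sB), informative = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      aSet <- if (hetA) aAll else aAll[1]
      bSet <- if (hetB) bAll else bAll[1]
      g <- expand.grid(aA = aSet, aB = bSet, stringsAsFactors = FALSE)
      data.frame(aA = g$aA, aB = g$aB,
                 const = (1 / length(aSet)) * (1 / length(bSet)),
                 k = 0L, informative = FALSE, stringsAsFactors = FALSE)
    }
  }

  inf1 <- pA$p1[1] != pA$p1[2] && pB$p1[1] != pB$p1[2]
  inf2 <- pA$p2[1] != pA$p2[2] && pB$p2[1] != pB$p2[2]
  phases1 <- if (inf1) 0:1 else 0L
  phases2 <- if (inf2) 0:1 else 0L

  phases <- list()
  for (ph1 in phases1) for (ph2 in phases2) {
    g1 <- gametes(pA$p1, pB$p1, ph1)
    g2 <- gametes(pA$p2, pB$p2, ph2)
    coef <- matrix(0, nrow = nA * nB, ncol = 3)
    for (i in seq_len(nrow(g1))) for (j in seq_len(nrow(g2))) {
      cA <- .offspringCode(g1$aA[i], g2$aA[j])
      cB <- .offspringCode(g1$aB[i], g2$aB[j])
      cls <- (match(cA, alA) - 1L) * nB + match(cB, alB)
      kk <- g1$k[i] + g2$k[j]
      coef[cls, kk + 1L] <- coef[cls, kk + 1L] + g1$const[i] * g2$const[j]
    }
    lab <- paste0(if (inf1) ph1 else "-", if (inf2) ph2 else "-")
    phases[[length(phases) + 1L]] <-
      list(label = lab, m = as.integer(inf1) + as.integer(inf2), coef = coef)
  }
  list(alA = alA, alB = alB, phases = phases,
       m = as.integer(inf1) + as.integer(inf2))
}

.pairModelCache <- new.env(parent = emptyenv())

.getPairModel <- function(typeA, typeB) {
  key <- paste(typeA, typeB)
  mod <- .pairModelCache[[key]]
  if (is.null(mod)) {
    mod <- .pairModel(typeA, typeB)
    .pairModelCache[[key]] <- mod
  }
  mod
}

# EM on a batch of pairs sharing one class model.
# N: npairs x nclass count matrix. Returns list(rf, lod, loglik, phase).
.emBatch <- function(N, model, starts = c(0.1, 0.35),
                     maxit = 200L, tol = 1e-10) {
  npairs <- nrow(N)
  ntot <- rowSums(N)
  m <- model$m
  kvec <- 0:2
  bestLL <- rep(-Inf, npairs)
  bestR <- rep(0.5, npairs)
  bestPhase <- rep(NA_character_, npairs)
  perPhase <- list()

  classProb <- function(coef, r) {
    W <- cbind((1 - r)^m, if (m >= 1) r * (1 - r)^(m - 1) else 0,
               if (m >= 2) r^2 else 0)
    tcrossprod(W, coef)                       # npairs x nclass
  }

  for (ph in model$phases) {
    coef <- ph$coef
    p05 <- as.numeric(0.5^m * rowSums(coef))
    ll05 <- as.numeric(N %*% log(pmax(p05, 1e-300)))
    llPhase <- rep(-Inf, npairs); rPhase <- rep(0.5, npairs)
    for (r0 in starts) {
      r <- rep(r0, npairs)
      for (it in seq_len(maxit)) {
        W <- cbind((1 - r)^m, if (m >= 1) r * (1 - r)^(m - 1) else 0,
                   if (m >= 2) r^2 else 0)
        P <- tcrossprod(W, coef)
        Wk <- sweep(W, 2, kvec, "*")
        Rnum <- tcrossprod(Wk, coef)
        expRec <- rowSums(N * Rnum / pmax(P, 1e-300))
        rNew <- pmin(pmax(expRec / (m * pmax(ntot, 1)), 0), 0.5)
        delta <- max(abs(rNew - r))
        r <- rNew
        if (delta < tol) break
      }
      P <- classProb(coef, r)
      ll <- rowSums(N * log(pmax(P, 1e-300)))
      upd <- ll > llPhase + 1e-12
      rPhase[upd] <- r[upd]; llPhase[upd] <- ll[upd]
    }
    upd <- llPhase > bestLL + 1e-9
    bestR[upd] <- rPhase[upd]
    bestLL[upd] <- llPhase[upd]
    bestPhase[upd] <- ph$label
    perPhase[[ph$label]] <- list(rf = rPhase, ll = llPhase, lod05 = ll05)
  }
  # LOD against r = 0.5 under the chosen phase (phase-free at 0.5)
  p05 <- as.numeric(0.5^m * rowSums(model$phases[[1]]$coef))
  ll05 <- as.numeric(N %*% log(pmax(p05, 1e-300)))
  lod <- pmax((bestLL - ll05) / log(10), 0)
  list(rf = bestR, lod = lod, loglik = bestLL, phase = bestPhase,
       perPhase = perPhase, ll05 = ll05)
}

#' All pairwise two-point estimates for a CP family
#'
#' Estimates the recombination fraction and LOD score for every marker pair
#' by maximum likelihood over the pair's joint transmission model,
#' maximizing over unknown parental linkage phases (EM is used for genotype
#' classes that do not identify the transmitting parent, e.g. \code{hk}).
#' Pairs that share no informative meioses (such as lmxll with nnxnp)
#' return \code{rf = 0.5}, \code{lod = 0}, \code{n_informative = 0}.
#'
#' @param gt a \linkS4class{CPGenotypes} object.
#' @param markers optional subset of marker ids.
#' @param phaseDetail if \code{TRUE}, attach attribute
#'   \code{"phase_detail"}: a long data.frame (\code{row}, \code{phase},
#'   \code{rf}, \code{lod}) with the estimate under every phase
#'   combination, used by phase-consistent ordering.
#' @return data.frame with columns \code{marker_a}, \code{marker_b},
#'   \code{rf}, \code{lod}, \code{n_informative}, \code{phase} (label of the
#'   maximizing phase combination, one character per parent, \code{-} for an
#'   uninformative parent, \code{NA} when no parent is informative).
#' @seealso \code{\link{estimateRF}} for a single pair.
#' @export
pairwiseRF <- function(gt, markers = NULL, phaseDetail = FALSE) {
  stopifnot(is(gt, "CPGenotypes"))
  ids <- if (is.null(markers)) markerIds(gt) else markers
  idx <- match(ids, markerIds(gt))
  if (anyNA(idx)) stop("unknown marker id: ", ids[is.na(idx)][1])
  n <- length(ids)
  if (n < 2) stop("need at least two markers")
  types <- gt@info$segregation_type[idx]

  codeIdx <- matrix(NA_integer_, nrow = n, ncol = nOffspring(gt))
  for (k in seq_len(n)) {
    alpha <- .CP_ALPHABET[[types[k]]]
    codeIdx[k, ] <- match(gt@codes[idx[k], ], alpha)
  }

  pairIdx <- utils::combn(n, 2)
  np <- ncol(pairIdx)
  key <- paste(types[pairIdx[1, ]], types[pairIdx[2, ]])
  out <- data.frame(marker_a = ids[pairIdx[1, ]],
                    marker_b = ids[pairIdx[2, ]],
                    rf = 0.5, lod = 0, n_informative = 0L,
                    phase = NA_character_, stringsAsFactors = FALSE)
  detail <- list()
  for (grp in split(seq_len(np), key)) {
    tA <- types[pairIdx[1, grp[1]]]
    tB <- types[pairIdx[2, grp[1]]]
    mod <- .getPairModel(tA, tB)
    nA <- length(mod$alA); nB <- length(mod$alB)
    N <- matrix(0, nrow = length(grp), ncol = nA * nB)
    for (q in seq_along(grp)) {
      i <- pairIdx[1, grp[q]]; j <- pairIdx[2, grp[q]]
      ci <- codeIdx[i, ]; cj <- codeIdx[j, ]
      ok <- !is.na(ci) & !is.na(cj)
      N[q, ] <- tabulate((ci[ok] - 1L) * nB + cj[ok], nbins = nA * nB)
    }
    ntot <- as.integer(rowSums(N))
    if (mod$m == 0L) {
      next  # no shared informative meioses: keep rf 0.5 / lod 0 / n 0
    }
    fit <- .emBatch(N, mod)
    out$rf[grp] <- ifelse(ntot > 0, fit$rf, 0.5)
    out$lod[grp] <- ifelse(ntot > 0, fit$lod, 0)
    out$n_informative[grp] <- ntot
    out$phase[grp] <- ifelse(ntot > 0, fit$phase, NA_character_)
    if (phaseDetail) {
      for (lab in names(fit$perPhase)) {
        pp <- fit$perPhase[[lab]]
        detail[[length(detail) + 1L]] <- data.frame(
          row = grp, phase = lab, rf = pp$rf,
          lod = (pp$ll - fit$ll05) / log(10), stringsAsFactors = FALSE)
      }
    }
  }
  if (phaseDetail)
    attr(out, "phase_detail") <-
      if (length(detail)) do.call(rbind, detail) else
        data.frame(row = integer(), phase = character(), rf = numeric(),
                   lod = numeric())
  out
}

#' Two-point estimate for one marker pair
#'
#' @param gt a \linkS4class{CPGenotypes} object.
#' @param a,b marker ids.
#' @return one-row data.frame as in \code{\link{pairwiseRF}}.
#' @export
estimateRF <- function(gt, a, b) {
  res <- pairwiseRF(gt, markers = c(a, b))
  res[1, , drop = FALSE]
}
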