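# Linkage grouping and regression-style marker ordering.

#' Partition markers into linkage groups
#'
#' Single-linkage connected components over the graph whose edges are marker
#' pairs with \code{lod >= lodGroupThreshold} and \code{rf <= maxRf}.
#' Markers without any qualifying edge are reported as unlinked.
#'
#' @param est two-point table from \code{\link{pairwiseRF}}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param markers character vector of all markers under consideration
#'   (defaults to those present in \code{est}).
#' @return list with \code{groups} (list of character vectors, size >= 2,
#'   largest first), \code{unlinked} (character) and \code{sweep}
#'   (data.frame \code{lod}, \code{n_groups}: group counts across
#'   \code{cfg@lodSweep}, reported diagnostically).
#' @export
groupMarkers <- function(est, cfg = pipelineConfig(), markers = NULL) {
  if (is.null(markers))
    markers <- sort(unique(c(est$marker_a, est$marker_b)))
  componentsAt <- function(lod) {
    keep <- est$lod >= lod & est$rf <= cfg@maxRf
    g <- igraph::graph_from_data_frame(
      est[keep, c("marker_a", "marker_b"), drop = FALSE],
      directed = FALSE,
      vertices = data.frame(name = markers))
    comp <- igraph::components(g)
    split(markers, comp$membership[markers])
  }
  sweep <- data.frame(lod = cfg@lodSweep, n_groups = NA_integer_)
  for (i in seq_along(cfg@lodSweep)) {
    cc <- componentsAt(cfg@lodSweep[i])
    sweep$n_groups[i] <- sum(lengths(cc) >= 2)
  }
  cc <- componentsAt(cfg@lodGroupThreshold)
  groups <- cc[lengths(cc) >= 2]
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = groups,
       unlinked = unlist(cc[lengths(cc) == 1], use.names = FALSE),
       sweep = sweep)
}

# Assign each group member a linkage phase per parent by propagating the
# maximum-likelihood pair phases from the strongest pairs outward
# (union-find with parity, edges in decreasing LOD order). Returns a
# 2-column 0/1 matrix (parents) with rownames = group.
.assignPhases <- function(group, est, ia, ib) {
  k <- length(group)
  ph <- matrix(0L, nrow = k, ncol = 2, dimnames = list(group, NULL))
  for (p in 1:2) {
    lab <- substr(est$phase, p, p)
    inf <- !is.na(lab) & lab != "-" & !is.na(ia) & !is.na(ib)
    ord <- which(inf)[order(-est$lod[inf])]
    parent <- seq_len(k); parity <- integer(k)
    find <- function(x) {
      par <- 0L
      while (parent[x] != x) { par <- xor(par, parity[x]); x <- parent[x] }
      c(x, par)
    }
    for (e in ord) {
      a <- ia[e]; b <- ib[e]; rel <- as.integer(lab[e])
      fa <- find(a); fb <- find(b)
      if (fa[1] != fb[1]) {
        parent[fb[1]] <- fa[1]
        parity[fb[1]] <- xor(xor(fa[2], fb[2]), rel)
      }
    }
    for (x in seq_len(k)) ph[x, p] <- find(x)[2]
    # refinement sweep: flip a marker's phase when that increases the
    # LOD-weighted agreement with the ML pair phases (the greedy spanning
    # propagation can leave a weakly linked marker on the wrong side)
    edges <- which(inf)
    for (sweep in 1:3) {
      changed <- FALSE
      for (x in seq_len(k)) {
        ex <- edges[ia[edges] == x | ib[edges] == x]
        if (!length(ex)) next
        other <- ifelse(ia[ex] == x, ib[ex], ia[ex])
        rel <- as.integer(lab[ex])
        agree <- xor(ph[x, p], ph[other, p]) == rel
        score <- sum(est$lod[ex] * ifelse(agree, 1, -1))
        if (score < 0) { ph[x, p] <- 1L - ph[x, p]; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  ph
}

# Distance/weight matrices for ordering. With phase detail available the
# recombination fraction of every pair is taken under the phases assigned
# group-wide (avoiding the downward bias of per-pair phase maximization on
# weakly linked pairs); weights are squared phase-consistent LODs.
.orderDW <- function(group, est, detail = NULL) {
  k <- length(group)
  ia <- match(est$marker_a, group)
  ib <- match(est$marker_b, group)
  keep <- which(!is.na(ia) & !is.na(ib))
  rf <- est$rf
  lod <- est$lod
  ph <- matrix(0L, nrow = k, ncol = 2, dimnames = list(group, NULL))
  if (!is.null(detail) && nrow(detail)) {
    ph <- .assignPhases(group, est, ia, ib)
    for (e in keep) {
      lab <- est$phase[e]
      if (is.na(lab)) next
      want <- vapply(1:2, function(p) {
        if (substr(lab, p, p) == "-") "-"
        else as.character(xor(ph[ia[e], p], ph[ib[e], p]) * 1L)
      }, character(1))
      want <- paste0(want[1], want[2])
      d <- detail[detail$row == e & detail$phase == want, ]
      if (nrow(d) == 1) { rf[e] <- d$rf; lod[e] <- d$lod }
    }
  }
  D <- matrix(Inf, k, k); diag(D) <- 0
  W <- matrix(0, k, k)
  usable <- rf < 0.4999 & lod > 0
  i <- ia[keep]; j <- ib[keep]
  D[cbind(i, j)] <- D[cbind(j, i)] <-
    ifelse(usable[keep], kosambiCM(pmin(rf[keep], 0.499899)), Inf)
  W[cbind(i, j)] <- W[cbind(j, i)] <-
    ifelse(usable[keep], pmax(lod[keep], 0)^2, 0)
  list(D = D, W = W, ph = ph)
}

# Weighted least-squares fit of map positions for a fixed marker order.
# D, W: symmetric distance / weight matrices over the group's markers.
# Returns list(pos, sse); pos aligned with `ord`.
.fitPositions <- function(ord, D, W) {
  k <- length(ord)
  if (k == 1) return(list(pos = 0, sse = 0))
  pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  i <- ord[pr[, 1]]; j <- ord[pr[, 2]]
  w <- W[cbind(i, j)]
  d <- D[cbind(i, j)]
  keep <- w > 0 & is.finite(d)
  if (!any(keep)) {
    # no usable pair: chain adjacent distances where finite
    gaps <- D[cbind(ord[-k], ord[-1])]
    gaps[!is.finite(gaps)] <- 0
    return(list(pos = cumsum(c(0, gaps)), sse = 0))
  }
  a <- pr[keep, 1]; b <- pr[keep, 2]
  w <- w[keep]; d <- d[keep]
  # unknowns: x_2..x_k of the current order (x_1 = 0)
  A <- matrix(0, nrow = length(a), ncol = k - 1)
  sel <- a > 1
  A[cbind(which(sel), a[sel] - 1)] <- -1
  A[cbind(seq_along(b), b - 1)] <- A[cbind(seq_along(b), b - 1)] + 1
  M <- crossprod(A, A * w)
  rhs <- crossprod(A, d * w)
  x <- tryCatch(as.numeric(solve(M, rhs)), error = function(e) NULL)
  if (is.null(x)) {
    gaps <- D[cbind(ord[-k], ord[-1])]
    gaps[!is.finite(gaps)] <- 0
    pos <- cumsum(c(0, gaps))
  } else {
    pos <- c(0, x)
  }
  resid <- as.numeric(A %*% pos[-1]) - d
  list(pos = pos, sse = sum(w * resid^2))
}

.PERM3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# One ripple pass: slide a window of 3 along the order, keeping the best of
# the 6 within-window permutations each time.
.ripple3 <- function(ord, D, W, sse) {
  k <- length(ord)
  if (k < 3) return(list(ord = ord, sse = sse))
  for (p in seq_len(k - 2)) {
    best <- list(ord = ord, sse = sse)
    for (q in 2:6) {
      cand <- ord
      cand[p:(p + 2)] <- ord[p:(p + 2)][.PERM3[q, ]]
      f <- .fitPositions(cand, D, W)
      if (f$sse < best$sse - 1e-12) best <- list(ord = cand, sse = f$sse)
    }
    ord <- best$ord; sse <- best$sse
  }
  list(ord = ord, sse = sse)
}

#' Order one linkage group and assign map positions
#'
#' Regression-style ordering: markers are added in decreasing order of
#' information content; each new marker is inserted at the position
#' minimizing the LOD-squared-weighted sum of squared differences between
#' fitted map distances and pairwise Kosambi distances, followed by a
#' window-of-three ripple (repeated to convergence after the last
#' insertion). Positions are the weighted least-squares fit, shifted so the
#' first marker sits at 0. When \code{est} carries phase detail (see
#' \code{\link{pairwiseRF}}), each marker's linkage phases are first fixed
#' group-wide by propagation from the strongest pairs and all ordering
#' distances are taken under those phases; this avoids the downward
#' distance bias that per-pair phase maximization causes on weakly linked
#' pairs. Recombination fractions above \code{maxRf} still contribute
#' ordering distances; pairs at rf 0.5 (or with LOD <= 0 under the assigned
#' phase) carry no weight.
#'
#' When the genotype table is supplied, a final ripple re-scores the same
#' window-of-three permutations by the group's exact joint likelihood (a
#' strand-inheritance hidden Markov chain with per-interval recombination
#' fractions re-fitted by a short EM). Local order conflicts that pairwise
#' distances cannot resolve - chiefly adjacent transpositions driven by a
#' single noisy low-information pair - are decided by the full genotype
#' patterns instead. The search space and the reported positions stay those
#' of the regression mapping.
#'
#' @param group character vector of marker ids forming one linkage group.
#' @param est two-point table from \code{\link{pairwiseRF}}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param gt the \linkS4class{CPGenotypes} the estimates came from; enables
#'   the likelihood-scored final ripple (optional but recommended).
#' @return data.frame \code{marker_id}, \code{position_cM} (nondecreasing,
#'   starting at 0).
#' @export
orderGroup <- function(group, est, cfg = pipelineConfig(), gt = NULL) {
  k <- length(group)
  if (k == 1)
    return(data.frame(marker_id = group, position_cM = 0))
  dw <- .orderDW(group, est, attr(est, "phase_detail"))
  D <- dw$D; W <- dw$W

  if (k == 2) {
    d <- if (is.finite(D[1, 2])) D[1, 2] else 0
    return(data.frame(marker_id = group, position_cM = c(0, round(d, 3))))
  }

  info <- rowSums(W)
  addOrder <- order(-info, group)
  ord <- addOrder[1]
  sse <- 0
  for (nx in addOrder[-1]) {
    best <- NULL
    for (slot in 0:length(ord)) {
      cand <- append(ord, nx, after = slot)
      f <- .fitPositions(cand, D, W)
      if (is.null(best) || f$sse < best$sse) best <- list(ord = cand, sse = f$sse)
    }
    rp <- .ripple3(best$ord, D, W, best$sse)
    ord <- rp$ord; sse <- rp$sse
  }
  # polish: ripple to convergence, then re-sort by fitted position when
  # that does not worsen the fit (the positions carry three-point
  # information that the discrete order cannot: transposing two markers
  # with no mutual weight leaves the objective unchanged)
  for (it in 1:10) {
    fit <- .fitPositions(ord, D, W)
    rp <- .ripple3(ord, D, W, fit$sse)
    fit <- .fitPositions(rp$ord, D, W)
    ord2 <- rp$ord[order(fit$pos)]
    if (!identical(ord2, rp$ord)) {
      f2 <- .fitPositions(ord2, D, W)
      if (f2$sse <= fit$sse + 1e-9) rp$ord <- ord2
    }
    if (identical(rp$ord, ord)) break
    ord <- rp$ord
  }
  if (!is.null(gt) && k >= 3) {
    idx <- match(group, markerIds(gt))
    if (!anyNA(idx)) {
      codes <- gt@codes[idx, , drop = FALSE]
      types <- gt@info$segregation_type[idx]
      E <- .emissionArray(codes, types, dw$ph)
      pos <- .fitPositions(ord, D, W)$pos
      rInit <- pmin(pmax(inverseKosambi(pmin(abs(diff(pos)), 200)),
                         0.03), 0.45)
      E <- .refinePhasesLik(E, ord, rInit, codes, types, dw$ph)$E
      ord <- .likRipple(E, ord, pos)
    }
  }
  fit <- .fitPositions(ord, D, W)
  pos <- cummax(fit$pos)   # guard against tiny residual LS inversions
  pos <- pos - pos[1]
  data.frame(marker_id = group[ord], position_cM = round(pos, 3))
}

#' Build a genetic linkage map from a CP genotype table
#'
#' Full linkage-mapping pipeline: markers failing the Mendelian segregation
#' chi-square test at \code{distortionAlpha} are excluded as distorted;
#' two-point recombination fractions and LODs are estimated for all
#' remaining pairs; linkage groups are formed at \code{lodGroupThreshold}
#' (rf capped at \code{maxRf}); each group is ordered by
#' \code{\link{orderGroup}}. Groups are labelled LG1, LG2, ... in decreasing
#' marker-count order.
#'
#' @param gt a \linkS4class{CPGenotypes} object.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{GeneticMap}; markers not mapped appear in
#'   \code{excludedMarkers(x)} with reason \code{"distorted"} or
#'   \code{"unlinked"}.
#' @export
buildGeneticMap <- function(gt, cfg = pipelineConfig()) {
  seg <- segregationTest(gt)
  distorted <- seg$marker_id[seg$p < cfg@distortionAlpha]
  keep <- setdiff(markerIds(gt), distorted)
  if (length(keep) < 2) stop("fewer than two markers pass the distortion filter")
  est <- pairwiseRF(gt, markers = keep, phaseDetail = TRUE)
  grp <- groupMarkers(est, cfg, markers = keep)
  lgs <- list()
  for (i in seq_along(grp$groups)) {
    om <- orderGroup(grp$groups[[i]], est, cfg)
    lgs[[i]] <- data.frame(lg_id = sprintf("LG%d", i), om,
                           stringsAsFactors = FALSE)
  }
  lgdf <- if (length(lgs)) do.call(rbind, lgs) else
    data.frame(lg_id = character(), marker_id = character(),
               position_cM = numeric())
  excl <- rbind(
    data.frame(marker_id = distorted,
               reason = rep("distorted", length(distorted))),
    data.frame(marker_id = grp$unlinked,
               reason = rep("unlinked", length(grp$unlinked))))
  new("GeneticMap", lgs = lgdf, excluded = excl)
}

#' Per-linkage-group map statistics
#'
#' Marker counts, genetic lengths and spacings per linkage group plus
#' totals. Average spacing is \code{length_cM / (n_markers - 1)} (NA for a
#' single-marker group); the mean group length is the total length divided
#' by the number of groups.
#'
#' @param gmap a \linkS4class{GeneticMap}.
#' @return list with \code{per_lg} (data.frame \code{lg_id},
#'   \code{n_markers}, \code{length_cM}, \code{avg_spacing},
#'   \code{max_spacing}) and \code{totals} (one-row data.frame
#'   \code{n_lgs}, \code{n_markers}, \code{total_length_cM},
#'   \code{mean_lg_length_cM}).
#' @export
mapStats <- function(gmap) {
  stopifnot(is(gmap, "GeneticMap"))
  sp <- split(gmap@lgs$position_cM, gmap@lgs$lg_id)
  per <- data.frame(
    lg_id = names(sp),
    n_markers = lengths(sp),
    length_cM = vapply(sp, max, 0),
    avg_spacing = vapply(sp, function(p)
      if (length(p) > 1) max(p) / (length(p) - 1) else NA_real_, 0),
    max_spacing = vapply(sp, function(p)
      if (length(p) > 1) max(diff(p)) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  per <- per[order(as.integer(sub("^\\D*", "", per$lg_id)), per$lg_id), ]
  rownames(per) <- NULL
  totals <- data.frame(
    n_lgs = nrow(per),
    n_markers = sum(per$n_markers),
    total_length_cM = sum(per$length_cM),
    mean_lg_length_cM = sum(per$length_cM) / nrow(per))
  list(per_lg = per, totals = totals)
}
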