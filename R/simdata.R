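# Synthetic-data generators: an F1 CP family segregating on a known genome,
# an FPC-style physical map whose BES carry marker sequences, and reference-
# genome placements with a 2:1 linkage-group-to-chromosome structure.
# Everything is deterministic given cfg@seed; each generator uses its own
# seed offset so stages can be regenerated independently.

.randomDNA <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

.mutateDNA <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate a ground-truth genome for a CP mapping study
#'
#' Draws marker positions along \code{nLgs} linkage groups (spacings
#' exponential above \code{minSpacingCm}, cumulated from 0), assigns each
#' marker a CP segregation type from \code{segtypeMix}, pairs linkage groups
#' so that every reference chromosome is homologous to exactly two of them
#' (the post-whole-genome-duplication 2:1 pattern), places contigs and
#' singleton BACs on distinct anchor markers, selects chimeric contigs, and
#' adds duplicated-marker pairs (suffixes \code{-1}/\code{-2}) either on the
#' two homoeologous groups or within one group.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A \linkS4class{TrueGenome}.
#' @export
simulateTrueGenome <- function(cfg = simConfig()) {
  validObject(cfg)
  set.seed(cfg@seed)
  nl <- cfg@nLgs; mpl <- cfg@markersPerLg
  gapMean <- cfg@meanLgCm / max(mpl - 1, 1)
  excess <- max(gapMean - cfg@minSpacingCm, 0.5)

  mk <- list(); lgs <- data.frame(lg_id = character(), length_cM = numeric())
  cnt <- 0L
  for (i in seq_len(nl)) {
    gaps <- cfg@minSpacingCm + stats::rexp(mpl - 1, 1 / excess)
    pos <- cumsum(c(0, gaps))
    type <- sample(names(cfg@segtypeMix), mpl, replace = TRUE,
                   prob = cfg@segtypeMix)
    isSnp <- stats::runif(mpl) < cfg@snpFraction
    ids <- sprintf("MK%04d%s", cnt + seq_len(mpl),
                   ifelse(isSnp, "_SNP", ""))
    cnt <- cnt + mpl
    mk[[i]] <- data.frame(marker_id = ids, lg_id = sprintf("LG%d", i),
                          position_cM = pos, segregation_type = type,
                          marker_type = ifelse(isSnp, "SNP", "SSR"),
                          stringsAsFactors = FALSE)
    lgs <- rbind(lgs, data.frame(lg_id = sprintf("LG%d", i),
                                 length_cM = max(pos)))
  }
  markers <- do.call(rbind, mk)

  # 2:1 homology: shuffle LGs, pair consecutive ones on one chromosome
  ord <- sample(nl)
  homology <- character(nl)
  names(homology) <- sprintf("LG%d", seq_len(nl))
  for (c in seq_len(nl / 2)) {
    homology[sprintf("LG%d", ord[c(2 * c - 1, 2 * c)])] <-
      sprintf("chr%d", c)
  }

  # duplicated-marker pairs
  dup <- data.frame(base_id = character(), lg_a = character(),
                    lg_b = character(), stringsAsFactors = FALSE)
  if (cfg@dupMarkerCount > 0) {
    nIntra <- round(cfg@dupMarkerCount * cfg@dupIntraFraction)
    for (d in seq_len(cfg@dupMarkerCount)) {
      base <- sprintf("DUP%03d", d)
      if (d <= nIntra) {
        lga <- lgb <- sample(lgs$lg_id, 1)
      } else {
        chr <- sample(unique(homology), 1)
        pairLgs <- names(homology)[homology == chr]
        lga <- pairLgs[1]; lgb <- pairLgs[2]
      }
      dup <- rbind(dup, data.frame(base_id = base, lg_a = lga, lg_b = lgb))
      for (side in 1:2) {
        lgx <- c(lga, lgb)[side]
        markers <- rbind(markers, data.frame(
          marker_id = paste0(base, "-", side), lg_id = lgx,
          position_cM = stats::runif(1, 0, lgs$length_cM[lgs$lg_id == lgx]),
          segregation_type = sample(names(cfg@segtypeMix), 1,
                                    prob = cfg@segtypeMix),
          marker_type = "SSR", stringsAsFactors = FALSE))
      }
    }
  }
  markers <- markers[order(as.integer(sub("^LG", "", markers$lg_id)),
                           markers$position_cM), ]
  rownames(markers) <- NULL

  # contig and singleton-BAC placements on distinct non-duplicated anchors
  plain <- markers$marker_id[!grepl("^DUP", markers$marker_id)]
  nChim <- round(cfg@chimericFraction * cfg@nContigs)
  need <- cfg@nContigs + nChim + cfg@nSingletonBacs
  if (need > length(plain))
    stop("not enough markers to anchor the requested contigs and BACs")
  picks <- sample(plain, need)
  anchors <- picks[seq_len(cfg@nContigs)]
  seconds <- if (nChim > 0)
    picks[cfg@nContigs + seq_len(nChim)] else character(0)
  bacAnchors <- picks[cfg@nContigs + nChim + seq_len(cfg@nSingletonBacs)]

  mrow <- function(id) markers[match(id, markers$marker_id), ]
  cp <- data.frame(
    contig_id = sprintf("ctg%d", seq_len(cfg@nContigs)),
    lg_id = mrow(anchors)$lg_id,
    anchor_marker = anchors,
    cM_anchor = mrow(anchors)$position_cM,
    cb_length = as.integer(round(stats::runif(cfg@nContigs,
                                              cfg@cbLengthRange[1],
                                              cfg@cbLengthRange[2]))),
    chimeric = FALSE, second_marker = NA_character_,
    stringsAsFactors = FALSE)
  if (nChim > 0) {
    # a chimeric contig carries a BES from a different linkage group
    chimIdx <- integer(0)
    for (s in seq_along(seconds)) {
      ok <- which(!cp$chimeric & cp$lg_id != mrow(seconds[s])$lg_id)
      pick <- ok[1]
      cp$chimeric[pick] <- TRUE
      cp$second_marker[pick] <- seconds[s]
      chimIdx <- c(chimIdx, pick)
    }
  }
  bp <- data.frame(
    clone_id = sprintf("SBC%03d", seq_len(cfg@nSingletonBacs)),
    lg_id = mrow(bacAnchors)$lg_id,
    anchor_marker = bacAnchors,
    cM_anchor = mrow(bacAnchors)$position_cM,
    stringsAsFactors = FALSE)

  loss <- data.frame(
    lg_id = lgs$lg_id,
    frac = cfg@lossFractions,
    start_frac = ifelse(cfg@lossFractions > 0,
                        stats::runif(nl) * (1 - cfg@lossFractions), 0),
    stringsAsFactors = FALSE)

  new("TrueGenome", lgs = lgs, markers = markers, contigPlacements = cp,
      bacPlacements = bp, homology = homology, lossIntervals = loss,
      dupPairs = dup)
}

#' Simulate genotypes of an F1 CP family
#'
#' For each parent, linkage group and offspring a gamete is drawn by the
#' sequential-interval model: the strand at the first marker is uniform and
#' between adjacent markers the strand switches with probability equal to
#' the inverse Kosambi transform of the true cM gap (no additional
#' interference). Parental linkage phases are randomized per marker and
#' recorded. Offspring codes follow each marker's segregation type;
#' distortion (biased transmission), random miscalls and missing data are
#' injected at the configured rates.
#'
#' @param genome a \linkS4class{TrueGenome}.
#' @param cfg the \linkS4class{SimConfig} used to build it.
#' @return A \linkS4class{CPGenotypes} with markers in genome order.
#' @export
simulateCPFamily <- function(genome, cfg = simConfig()) {
  set.seed(cfg@seed + 1L)
  n <- cfg@nOffspring
  mk <- genome@markers
  nm <- nrow(mk)
  codes <- matrix("", nrow = nm, ncol = n)
  phase <- character(nm)

  for (lg in unique(mk$lg_id)) {
    rows <- which(mk$lg_id == lg)
    pos <- mk$position_cM[rows]
    rgap <- inverseKosambi(diff(pos))
    m <- length(rows)
    trans <- list()
    for (p in 1:2) {
      # strand inheritance along the group
      S <- matrix(0L, nrow = n, ncol = m)
      S[, 1] <- sample(1:2, n, replace = TRUE)
      if (m > 1) for (j in 2:m) {
        sw <- stats::runif(n) < rgap[j - 1]
        S[, j] <- ifelse(sw, 3L - S[, j - 1], S[, j - 1])
      }
      al <- matrix("", nrow = n, ncol = m)
      ph <- integer(m)
      for (j in seq_len(m)) {
        pa <- .CP_PARENTS[[mk$segregation_type[rows[j]]]][[p]]
        ph[j] <- if (pa[1] != pa[2]) sample(0:1, 1) else 0L
        strandAllele <- if (ph[j] == 0) pa else rev(pa)
        al[, j] <- strandAllele[S[, j]]
      }
      trans[[p]] <- list(al = al, ph = ph,
                         het = vapply(seq_len(m), function(j) {
                           pa <- .CP_PARENTS[[mk$segregation_type[rows[j]]]][[p]]
                           pa[1] != pa[2]
                         }, logical(1)))
    }
    for (j in seq_len(m)) {
      codes[rows[j], ] <- .offspringCode(trans[[1]]$al[, j],
                                         trans[[2]]$al[, j])
      phase[rows[j]] <- paste0(
        if (trans[[1]]$het[j]) trans[[1]]$ph[j] else "-",
        if (trans[[2]]$het[j]) trans[[2]]$ph[j] else "-")
    }
  }

  # segregation distortion: re-draw one parent's transmitted allele with a
  # biased probability, independent of linkage
  nd <- round(cfg@distortionFrac * nm)
  if (nd > 0) {
    distorted <- sample(nm, nd)
    for (i in distorted) {
      type <- mk$segregation_type[i]
      p <- if (.CP_PARENTS[[type]]$p1[1] != .CP_PARENTS[[type]]$p1[2]) 1 else 2
      pa <- .CP_PARENTS[[type]][[p]]
      other <- .CP_PARENTS[[type]][[3 - p]]
      otherAl <- if (other[1] != other[2])
        sample(other, n, replace = TRUE) else rep(other[1], n)
      biased <- ifelse(stats::runif(n) < cfg@distortionBias, pa[1], pa[2])
      codes[i, ] <- .offspringCode(biased, otherAl)
    }
  }

  if (cfg@genotypingErrorRate > 0) {
    for (i in seq_len(nm)) {
      alpha <- .CP_ALPHABET[[mk$segregation_type[i]]]
      err <- which(stats::runif(n) < cfg@genotypingErrorRate)
      if (length(err))
        codes[i, err] <- sample(alpha, length(err), replace = TRUE)
    }
  }

  if (cfg@missingRate > 0) {
    miss <- matrix(stats::runif(nm * n) < cfg@missingRate, nm, n)
    codes[miss] <- .MISSING_CODE
  }

  info <- data.frame(marker_id = mk$marker_id,
                     marker_type = mk$marker_type,
                     segregation_type = mk$segregation_type,
                     phase = phase, stringsAsFactors = FALSE)
  rownames(codes) <- mk$marker_id
  new("CPGenotypes", familyName = "simfam", info = info, codes = codes)
}

#' Simulate the physical map, BES set and marker sequences
#'
#' Every contig receives a set of clones with forward/reverse BAC-end
#' sequences; the first clone's forward BES carries the contig's anchor
#' marker sequence verbatim (optionally mutated at \code{besErrorRate}), so
#' sequence alignment can recover the true anchors. Chimeric contigs
#' additionally embed a marker from a second linkage group. Singleton BACs
#' are built the same way.
#'
#' @param genome a \linkS4class{TrueGenome}.
#' @param cfg the \linkS4class{SimConfig} used to build it.
#' @return list with \code{physicalMap} (\linkS4class{PhysicalMap}),
#'   \code{bes} and \code{markerSeqs} (named \code{DNAStringSet}),
#'   \code{truth} (data.frame \code{marker_id}, \code{target_kind},
#'   \code{target_id}, \code{lg_id}, \code{via_chimeric_arm}) and
#'   \code{besInfo} (data.frame \code{bes_id}, \code{clone_id},
#'   \code{contig_id}, \code{lg_id}, \code{cM}).
#' @export
simulatePhysicalBES <- function(genome, cfg = simConfig()) {
  set.seed(cfg@seed + 2L)
  mk <- genome@markers
  lens <- ifelse(mk$marker_type == "SNP", cfg@snpSeqLengthBp,
                 cfg@ssrSeqLengthBp)
  markerSeqs <- stats::setNames(
    vapply(seq_len(nrow(mk)), function(i)
      .randomDNA(1, lens[i]), character(1)),
    mk$marker_id)

  embed <- function(host, insert) {
    insert <- .mutateDNA(insert, cfg@besErrorRate)
    at <- sample(nchar(host) - nchar(insert) + 1, 1)
    paste0(substr(host, 1, at - 1), insert,
           substr(host, at + nchar(insert), nchar(host)))
  }

  cp <- genome@contigPlacements
  lgLen <- stats::setNames(genome@lgs$length_cM, genome@lgs$lg_id)
  besSeq <- character(0); besInfo <- list(); contigs <- list()
  cloneN <- 0L
  for (i in seq_len(nrow(cp))) {
    nclones <- sample(seq(cfg@clonesPerContigRange[1],
                          cfg@clonesPerContigRange[2]), 1)
    cls <- sprintf("CYC%05d", cloneN + seq_len(nclones))
    cloneN <- cloneN + nclones
    # clones spread across the contig's physical span (1.428 kb per CB,
    # genetic scale set by the homologous chromosome length)
    spanCM <- cp$cb_length[i] * 1.428 / (cfg@chromMb * 1000) *
      lgLen[[cp$lg_id[i]]]
    cloneCM <- pmin(pmax(
      cp$cM_anchor[i] + stats::runif(nclones, -0.5, 0.5) * spanCM, 0),
      lgLen[[cp$lg_id[i]]])
    for (ci in seq_along(cls)) for (end in c("f", "r")) {
      id <- paste0(cls[ci], ".", end)
      s <- .randomDNA(1, cfg@besLengthBp)
      lg <- cp$lg_id[i]; cm <- cloneCM[ci]
      if (ci == 1 && end == "f")
        s <- embed(s, markerSeqs[[cp$anchor_marker[i]]])
      if (cp$chimeric[i] && ci == 2 && end == "f") {
        s <- embed(s, markerSeqs[[cp$second_marker[i]]])
        lg <- mk$lg_id[match(cp$second_marker[i], mk$marker_id)]
        cm <- mk$position_cM[match(cp$second_marker[i], mk$marker_id)]
      } else if (cp$chimeric[i] && ci == 2) {
        lg <- mk$lg_id[match(cp$second_marker[i], mk$marker_id)]
        cm <- mk$position_cM[match(cp$second_marker[i], mk$marker_id)]
      }
      besSeq[id] <- s
      besInfo[[length(besInfo) + 1L]] <- data.frame(
        bes_id = id, clone_id = cls[ci], contig_id = cp$contig_id[i],
        lg_id = lg, cM = cm, stringsAsFactors = FALSE)
    }
    contigs[[i]] <- data.frame(contig_id = cp$contig_id[i],
                               cb_length = cp$cb_length[i],
                               stringsAsFactors = FALSE)
    contigs[[i]]$clone_ids <- list(cls)
  }

  bp <- genome@bacPlacements
  for (i in seq_len(nrow(bp))) {
    for (end in c("f", "r")) {
      id <- paste0(bp$clone_id[i], ".", end)
      s <- .randomDNA(1, cfg@besLengthBp)
      if (end == "f") s <- embed(s, markerSeqs[[bp$anchor_marker[i]]])
      besSeq[id] <- s
      besInfo[[length(besInfo) + 1L]] <- data.frame(
        bes_id = id, clone_id = bp$clone_id[i], contig_id = NA_character_,
        lg_id = bp$lg_id[i], cM = bp$cM_anchor[i], stringsAsFactors = FALSE)
    }
  }

  pm <- new("PhysicalMap", contigs = do.call(rbind, contigs),
            singletons = bp$clone_id)

  truth <- rbind(
    data.frame(marker_id = cp$anchor_marker, target_kind = "contig",
               target_id = cp$contig_id, lg_id = cp$lg_id,
               via_chimeric_arm = FALSE, stringsAsFactors = FALSE),
    if (any(cp$chimeric)) data.frame(
      marker_id = cp$second_marker[cp$chimeric], target_kind = "contig",
      target_id = cp$contig_id[cp$chimeric],
      lg_id = mk$lg_id[match(cp$second_marker[cp$chimeric], mk$marker_id)],
      via_chimeric_arm = TRUE, stringsAsFactors = FALSE),
    data.frame(marker_id = bp$anchor_marker, target_kind = "single_bac",
               target_id = bp$clone_id, lg_id = bp$lg_id,
               via_chimeric_arm = FALSE, stringsAsFactors = FALSE))

  list(physicalMap = pm,
       bes = Biostrings::DNAStringSet(besSeq),
       markerSeqs = Biostrings::DNAStringSet(markerSeqs),
       truth = truth,
       besInfo = do.call(rbind, besInfo))
}

#' Simulate reference-genome placements of the BES set
#'
#' Each BES receives one significant hit on the reference chromosome
#' homologous to its linkage group, at a position collinear with its cM
#' coordinate (Gaussian jitter of \code{jitterBpSd}), unless the position
#' falls inside the group's segmental-loss interval, in which case only an
#' above-cutoff decoy may be emitted. A configurable fraction of BES emit
#' an extra decoy hit regardless. Output follows the 12-column tabular
#' alignment convention (1-based inclusive, minus strand as
#' \code{sstart > send}).
#'
#' @param genome a \linkS4class{TrueGenome}.
#' @param phys result of \code{\link{simulatePhysicalBES}}.
#' @param cfg the \linkS4class{SimConfig} used to build them.
#' @return data.frame of tabular hits (as \code{\link{readBlastTab}}).
#' @export
simulateReferencePlacements <- function(genome, phys, cfg = simConfig()) {
  set.seed(cfg@seed + 3L)
  bi <- phys$besInfo
  chromLen <- cfg@chromMb * 1e6
  lgLen <- stats::setNames(genome@lgs$length_cM, genome@lgs$lg_id)
  loss <- genome@lossIntervals

  hits <- list()
  mkHit <- function(q, chr, pos, len, ev, score) {
    minus <- stats::runif(1) < 0.5
    s1 <- round(pos); s2 <- round(pos) + len - 1
    data.frame(query_id = q, subject_id = chr,
               identity_pct = round(stats::runif(1, 90, 100), 2),
               align_len = len, mismatch = 0L, gapopen = 0L,
               qstart = 1L, qend = len,
               sstart = if (minus) s2 else s1,
               send = if (minus) s1 else s2,
               evalue = ev, bitscore = score, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(bi))) {
    lg <- bi$lg_id[i]
    chr <- genome@homology[[lg]]
    rel <- bi$cM[i] / lgLen[[lg]]
    li <- loss[loss$lg_id == lg, ]
    lost <- nrow(li) == 1 && li$frac > 0 &&
      rel >= li$start_frac && rel < li$start_frac + li$frac
    len <- as.integer(round(cfg@besLengthBp * stats::runif(1, 0.5, 1)))
    if (!lost) {
      pos <- rel * chromLen + stats::rnorm(1, 0, cfg@jitterBpSd)
      pos <- min(max(pos, 1), chromLen - len)
      ev <- 10^stats::runif(1, -50, -10)
      hits[[length(hits) + 1L]] <-
        mkHit(bi$bes_id[i], chr, pos, len, ev, round(2 * len * 0.9))
    }
    if (lost || stats::runif(1) < cfg@decoyRate) {
      dchr <- sample(unique(genome@homology), 1)
      dpos <- stats::runif(1, 1, chromLen - len)
      hits[[length(hits) + 1L]] <-
        mkHit(bi$bes_id[i], dchr, dpos, len, 10^stats::runif(1, -4.5, -3),
              round(0.5 * len))
    }
  }
  out <- do.call(rbind, hits)
  out$strand <- ifelse(out$sstart > out$send, "-", "+")
  out
}

#' Write one complete simulated dataset to disk
#'
#' Emits every external format the pipeline reads (CP genotype dialect,
#' physical-map TSV, marker and BES FASTA, tabular reference hits) plus a
#' \code{truth/} directory of evaluation tables.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects.
#' @export
writeSimulatedDataset <- function(cfg, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  genome <- simulateTrueGenome(cfg)
  gt <- simulateCPFamily(genome, cfg)
  phys <- simulatePhysicalBES(genome, cfg)
  refHits <- simulateReferencePlacements(genome, phys, cfg)

  writeGenotypes(gt, file.path(dir, "genotypes.txt"))
  writePhysicalMap(phys$physicalMap, file.path(dir, "physical_map.tsv"))
  Biostrings::writeXStringSet(phys$bes, file.path(dir, "bes.fasta"))
  Biostrings::writeXStringSet(phys$markerSeqs,
                              file.path(dir, "markers.fasta"))
  writeBlastTab(refHits, file.path(dir, "reference_hits.tsv"))

  wt <- function(x, f) utils::write.table(
    x, file.path(dir, "truth", f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(genome@markers, "markers.tsv")
  wt(genome@contigPlacements, "contig_placements.tsv")
  wt(phys$truth, "anchors.tsv")
  wt(data.frame(lg_id = names(genome@homology),
                chromosome = unname(genome@homology)), "homology.tsv")
  wt(genome@dupPairs, "duplicated_markers.tsv")
  invisible(list(genome = genome, genotypes = gt, physical = phys,
                 referenceHits = refHits))
}
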