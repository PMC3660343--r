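# Marker-to-BES anchoring: a seed-and-extend aligner for synthetic data,
# threshold filtering, and resolution of hits to physical-map targets.

#' Exact-seed ungapped aligner
#'
#' Minimal deterministic aligner used to anchor marker sequences in a BES
#' set without an external alignment binary: exact 21-mer seeds (sampled
#' every k bases plus the final window, both strands) followed by ungapped
#' extension across the full query/subject overlap. Reports hits in the
#' 12-column tabular convention; the e-value is 0 (identity and length are
#' the deciding statistics downstream) and the score is twice the number of
#' matching bases. Real BLASTn tabular output can be used as a drop-in
#' replacement anywhere this function's output is consumed.
#'
#' @param queries named character vector or \code{DNAStringSet} of marker
#'   sequences (uppercase ACGTN).
#' @param subjects named \code{DNAStringSet} (or named character) of BES.
#' @param k seed length.
#' @return data.frame of hits as \code{\link{readBlastTab}} returns.
#' @export
naiveAlign <- function(queries, subjects, k = 21L) {
  qs <- if (is.character(queries)) queries else as.character(queries)
  if (is.null(names(qs)) || any(!nzchar(names(qs))))
    stop("queries must be named")
  if (any(nchar(qs) == 0)) stop("empty query sequence")
  if (any(grepl("[^ACGTN]", qs))) stop("queries must be uppercase ACGTN")
  if (!is(subjects, "DNAStringSet"))
    subjects <- Biostrings::DNAStringSet(subjects)
  if (is.null(names(subjects))) stop("subjects must be named")

  # seed table over both strands
  seeds <- list()
  for (qi in seq_along(qs)) {
    L <- nchar(qs[qi])
    if (L < k) next
    starts <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    for (strand in c("+", "-")) {
      s <- if (strand == "+") qs[qi] else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(qs[qi])))
      sub <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("N", sub, fixed = TRUE)
      if (!any(ok)) next
      seeds[[length(seeds) + 1L]] <- data.frame(
        qi = qi, strand = strand, qpos = starts[ok], seq = sub[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(seeds)) return(.emptyHits())
  seeds <- do.call(rbind, seeds)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seq))

  # one search against the concatenated subjects (N runs as separators:
  # seeds are N-free and N never matches, so no hit can span a junction)
  subjChr <- as.character(subjects)
  sep <- strrep("N", k + 4L)
  subjStart <- cumsum(c(1L, nchar(subjChr) + nchar(sep)))[seq_along(subjChr)]
  big <- Biostrings::DNAString(paste(subjChr, collapse = sep))
  m <- Biostrings::matchPDict(pd, big)
  st <- IRanges::start(m)
  n <- lengths(st)
  if (sum(n) == 0) return(.emptyHits())
  sidx <- rep(seq_along(n), n)
  gstart <- unlist(st, use.names = FALSE)
  subj <- findInterval(gstart, subjStart)
  cand <- unique(data.frame(
    si = seeds$qi[sidx], strand = seeds$strand[sidx], subj = subj,
    offset = gstart - subjStart[subj] + 1L - seeds$qpos[sidx] + 1L,
    stringsAsFactors = FALSE))

  rcCache <- new.env(parent = emptyenv())
  rcOf <- function(qi) {
    key <- as.character(qi)
    v <- rcCache[[key]]
    if (is.null(v)) {
      v <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(qs[qi])))
      rcCache[[key]] <- v
    }
    v
  }
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    qi <- cand$si[i]; j <- cand$subj[i]; o <- cand$offset[i]
    qlen <- nchar(qs[qi]); slen <- nchar(subjChr[j])
    qseq <- if (cand$strand[i] == "+") qs[qi] else rcOf(qi)
    qFrom <- max(1L, 2L - o); qTo <- min(qlen, slen - o + 1L)
    L <- qTo - qFrom + 1L
    if (L < k) next
    frag <- substr(qseq, qFrom, qTo)
    sfrag <- substr(subjChr[j], o + qFrom - 1L, o + qTo - 1L)
    mism <- sum(charToRaw(frag) != charToRaw(sfrag))
    sFrom <- o + qFrom - 1L; sTo <- o + qTo - 1L
    if (cand$strand[i] == "+") {
      qA <- qFrom; qB <- qTo; sA <- sFrom; sB <- sTo
    } else {
      qA <- qlen - qTo + 1L; qB <- qlen - qFrom + 1L
      sA <- sTo; sB <- sFrom
    }
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = names(qs)[qi], subject_id = names(subjects)[j],
      identity_pct = round(100 * (L - mism) / L, 2), align_len = L,
      mismatch = mism, gapopen = 0L, qstart = qA, qend = qB,
      sstart = sA, send = sB, evalue = 0, bitscore = 2 * (L - mism),
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(.emptyHits())
  out <- unique(do.call(rbind, hits))
  out$strand <- ifelse(out$sstart > out$send, "-", "+")
  rownames(out) <- NULL
  out
}

.emptyHits <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = 12,
                           dimnames = list(NULL, .BLAST_COLS)))
  out$strand <- character(0)
  out
}

#' Filter anchoring hits by length, identity and e-value
#'
#' Applies the anchoring acceptance thresholds: microsatellite (SSR) markers
#' need alignments of at least \code{ssrMinAlignBp} (default 150 bp), SNP
#' markers at least \code{snpMinAlignBp} (default 100 bp), identity strictly
#' above \code{minIdentityPct} (default 95), e-value at most
#' \code{evalueCutoff}. Among a marker's surviving hits the best is chosen
#' by bitscore (descending), then e-value (ascending), then subject id;
#' exact ties on all three are all retained so downstream resolution can
#' flag ambiguous markers.
#'
#' @param hits alignment data.frame (\code{\link{naiveAlign}} or
#'   \code{\link{readBlastTab}}).
#' @param markerTypes named character vector, marker id -> "SSR"/"SNP";
#'   markers absent from it are treated as SSR.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return the input with added columns \code{reject_reason}
#'   (\code{below_length}, \code{below_identity}, \code{above_evalue} or
#'   \code{none}) and \code{accepted} (passing and best for its marker).
#' @export
filterAnchorHits <- function(hits, markerTypes = NULL,
                             cfg = pipelineConfig()) {
  if (!nrow(hits)) {
    hits$reject_reason <- character(0); hits$accepted <- logical(0)
    return(hits)
  }
  type <- if (is.null(markerTypes)) rep("SSR", nrow(hits)) else {
    tp <- markerTypes[hits$query_id]
    tp[is.na(tp)] <- "SSR"
    tp
  }
  minLen <- ifelse(type == "SNP", cfg@snpMinAlignBp, cfg@ssrMinAlignBp)
  reason <- rep("none", nrow(hits))
  reason[hits$align_len < minLen] <- "below_length"
  ok <- reason == "none"
  reason[ok & hits$identity_pct <= cfg@minIdentityPct] <- "below_identity"
  ok <- reason == "none"
  reason[ok & hits$evalue > cfg@evalueCutoff] <- "above_evalue"
  hits$reject_reason <- reason
  hits$accepted <- FALSE
  pass <- which(reason == "none")
  for (grp in split(pass, hits$query_id[pass])) {
    o <- grp[order(-hits$bitscore[grp], hits$evalue[grp],
                   hits$subject_id[grp])]
    top <- o[1]
    ties <- grp[hits$bitscore[grp] == hits$bitscore[top] &
                hits$evalue[grp] == hits$evalue[top]]
    hits$accepted[ties] <- TRUE
  }
  hits
}

#' Resolve accepted hits to physical-map targets
#'
#' Maps each accepted hit's BES to its clone and then to a physical-map
#' contig (or a singleton BAC). A marker whose equally scored best hits
#' resolve to more than one target is assigned to neither and listed in the
#' \code{"ambiguous"} attribute; BES whose clone is absent from the physical
#' map are listed in \code{"unresolved"}.
#'
#' @param filtered output of \code{\link{filterAnchorHits}}.
#' @param pm a \linkS4class{PhysicalMap}.
#' @return data.frame of marker anchors: \code{marker_id}, \code{bes_id},
#'   \code{clone_id}, \code{target_kind} ("contig"/"single_bac"),
#'   \code{target_id}, \code{accepted}, \code{reject_reason}; attributes
#'   \code{"ambiguous"} and \code{"unresolved"} carry the flagged ids.
#' @export
resolveTargets <- function(filtered, pm) {
  stopifnot(is(pm, "PhysicalMap"))
  acc <- filtered[filtered$accepted, , drop = FALSE]
  empty <- data.frame(marker_id = character(), bes_id = character(),
                      clone_id = character(), target_kind = character(),
                      target_id = character(), accepted = logical(),
                      reject_reason = character(), stringsAsFactors = FALSE)
  if (!nrow(acc)) {
    attr(empty, "ambiguous") <- character(0)
    attr(empty, "unresolved") <- character(0)
    return(empty)
  }
  bt <- besTable(acc$subject_id)
  cloneToContig <- stats::setNames(
    rep(pm@contigs$contig_id, lengths(pm@contigs$clone_ids)),
    unlist(pm@contigs$clone_ids, use.names = FALSE))
  contig <- cloneToContig[bt$clone_id]
  isSingle <- bt$clone_id %in% pm@singletons
  unresolved <- unique(bt$bes_id[is.na(contig) & !isSingle])
  res <- data.frame(marker_id = acc$query_id, bes_id = bt$bes_id,
                    clone_id = bt$clone_id,
                    target_kind = ifelse(isSingle, "single_bac", "contig"),
                    target_id = ifelse(isSingle, bt$clone_id,
                                       unname(contig)),
                    stringsAsFactors = FALSE)
  res <- res[!is.na(res$target_id), , drop = FALSE]
  ambiguous <- character(0)
  keep <- logical(nrow(res))
  for (grp in split(seq_len(nrow(res)), res$marker_id)) {
    tg <- unique(res$target_id[grp])
    if (length(tg) == 1) keep[grp[1]] <- TRUE
    else ambiguous <- c(ambiguous, res$marker_id[grp[1]])
  }
  out <- res[keep, , drop = FALSE]
  out$accepted <- TRUE
  out$reject_reason <- "none"
  rownames(out) <- NULL
  attr(out, "ambiguous") <- ambiguous
  attr(out, "unresolved") <- unresolved
  out
}

# Perfect di-/tri-/tetra-nucleotide repeats of total length >= minLen,
# excluding units that are themselves repeats of a shorter unit.
.findSSRMotifs <- function(seq, minLen = 12L) {
  out <- list()
  for (u in 2:4) {
    copies <- ceiling(minLen / u)
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, copies - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      unit <- substr(seq, m[i], m[i] + u - 1L)
      # reject units with an internal period (e.g. "ATAT", "AA")
      degenerate <- any(vapply(seq_len(u - 1), function(p) {
        u %% p == 0 &&
          unit == paste(rep(substr(unit, 1, p), u / p), collapse = "")
      }, logical(1)))
      if (degenerate) next
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m[i]), end = as.integer(m[i] + len[i] - 1L),
        unit = unit, unit_len = u, motif_len = len[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), unit_len = integer(),
                      motif_len = integer()))
  res <- do.call(rbind, out)
  res <- res[order(-res$motif_len, res$start), ]
  # drop motifs nested in a longer one
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(res)) > i &
                res$start <= res$end[i] & res$end >= res$start[i])
    keep[ov] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select candidate microsatellite loci from large contigs
#'
#' Implements the contig-anchored marker development screen: contigs whose
#' physical length (\code{cb_length * kbPerCb}) exceeds 1 Mb are taken in
#' decreasing size order; their BES are scanned for perfect di-, tri- and
#' tetra-nucleotide repeats of total length >= 12 bp; a locus is kept only
#' if at least 50 bp of flanking sequence is available on both sides of the
#' motif; at most two loci are reported per contig (longest motifs first).
#'
#' @param pm a \linkS4class{PhysicalMap}.
#' @param bes named \code{DNAStringSet} (or named character) of BES.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param minContigKb minimum contig size (kb) to screen.
#' @param minFlankBp required flank on each side of a motif.
#' @param maxPerContig loci reported per contig.
#' @return data.frame \code{contig_id}, \code{bes_id}, \code{start},
#'   \code{end}, \code{unit}, \code{motif_len}, \code{contig_kb}.
#' @export
selectCandidateLoci <- function(pm, bes, cfg = pipelineConfig(),
                                minContigKb = 1000, minFlankBp = 50L,
                                maxPerContig = 2L) {
  stopifnot(is(pm, "PhysicalMap"))
  seqs <- if (is(bes, "DNAStringSet")) as.character(bes) else bes
  bt <- besTable(names(seqs))
  ct <- pm@contigs
  ct$kb <- ct$cb_length * cfg@kbPerCb
  big <- ct[ct$kb > minContigKb, , drop = FALSE]
  big <- big[order(-big$kb), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(big))) {
    cbes <- bt$bes_id[bt$clone_id %in% big$clone_ids[[i]]]
    loci <- list()
    for (b in cbes) {
      mo <- .findSSRMotifs(seqs[[b]])
      if (!nrow(mo)) next
      flankOk <- mo$start > minFlankBp &
        mo$end <= nchar(seqs[[b]]) - minFlankBp
      mo <- mo[flankOk, , drop = FALSE]
      if (nrow(mo)) loci[[b]] <- data.frame(bes_id = b, mo)
    }
    if (!length(loci)) next
    loci <- do.call(rbind, loci)
    loci <- loci[order(-loci$motif_len, loci$bes_id, loci$start), ]
    loci <- utils::head(loci, maxPerContig)
    out[[length(out) + 1L]] <- data.frame(
      contig_id = big$contig_id[i], loci[, c("bes_id", "start", "end",
                                             "unit", "motif_len")],
      contig_kb = big$kb[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig_id = character(), bes_id = character(),
                      start = integer(), end = integer(),
                      unit = character(), motif_len = integer(),
                      contig_kb = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
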