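# Integration of anchored contigs/BACs with the genetic map: placement,
# physical coverage accounting, assembly-conflict detection and
# duplicated-marker classification.

#' Attach anchored elements to linkage-group positions
#'
#' Joins marker anchors with the genetic map: every anchored contig or
#' single BAC is attached at its marker's cM position on every linkage
#' group where it has an accepted anchor. Contigs anchored on two or more
#' different linkage groups are flagged as conflicting (but retained).
#' Elements with two or more anchoring markers on one group are orientable
#' in principle; since BES positions along a contig are not modelled, the
#' orientation is reported as \code{unoriented} and the marker multiplicity
#' is left to the caller. Anchored markers absent from the map are recorded
#' in the \code{unplacedMarkers} slot, not placed.
#'
#' @param gmap a \linkS4class{GeneticMap}.
#' @param anchors anchor table from \code{\link{resolveTargets}}.
#' @param pm a \linkS4class{PhysicalMap}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param warnSpanCm intra-group anchor span (cM) above which a warning is
#'   logged (a wide same-group span is suspicious but is not a conflict).
#' @return An \linkS4class{IntegratedMap}.
#' @export
integrateMap <- function(gmap, anchors, pm, cfg = pipelineConfig(),
                         warnSpanCm = 20) {
  stopifnot(is(gmap, "GeneticMap"), is(pm, "PhysicalMap"))
  known <- anchors$target_kind == "single_bac" |
    anchors$target_id %in% pm@contigs$contig_id
  if (any(!known))
    stop("anchor references unknown contig: ",
         anchors$target_id[!known][1])
  pos <- gmap@lgs[match(anchors$marker_id, gmap@lgs$marker_id), ]
  unplaced <- unique(anchors$marker_id[is.na(pos$lg_id)])
  ok <- !is.na(pos$lg_id)
  cbl <- stats::setNames(pm@contigs$cb_length, pm@contigs$contig_id)
  tab <- data.frame(
    lg_id = pos$lg_id[ok],
    position_cM = pos$position_cM[ok],
    marker_id = anchors$marker_id[ok],
    element_kind = anchors$target_kind[ok],
    element_id = anchors$target_id[ok],
    length_kb = ifelse(anchors$target_kind[ok] == "contig",
                       unname(cbl[anchors$target_id[ok]]) * cfg@kbPerCb,
                       cfg@bacInsertKb),
    orientation = "unoriented",
    stringsAsFactors = FALSE)
  # conflict: a contig with accepted anchors on >= 2 linkage groups
  lgPerElem <- tapply(tab$lg_id, tab$element_id,
                      function(x) length(unique(x)))
  tab$conflict <- tab$element_kind == "contig" &
    lgPerElem[tab$element_id] >= 2
  # wide same-group spans are logged, not flagged
  spans <- tapply(seq_len(nrow(tab)), paste(tab$element_id, tab$lg_id),
                  function(i) diff(range(tab$position_cM[i])))
  wide <- names(spans)[spans > warnSpanCm]
  if (length(wide))
    warning("anchor span > ", warnSpanCm, " cM within one group for: ",
            paste(wide, collapse = ", "))
  rownames(tab) <- NULL
  new("IntegratedMap", anchors = tab, unplacedMarkers = unplaced)
}

#' Physical coverage of the integrated map
#'
#' Per-group sums count every attachment (a contig conflicting between two
#' groups contributes its full length to both: "with redundancy"); the
#' non-redundant totals count each distinct contig or BAC once. Contig
#' lengths are \code{cb_length * kbPerCb}, single BACs \code{bacInsertKb}.
#' Lengths are kept exact in kb internally; the \code{*_mb} fields are
#' rounded to 2 decimals at report time.
#'
#' @param imap an \linkS4class{IntegratedMap}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param genomeMb assumed genome size (Mb) for the coverage fraction;
#'   defaults to \code{cfg@genomeMb}.
#' @return list with \code{per_lg} (data.frame \code{lg_id},
#'   \code{anchored_kb}, \code{anchored_mb}), \code{totals} (one-row
#'   data.frame: \code{contig_kb}, \code{single_bac_kb}, \code{contig_mb},
#'   \code{single_bac_mb}, \code{total_nonredundant_mb},
#'   \code{total_redundant_mb}, \code{n_contigs}, \code{n_single_bacs},
#'   \code{mean_contig_kb}, \code{genome_fraction}).
#' @export
physicalCoverage <- function(imap, cfg = pipelineConfig(),
                             genomeMb = cfg@genomeMb) {
  stopifnot(is(imap, "IntegratedMap"))
  a <- anchorTable(imap)
  # one row per (lg, element): multiple markers on one group count once
  el <- unique(a[, c("lg_id", "element_kind", "element_id", "length_kb")])
  perKb <- tapply(el$length_kb, el$lg_id, sum)
  per <- data.frame(lg_id = names(perKb), anchored_kb = as.numeric(perKb),
                    anchored_mb = round(as.numeric(perKb) / 1000, 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  distinct <- unique(el[, c("element_kind", "element_id", "length_kb")])
  ctgKb <- sum(distinct$length_kb[distinct$element_kind == "contig"])
  bacKb <- sum(distinct$length_kb[distinct$element_kind == "single_bac"])
  nCtg <- sum(distinct$element_kind == "contig")
  nBac <- sum(distinct$element_kind == "single_bac")
  totals <- data.frame(
    contig_kb = ctgKb, single_bac_kb = bacKb,
    contig_mb = round(ctgKb / 1000, 2),
    single_bac_mb = round(bacKb / 1000, 2),
    total_nonredundant_mb = round((ctgKb + bacKb) / 1000, 2),
    total_redundant_mb = round(sum(el$length_kb) / 1000, 2),
    n_contigs = nCtg, n_single_bacs = nBac,
    mean_contig_kb = if (nCtg) ctgKb / nCtg else NA_real_,
    genome_fraction = (ctgKb + bacKb) / 1000 / genomeMb)
  list(per_lg = per, totals = totals)
}

#' Detect physical-map assembly conflicts
#'
#' A contig is conflicting when its accepted anchors fall on two or more
#' different linkage groups; the conflict rate over all anchored contigs
#' estimates the physical-map assembly error rate (conflicts can also stem
#' from anchoring through duplicated loci, so it is an upper bound).
#'
#' @param imap an \linkS4class{IntegratedMap}.
#' @return list with \code{conflicting} (character vector of contig ids),
#'   \code{n_anchored_contigs}, and \code{error_rate_pct} (integer percent,
#'   rounded to the nearest whole number).
#' @export
detectConflicts <- function(imap) {
  stopifnot(is(imap, "IntegratedMap"))
  a <- anchorTable(imap)
  ctg <- a[a$element_kind == "contig", , drop = FALSE]
  nl <- tapply(ctg$lg_id, ctg$element_id, function(x) length(unique(x)))
  conflicting <- sort(names(nl)[nl >= 2])
  n <- length(nl)
  list(conflicting = conflicting, n_anchored_contigs = n,
       error_rate_pct = if (n) as.integer(round(100 * length(conflicting) / n))
                        else 0L)
}

#' Classify duplicated markers
#'
#' A duplicated marker is one assay amplifying two mappable loci (suffixes
#' \code{-1}/\code{-2}). A pair whose loci map to two different linkage
#' groups is consistent with the whole-genome duplication
#' (\code{wgd_consistent}; annotated with the shared orthologous reference
#' chromosome when both groups are assigned to the same one); a pair on a
#' single group points to a segmental duplication (\code{intra_lg}). Pairs
#' with an unmapped locus are \code{unclassifiable}.
#'
#' @param pairs data.frame with columns \code{base_id}, \code{lg_a},
#'   \code{lg_b} (NA for an unmapped locus).
#' @param homology optional homology table (\code{\link{assignLgHomology}}
#'   output or any data.frame with \code{lg_id}, \code{chromosome}).
#' @return the input with added \code{classification} and
#'   \code{orthologous_chromosome}; counts in attribute \code{"counts"}.
#' @export
classifyDuplicatedMarkers <- function(pairs, homology = NULL) {
  cls <- ifelse(is.na(pairs$lg_a) | is.na(pairs$lg_b), "unclassifiable",
                ifelse(pairs$lg_a == pairs$lg_b, "intra_lg",
                       "wgd_consistent"))
  orth <- rep(NA_character_, nrow(pairs))
  if (!is.null(homology) && nrow(homology)) {
    chrOf <- stats::setNames(homology$chromosome, homology$lg_id)
    ca <- chrOf[pairs$lg_a]; cb <- chrOf[pairs$lg_b]
    same <- !is.na(ca) & !is.na(cb) & ca == cb
    orth[same] <- ca[same]
  }
  out <- pairs
  out$classification <- cls
  out$orthologous_chromosome <- orth
  attr(out, "counts") <- c(
    wgd_consistent = sum(cls == "wgd_consistent"),
    intra_lg = sum(cls == "intra_lg"),
    unclassifiable = sum(cls == "unclassifiable"))
  out
}

#' Collect duplicated-marker pairs from a genetic map
#'
#' Finds markers whose ids share a base name with suffixes \code{-1} and
#' \code{-2} and reports the linkage group of each locus (NA if unmapped).
#'
#' @param gmap a \linkS4class{GeneticMap}.
#' @return data.frame \code{base_id}, \code{lg_a}, \code{lg_b} suitable for
#'   \code{\link{classifyDuplicatedMarkers}}.
#' @export
dupPairsFromMap <- function(gmap) {
  stopifnot(is(gmap, "GeneticMap"))
  ids <- c(gmap@lgs$marker_id, gmap@excluded$marker_id)
  dup <- grep("-[12]$", ids, value = TRUE)
  bases <- sort(unique(sub("-[12]$", "", dup)))
  lgOf <- stats::setNames(gmap@lgs$lg_id, gmap@lgs$marker_id)
  data.frame(base_id = bases,
             lg_a = unname(lgOf[paste0(bases, "-1")]),
             lg_b = unname(lgOf[paste0(bases, "-2")]),
             stringsAsFactors = FALSE)
}
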