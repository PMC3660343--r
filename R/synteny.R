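# Comparative mapping against a diploid reference genome: top-hit query
# placement, linkage-group-to-chromosome homology, synteny-block merging
# and segmental-loss detection.

#' Place queries on the reference genome
#'
#' Keeps, per query, the single top hit below the e-value cutoff, ordered
#' by bitscore (descending), e-value (ascending), chromosome, then start
#' (a deterministic tie-break). Coordinates are converted from the 1-based
#' inclusive file convention to 0-based half-open; the strand comes from
#' the coordinate order. Optionally tags every placement with its source
#' linkage group and cM position.
#'
#' @param hits alignment data.frame (\code{\link{readBlastTab}} columns).
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param sourceMap optional data.frame \code{query_id}, \code{lg_id},
#'   \code{cM}.
#' @return data.frame \code{query_id}, \code{chromosome}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{evalue},
#'   \code{bitscore}, and (if \code{sourceMap} given) \code{source_lg},
#'   \code{source_cM}.
#' @export
placeQueries <- function(hits, cfg = pipelineConfig(), sourceMap = NULL) {
  keep <- hits$evalue <= cfg@evalueCutoff
  h <- hits[keep, , drop = FALSE]
  if (nrow(h)) {
    lo <- pmin(h$sstart, h$send)
    hi <- pmax(h$sstart, h$send)
    h$start <- lo - 1L
    h$end <- hi
    h$strand <- ifelse(h$sstart > h$send, "-", "+")
    o <- order(h$query_id, -h$bitscore, h$evalue, h$subject_id, h$start)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
  }
  out <- data.frame(query_id = h$query_id, chromosome = h$subject_id,
                    start = h$start, end = h$end, strand = h$strand,
                    evalue = h$evalue, bitscore = h$bitscore,
                    stringsAsFactors = FALSE)
  if (!is.null(sourceMap)) {
    i <- match(out$query_id, sourceMap$query_id)
    out$source_lg <- sourceMap$lg_id[i]
    out$source_cM <- sourceMap$cM[i]
  }
  rownames(out) <- NULL
  out
}

#' Assign each linkage group a homologous reference chromosome
#'
#' Per linkage group, the modal chromosome among its placed queries and the
#' fraction of placements supporting it; an assignment is emitted when the
#' fraction reaches \code{homologyMinFraction}. Groups without placements
#' are reported unassigned. The attribute \code{"two_to_one"} summarizes,
#' per chromosome, the assigned groups and whether there are exactly two —
#' the pattern expected when the mapped genome derives from a whole-genome
#' duplication of the reference karyotype.
#'
#' @param placements \code{\link{placeQueries}} output with
#'   \code{source_lg}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return data.frame \code{lg_id}, \code{chromosome} (NA if unassigned),
#'   \code{supporting_hits}, \code{n_placed}, \code{fraction},
#'   \code{assigned}; attribute \code{"two_to_one"} is a data.frame
#'   \code{chromosome}, \code{lg_list}, \code{n_lgs}, \code{is_two_to_one}.
#' @export
assignLgHomology <- function(placements, cfg = pipelineConfig()) {
  pl <- placements[!is.na(placements$source_lg), , drop = FALSE]
  lgIds <- sort(unique(pl$source_lg))
  out <- data.frame(lg_id = lgIds, chromosome = NA_character_,
                    supporting_hits = 0L, n_placed = 0L,
                    fraction = NA_real_, assigned = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lgIds)) {
    chr <- pl$chromosome[pl$source_lg == lgIds[i]]
    tab <- sort(table(chr), decreasing = TRUE)
    out$n_placed[i] <- length(chr)
    out$supporting_hits[i] <- as.integer(tab[1])
    out$fraction[i] <- tab[1] / length(chr)
    if (out$fraction[i] >= cfg@homologyMinFraction) {
      out$chromosome[i] <- names(tab)[1]
      out$assigned[i] <- TRUE
    }
  }
  asg <- out[out$assigned, , drop = FALSE]
  tto <- do.call(rbind, lapply(split(asg$lg_id, asg$chromosome),
    function(l) data.frame(lg_list = paste(sort(l), collapse = ","),
                           n_lgs = length(l))))
  if (!is.null(tto)) {
    tto <- data.frame(chromosome = rownames(tto), tto, row.names = NULL,
                      stringsAsFactors = FALSE)
    tto$is_two_to_one <- tto$n_lgs == 2L
  } else {
    tto <- data.frame(chromosome = character(), lg_list = character(),
                      n_lgs = integer(), is_two_to_one = logical())
  }
  attr(out, "two_to_one") <- tto
  out
}

#' Merge collinear placements into synteny blocks
#'
#' Within each (linkage group, chromosome) pair, placements sorted by
#' reference position are merged while the gap to the previous placement is
#' at most \code{syntenyMaxGapBp}. A block records its reference span, its
#' support count and the cM range of its members; single-hit blocks are
#' permitted. Merging is idempotent on its own output intervals.
#'
#' @param placements \code{\link{placeQueries}} output with
#'   \code{source_lg} (rows with NA source are dropped).
#' @param cfg a \linkS4class{PipelineConfig}.
#' @return data.frame \code{lg_id}, \code{chromosome}, \code{bp_start},
#'   \code{bp_end} (0-based half-open), \code{n_support}, \code{cM_start},
#'   \code{cM_end}.
#' @export
mergeSyntenyBlocks <- function(placements, cfg = pipelineConfig()) {
  pl <- placements[!is.na(placements$source_lg), , drop = FALSE]
  empty <- data.frame(lg_id = character(), chromosome = character(),
                      bp_start = numeric(), bp_end = numeric(),
                      n_support = integer(), cM_start = numeric(),
                      cM_end = numeric(), stringsAsFactors = FALSE)
  if (!nrow(pl)) return(empty)
  hasCm <- "source_cM" %in% names(pl)
  if (!hasCm) pl$source_cM <- NA_real_
  out <- list()
  for (grp in split(pl, list(pl$source_lg, pl$chromosome), drop = TRUE)) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    bstart <- grp$start[1]; bend <- grp$end[1]
    cms <- grp$source_cM[1]; n <- 1L
    flush <- function(acc) rbind(acc, data.frame(
      lg_id = grp$source_lg[1], chromosome = grp$chromosome[1],
      bp_start = bstart, bp_end = bend, n_support = n,
      cM_start = suppressWarnings(min(cms, na.rm = TRUE)),
      cM_end = suppressWarnings(max(cms, na.rm = TRUE)),
      stringsAsFactors = FALSE))
    acc <- NULL
    for (i in seq_len(nrow(grp))[-1]) {
      if (grp$start[i] - bend <= cfg@syntenyMaxGapBp) {
        bend <- max(bend, grp$end[i])
        cms <- c(cms, grp$source_cM[i]); n <- n + 1L
      } else {
        acc <- flush(acc)
        bstart <- grp$start[i]; bend <- grp$end[i]
        cms <- grp$source_cM[i]; n <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush(acc)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$lg_id, res$chromosome, res$bp_start), ]
  if (!hasCm) res$cM_start <- res$cM_end <- NA_real_
  rownames(res) <- NULL
  res
}

#' Detect candidate segmental loss
#'
#' For each linkage group assigned a homologous chromosome, the fraction of
#' that chromosome covered by the group's merged synteny blocks. Groups
#' covering less than \code{lossFlagFraction} of their chromosome are
#' flagged as candidate segmental loss; unassigned groups are reported with
#' fraction 0 and flagged.
#'
#' @param assignments \code{\link{assignLgHomology}} output.
#' @param placements \code{\link{placeQueries}} output with
#'   \code{source_lg}.
#' @param cfg a \linkS4class{PipelineConfig}.
#' @param chromLengths optional named numeric of chromosome lengths (bp);
#'   when absent the maximum placement end per chromosome is used (a
#'   documented underestimate).
#' @return data.frame \code{lg_id}, \code{chromosome}, \code{covered_bp},
#'   \code{chrom_bp}, \code{covered_fraction}, \code{flagged}.
#' @export
detectSegmentalLoss <- function(assignments, placements,
                                cfg = pipelineConfig(),
                                chromLengths = NULL) {
  if (is.null(chromLengths)) {
    chromLengths <- tapply(placements$end, placements$chromosome, max)
  }
  blocks <- mergeSyntenyBlocks(placements, cfg)
  out <- data.frame(lg_id = assignments$lg_id,
                    chromosome = assignments$chromosome,
                    covered_bp = 0, chrom_bp = NA_real_,
                    covered_fraction = 0, flagged = TRUE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    chr <- out$chromosome[i]
    if (is.na(chr)) next
    out$chrom_bp[i] <- chromLengths[[chr]]
    b <- blocks[blocks$lg_id == out$lg_id[i] & blocks$chromosome == chr, ]
    out$covered_bp[i] <- sum(b$bp_end - b$bp_start)
    out$covered_fraction[i] <- out$covered_bp[i] / out$chrom_bp[i]
    out$flagged[i] <- out$covered_fraction[i] < cfg@lossFlagFraction
  }
  out
}
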