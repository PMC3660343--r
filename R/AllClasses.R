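#' @import methods
NULL

#' Pipeline configuration
#'
#' Holds every numeric constant used across the mapping, anchoring,
#' integration and synteny stages. Create instances with
#' \code{\link{pipelineConfig}}.
#'
#' @slot lodGroupThreshold LOD threshold at which linkage groups are formed.
#' @slot lodSweep increasing vector of LOD thresholds for the diagnostic
#'   grouping sweep.
#' @slot maxRf maximum recombination fraction accepted as linkage evidence.
#' @slot distortionAlpha significance level of the segregation chi-square
#'   filter.
#' @slot ssrMinAlignBp minimum alignment length (bp) for a microsatellite
#'   marker to anchor a BAC-end sequence.
#' @slot snpMinAlignBp minimum alignment length (bp) for a SNP marker.
#' @slot minIdentityPct identity threshold (percent, strict) for anchoring
#'   alignments.
#' @slot evalueCutoff e-value cutoff for alignment hits.
#' @slot kbPerCb kilobases per consensus band (FPC physical-map length unit).
#' @slot bacInsertKb assumed insert length (kb) of a single BAC clone.
#' @slot syntenyMaxGapBp maximum reference-coordinate gap (bp) merged into
#'   one synteny block.
#' @slot homologyMinFraction minimum fraction of a linkage group's placed
#'   queries on its modal chromosome for a homology assignment.
#' @slot lossFlagFraction linkage groups covering less than this fraction of
#'   their homologous chromosome are flagged as candidate segmental loss.
#' @slot genomeMb assumed genome size (Mb) used for the coverage fraction.
#' @slot rngSeed integer seed recorded with the configuration.
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
  lodGroupThreshold = "numeric",
  lodSweep = "numeric",
  maxRf = "numeric",
  distortionAlpha = "numeric",
  ssrMinAlignBp = "numeric",
  snpMinAlignBp = "numeric",
  minIdentityPct = "numeric",
  evalueCutoff = "numeric",
  kbPerCb = "numeric",
  bacInsertKb = "numeric",
  syntenyMaxGapBp = "numeric",
  homologyMinFraction = "numeric",
  lossFlagFraction = "numeric",
  genomeMb = "numeric",
  rngSeed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!(object@maxRf > 0 && object@maxRf < 0.5))
    msg <- c(msg, "maxRf must lie in (0, 0.5)")
  if (object@kbPerCb <= 0) msg <- c(msg, "kbPerCb must be positive")
  pos <- c(object@lodGroupThreshold, object@distortionAlpha,
           object@ssrMinAlignBp, object@snpMinAlignBp, object@minIdentityPct,
           object@bacInsertKb, object@syntenyMaxGapBp, object@genomeMb)
  if (any(pos <= 0)) msg <- c(msg, "all thresholds must be positive")
  if (object@evalueCutoff <= 0) msg <- c(msg, "evalueCutoff must be positive")
  if (length(object@lodSweep) && any(diff(object@lodSweep) <= 0))
    msg <- c(msg, "lodSweep must be strictly increasing")
  if (!(object@homologyMinFraction > 0 && object@homologyMinFraction <= 1))
    msg <- c(msg, "homologyMinFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic CP-family / physical-map / reference-genome
#' generator. Create instances with \code{\link{simConfig}}.
#'
#' @slot nLgs number of linkage groups (must be even: the reference genome is
#'   diploid and every chromosome corresponds to exactly two linkage groups).
#' @slot meanLgCm mean linkage-group length in centimorgans.
#' @slot markersPerLg markers simulated per linkage group.
#' @slot nOffspring F1 family size.
#' @slot segtypeMix named proportions over the five CP segregation types.
#' @slot snpFraction fraction of markers emitted as SNPs (rest SSR).
#' @slot missingRate per-genotype missing-data probability.
#' @slot distortionFrac fraction of markers with injected segregation
#'   distortion.
#' @slot distortionBias probability with which the favoured parental allele
#'   is transmitted at a distorted marker.
#' @slot genotypingErrorRate per-genotype probability of replacing the true
#'   code by a random legal code.
#' @slot minSpacingCm minimum spacing between adjacent simulated markers.
#' @slot nContigs number of anchored physical-map contigs.
#' @slot cbLengthRange range (consensus bands) of contig lengths.
#' @slot clonesPerContigRange range of clone counts per contig.
#' @slot nSingletonBacs number of anchored singleton BAC clones.
#' @slot chimericFraction fraction of contigs made deliberately chimeric
#'   (carrying a BES from a second linkage group).
#' @slot besLengthBp length (bp) of simulated BAC-end sequences.
#' @slot ssrSeqLengthBp,snpSeqLengthBp lengths of simulated marker sequences.
#' @slot besErrorRate per-base substitution rate applied to marker copies
#'   embedded in BES.
#' @slot dupMarkerCount number of duplicated-marker pairs.
#' @slot dupIntraFraction fraction of duplicated pairs placed on a single
#'   linkage group (segmental-duplication-like) rather than on the two
#'   homoeologous groups.
#' @slot chromMb reference chromosome length (Mb).
#' @slot jitterBpSd standard deviation (bp) of placement jitter on the
#'   reference genome.
#' @slot lossFractions per-LG fraction of the homologous chromosome missing
#'   from the reference placements (recycled to nLgs).
#' @slot decoyRate fraction of BES additionally emitting an above-cutoff
#'   decoy hit.
#' @slot seed integer seed; all generators are deterministic given it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nLgs = "integer", meanLgCm = "numeric", markersPerLg = "integer",
  nOffspring = "integer", segtypeMix = "numeric", snpFraction = "numeric",
  missingRate = "numeric", distortionFrac = "numeric",
  distortionBias = "numeric", genotypingErrorRate = "numeric",
  minSpacingCm = "numeric",
  nContigs = "integer", cbLengthRange = "numeric",
  clonesPerContigRange = "numeric", nSingletonBacs = "integer",
  chimericFraction = "numeric", besLengthBp = "integer",
  ssrSeqLengthBp = "integer", snpSeqLengthBp = "integer",
  besErrorRate = "numeric",
  dupMarkerCount = "integer", dupIntraFraction = "numeric",
  chromMb = "numeric", jitterBpSd = "numeric", lossFractions = "numeric",
  decoyRate = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nLgs < 2 || object@nLgs %% 2L != 0L)
    msg <- c(msg, "nLgs must be an even number >= 2")
  if (abs(sum(object@segtypeMix) - 1) > 1e-8)
    msg <- c(msg, "segtypeMix proportions must sum to 1")
  if (!all(names(object@segtypeMix) %in% .CP_TYPES))
    msg <- c(msg, "segtypeMix names must be CP segregation types")
  if (any(c(object@markersPerLg, object@nOffspring, object@nContigs) < 1))
    msg <- c(msg, "all counts must be positive")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (any(object@lossFractions < 0 | object@lossFractions >= 1))
    msg <- c(msg, "lossFractions must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' CP-family genotype table
#'
#' Genotypes of an outbred F1 full-sib family. Rows of the code matrix are
#' markers, columns are offspring; codes come from the segregation type's
#' alphabet (e.g. \code{lm}/\code{ll}) with \code{"--"} for missing data.
#'
#' @slot familyName family label.
#' @slot info data.frame with one row per marker: \code{marker_id},
#'   \code{marker_type} ("SSR" or "SNP"), \code{segregation_type},
#'   \code{phase} (two characters from \code{0/1/-}, one per parent).
#' @slot codes character matrix (markers x offspring) of genotype codes.
#' @exportClass CPGenotypes
setClass("CPGenotypes", representation(
  familyName = "character",
  info = "data.frame",
  codes = "matrix"
))

setValidity("CPGenotypes", function(object) {
  msg <- character()
  info <- object@info
  need <- c("marker_id", "marker_type", "segregation_type", "phase")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(info) != nrow(object@codes))
    msg <- c(msg, "info rows and code-matrix rows differ")
  if (anyDuplicated(info$marker_id))
    msg <- c(msg, "marker ids must be unique")
  if (!all(info$segregation_type %in% .CP_TYPES))
    msg <- c(msg, "unknown segregation type present")
  if (ncol(object@codes) < 1) msg <- c(msg, "family must have offspring")
  if (!length(msg)) {
    for (i in seq_len(nrow(info))) {
      alpha <- .CP_ALPHABET[[info$segregation_type[i]]]
      bad <- !(object@codes[i, ] %in% c(alpha, .MISSING_CODE))
      if (any(bad)) {
        msg <- c(msg, sprintf(
          "marker %s: illegal code(s) %s for type %s", info$marker_id[i],
          paste(unique(object@codes[i, bad]), collapse = ","),
          info$segregation_type[i]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' FPC-style physical map
#'
#' Contigs of fingerprinted BAC clones with consensus-band (CB) lengths, plus
#' clones left as singletons.
#'
#' @slot contigs data.frame with columns \code{contig_id},
#'   \code{cb_length} (integer CB units) and list column \code{clone_ids}.
#' @slot singletons character vector of singleton clone ids.
#' @exportClass PhysicalMap
setClass("PhysicalMap", representation(
  contigs = "data.frame",
  singletons = "character"
))

setValidity("PhysicalMap", function(object) {
  msg <- character()
  ct <- object@contigs
  if (!all(c("contig_id", "cb_length", "clone_ids") %in% names(ct)))
    return("contigs needs columns contig_id, cb_length, clone_ids")
  if (nrow(ct)) {
    if (anyDuplicated(ct$contig_id)) msg <- c(msg, "duplicate contig ids")
    if (any(ct$cb_length < 1)) msg <- c(msg, "cb_length must be >= 1")
    if (any(lengths(ct$clone_ids) == 0))
      msg <- c(msg, "every contig needs at least one clone")
    members <- unlist(ct$clone_ids, use.names = FALSE)
    if (anyDuplicated(members))
      msg <- c(msg, "a clone appears in two contigs")
    if (length(intersect(members, object@singletons)))
      msg <- c(msg, "singletons overlap contig members")
  }
  if (length(msg)) msg else TRUE
})

#' Genetic linkage map
#'
#' Ordered linkage groups with cumulative Kosambi positions, plus the markers
#' excluded from mapping and why.
#'
#' @slot lgs data.frame with columns \code{lg_id}, \code{marker_id},
#'   \code{position_cM}; positions are nondecreasing within a group and
#'   start at 0.
#' @slot excluded data.frame with columns \code{marker_id}, \code{reason}
#'   ("distorted" or "unlinked").
#' @exportClass GeneticMap
setClass("GeneticMap", representation(
  lgs = "data.frame",
  excluded = "data.frame"
))

setValidity("GeneticMap", function(object) {
  msg <- character()
  lg <- object@lgs
  if (!all(c("lg_id", "marker_id", "position_cM") %in% names(lg)))
    return("lgs needs columns lg_id, marker_id, position_cM")
  if (nrow(lg)) {
    if (anyDuplicated(lg$marker_id)) msg <- c(msg, "marker mapped twice")
    for (g in split(lg$position_cM, lg$lg_id)) {
      if (g[1] != 0) { msg <- c(msg, "first position in a group must be 0"); break }
      if (is.unsorted(g)) { msg <- c(msg, "positions must be nondecreasing"); break }
    }
  }
  if (nrow(object@excluded) &&
      length(intersect(object@excluded$marker_id, lg$marker_id)))
    msg <- c(msg, "a marker is both mapped and excluded")
  if (length(msg)) msg else TRUE
})

#' Simulated ground truth genome
#'
#' The latent structure behind one synthetic dataset: marker positions on
#' linkage groups, contig placements, the 2:1 LG-to-reference-chromosome
#' homology, segmental-loss intervals and duplicated-marker pairs.
#'
#' @slot lgs data.frame \code{lg_id}, \code{length_cM}.
#' @slot markers data.frame \code{marker_id}, \code{lg_id},
#'   \code{position_cM}, \code{segregation_type}, \code{marker_type}.
#' @slot contigPlacements data.frame \code{contig_id}, \code{lg_id},
#'   \code{anchor_marker}, \code{cM_anchor}, \code{cb_length},
#'   \code{chimeric}, \code{second_marker}.
#' @slot bacPlacements data.frame \code{clone_id}, \code{lg_id},
#'   \code{anchor_marker}, \code{cM_anchor} for singleton BACs.
#' @slot homology named character, linkage group -> reference chromosome.
#' @slot lossIntervals data.frame \code{lg_id}, \code{start_frac},
#'   \code{frac}: fraction of the homologous chromosome unrepresented.
#' @slot dupPairs data.frame \code{base_id}, \code{lg_a}, \code{lg_b}.
#' @exportClass TrueGenome
setClass("TrueGenome", representation(
  lgs = "data.frame",
  markers = "data.frame",
  contigPlacements = "data.frame",
  bacPlacements = "data.frame",
  homology = "character",
  lossIntervals = "data.frame",
  dupPairs = "data.frame"
))

setValidity("TrueGenome", function(object) {
  msg <- character()
  tab <- table(object@homology)
  if (length(tab) && any(tab != 2))
    msg <- c(msg, "every reference chromosome must host exactly two LGs")
  for (g in split(object@markers$position_cM, object@markers$lg_id)) {
    if (g[1] != 0 || is.unsorted(g)) {
      msg <- c(msg, "marker positions must start at 0 and be nondecreasing")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Integrated genetic-physical map
#'
#' Physical-map contigs and single BACs attached to linkage-group positions
#' through their anchoring markers.
#'
#' @slot anchors data.frame, one row per (linkage group, element, marker):
#'   \code{lg_id}, \code{position_cM}, \code{marker_id}, \code{element_kind}
#'   ("contig"/"single_bac"), \code{element_id}, \code{length_kb},
#'   \code{orientation}, \code{conflict}.
#' @slot unplacedMarkers character: anchored markers absent from the genetic
#'   map.
#' @exportClass IntegratedMap
setClass("IntegratedMap", representation(
  anchors = "data.frame",
  unplacedMarkers = "character"
))

setValidity("IntegratedMap", function(object) {
  a <- object@anchors
  need <- c("lg_id", "position_cM", "marker_id", "element_kind",
            "element_id", "length_kb", "orientation", "conflict")
  if (!all(need %in% names(a)))
    return(paste("anchors needs columns:", paste(need, collapse = ", ")))
  if (nrow(a) && !all(a$element_kind %in% c("contig", "single_bac")))
    return("element_kind must be contig or single_bac")
  TRUE
})
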