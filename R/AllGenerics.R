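#' @include AllClasses.R
NULL

#' Accessors for carpmap containers
#'
#' Small accessor generics used across the package's S4 containers.
#'
#' @param x a carpmap object.
#' @return \code{nMarkers}/\code{nOffspring}: integer counts;
#'   \code{markerIds}: character vector; \code{segregationTypes}: named
#'   character vector; \code{genotypeCodes}: character matrix;
#'   \code{markerInfo}, \code{contigTable}, \code{lgTable},
#'   \code{excludedMarkers}, \code{anchorTable}: data.frames;
#'   \code{singletonClones}: character vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setGeneric("nOffspring", function(x) standardGeneric("nOffspring"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("segregationTypes", function(x) standardGeneric("segregationTypes"))
#' @rdname accessors
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))
#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname accessors
#' @export
setGeneric("contigTable", function(x) standardGeneric("contigTable"))
#' @rdname accessors
#' @export
setGeneric("singletonClones", function(x) standardGeneric("singletonClones"))
#' @rdname accessors
#' @export
setGeneric("lgTable", function(x) standardGeneric("lgTable"))
#' @rdname accessors
#' @export
setGeneric("excludedMarkers", function(x) standardGeneric("excludedMarkers"))
#' @rdname accessors
#' @export
setGeneric("anchorTable", function(x) standardGeneric("anchorTable"))

#' @rdname accessors
setMethod("nMarkers", "CPGenotypes", function(x) nrow(x@info))
#' @rdname accessors
setMethod("nOffspring", "CPGenotypes", function(x) ncol(x@codes))
#' @rdname accessors
setMethod("markerIds", "CPGenotypes", function(x) x@info$marker_id)
#' @rdname accessors
setMethod("segregationTypes", "CPGenotypes", function(x)
  stats::setNames(x@info$segregation_type, x@info$marker_id))
#' @rdname accessors
setMethod("genotypeCodes", "CPGenotypes", function(x) x@codes)
#' @rdname accessors
setMethod("markerInfo", "CPGenotypes", function(x) x@info)
#' @rdname accessors
setMethod("contigTable", "PhysicalMap", function(x) x@contigs)
#' @rdname accessors
setMethod("singletonClones", "PhysicalMap", function(x) x@singletons)
#' @rdname accessors
setMethod("lgTable", "GeneticMap", function(x) x@lgs)
#' @rdname accessors
setMethod("excludedMarkers", "GeneticMap", function(x) x@excluded)
#' @rdname accessors
setMethod("markerIds", "GeneticMap", function(x) x@lgs$marker_id)
#' @rdname accessors
setMethod("anchorTable", "IntegratedMap", function(x) x@anchors)

setMethod("show", "CPGenotypes", function(object) {
  cat(sprintf("CPGenotypes '%s': %d markers x %d offspring\n",
              object@familyName, nMarkers(object), nOffspring(object)))
  tab <- table(object@info$segregation_type)
  cat("  segregation types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "PhysicalMap", function(object) {
  cat(sprintf("PhysicalMap: %d contigs (%s CB), %d singleton clones\n",
              nrow(object@contigs),
              format(sum(object@contigs$cb_length), big.mark = ","),
              length(object@singletons)))
})

setMethod("show", "GeneticMap", function(object) {
  n <- length(unique(object@lgs$lg_id))
  cat(sprintf("GeneticMap: %d markers on %d linkage groups (%.1f cM), %d excluded\n",
              nrow(object@lgs), n,
              sum(vapply(split(object@lgs$position_cM, object@lgs$lg_id),
                         max, 0)),
              nrow(object@excluded)))
})

setMethod("show", "IntegratedMap", function(object) {
  a <- object@anchors
  cat(sprintf(
    "IntegratedMap: %d contigs + %d single BACs on %d linkage groups\n",
    length(unique(a$element_id[a$element_kind == "contig"])),
    length(unique(a$element_id[a$element_kind == "single_bac"])),
    length(unique(a$lg_id))))
  if (length(object@unplacedMarkers))
    cat("  unplaced anchored markers:", length(object@unplacedMarkers), "\n")
})

setMethod("show", "TrueGenome", function(object) {
  cat(sprintf(
    "TrueGenome: %d LGs, %d markers, %d contigs, %d reference chromosomes\n",
    nrow(object@lgs), nrow(object@markers), nrow(object@contigPlacements),
    length(unique(object@homology))))
})
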