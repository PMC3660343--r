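#' Read a CP-family genotype file
#'
#' Parses the package's plain-text CP genotype dialect, a simplified
#' reconstruction of the classic outbred full-sib ("CP") input format: four
#' header lines \code{name = <family>}, \code{popt = CP}, \code{nloc = <n>},
#' \code{nind = <n>}, followed by one tab-separated line per marker:
#' \code{marker_id<TAB>(segtype)<TAB>phase<TAB>code1 code2 ... codeN}.
#' The phase field carries one character per parent from \code{0/1/-}
#' (\code{--} when unknown). Genotype codes must belong to the segregation
#' type's alphabet; missing data is \code{--}. A marker id ending in
#' \code{_SNP} is typed as SNP, all others as SSR.
#'
#' @param path file path.
#' @return A \linkS4class{CPGenotypes} object.
#' @seealso \code{\link{writeGenotypes}}
#' @export
readGenotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 4) stop("truncated genotype file: ", path)
  hdr <- function(i, key) {
    m <- regmatches(lines[i], regexec(paste0("^", key, "\\s*=\\s*(\\S+)"),
                                      lines[i]))[[1]]
    if (length(m) < 2)
      stop(sprintf("line %d: expected header '%s = ...'", i, key))
    m[2]
  }
  family <- hdr(1, "name")
  popt <- hdr(2, "popt")
  if (popt != "CP") stop("line 2: only popt = CP is supported, got ", popt)
  nloc <- as.integer(hdr(3, "nloc"))
  nind <- as.integer(hdr(4, "nind"))
  body <- lines[-(1:4)]
  if (length(body) != nloc)
    stop(sprintf("header says nloc = %d but file has %d marker lines",
                 nloc, length(body)))
  info <- data.frame(marker_id = character(nloc), marker_type = "SSR",
                     segregation_type = character(nloc),
                     phase = character(nloc), stringsAsFactors = FALSE)
  codes <- matrix("", nrow = nloc, ncol = nind)
  for (i in seq_len(nloc)) {
    lineno <- i + 4L
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop(sprintf("line %d: expected 4 tab-separated fields, got %d",
                   lineno, length(f)))
    seg <- sub("^<(.*)>$", "\\1", f[2])
    if (!seg %in% .CP_TYPES)
      stop(sprintf("line %d: unknown segregation type '%s'", lineno, f[2]))
    g <- strsplit(trimws(f[4]), "\\s+")[[1]]
    if (length(g) != nind)
      stop(sprintf("line %d: expected %d genotype codes, found %d",
                   lineno, nind, length(g)))
    bad <- !(g %in% c(.CP_ALPHABET[[seg]], .MISSING_CODE))
    if (any(bad))
      stop(sprintf("line %d: illegal code '%s' for segregation type %s",
                   lineno, g[which(bad)[1]], seg))
    info$marker_id[i] <- f[1]
    info$marker_type[i] <- if (grepl("_SNP$", f[1])) "SNP" else "SSR"
    info$segregation_type[i] <- seg
    info$phase[i] <- f[3]
    codes[i, ] <- g
  }
  if (anyDuplicated(info$marker_id))
    stop("duplicate marker id: ",
         info$marker_id[duplicated(info$marker_id)][1])
  rownames(codes) <- info$marker_id
  new("CPGenotypes", familyName = family, info = info, codes = codes)
}

#' Write a CP-family genotype file
#'
#' Inverse of \code{\link{readGenotypes}}; emits the dialect bit-exactly so
#' that a write/read cycle is an identity.
#'
#' @param gt a \linkS4class{CPGenotypes} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(gt, path) {
  stopifnot(is(gt, "CPGenotypes"))
  hdr <- c(paste("name =", gt@familyName), "popt = CP",
           paste("nloc =", nMarkers(gt)), paste("nind =", nOffspring(gt)))
  rows <- vapply(seq_len(nMarkers(gt)), function(i) {
    paste(gt@info$marker_id[i],
          paste0("<", gt@info$segregation_type[i], ">"),
          gt@info$phase[i],
          paste(gt@codes[i, ], collapse = " "),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a physical-map contig table
#'
#' Tab-separated file with columns \code{contig_id}, \code{cb_length},
#' \code{clone_ids} (semicolon-separated); singleton clones are listed on
#' rows whose contig_id is \code{SINGLETON} (cb_length ignored). A header
#' row is required.
#'
#' @param path file path.
#' @return A \linkS4class{PhysicalMap}.
#' @export
readPhysicalMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("contig_id", "cb_length", "clone_ids") %in% names(tab)))
    stop("physical map TSV needs columns contig_id, cb_length, clone_ids")
  single <- tab$contig_id == "SINGLETON"
  singles <- unlist(strsplit(tab$clone_ids[single], ";", fixed = TRUE))
  ct <- tab[!single, , drop = FALSE]
  cb <- suppressWarnings(as.numeric(ct$cb_length))
  if (nrow(ct) && any(is.na(cb) | cb != round(cb)))
    stop("non-integer cb_length for contig ",
         ct$contig_id[which(is.na(cb) | cb != round(cb))[1]])
  contigs <- data.frame(contig_id = ct$contig_id,
                        cb_length = as.integer(round(cb)),
                        stringsAsFactors = FALSE)
  contigs$clone_ids <- strsplit(ct$clone_ids, ";", fixed = TRUE)
  new("PhysicalMap", contigs = contigs,
      singletons = as.character(singles))
}

#' Write a physical-map contig table
#'
#' @param pm a \linkS4class{PhysicalMap}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePhysicalMap <- function(pm, path) {
  stopifnot(is(pm, "PhysicalMap"))
  ct <- pm@contigs
  out <- data.frame(
    contig_id = ct$contig_id,
    cb_length = ct$cb_length,
    clone_ids = vapply(ct$clone_ids, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  if (length(pm@singletons))
    out <- rbind(out, data.frame(
      contig_id = "SINGLETON", cb_length = 0L,
      clone_ids = paste(pm@singletons, collapse = ";")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.BLAST_COLS <- c("query_id", "subject_id", "identity_pct", "align_len",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read 12-column tabular alignment output
#'
#' Standard BLAST tabular format (outfmt 6): qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore. The subject
#' strand is inferred from the coordinate order (\code{sstart > send}
#' means minus).
#'
#' @param path file path.
#' @return data.frame of hits with an extra \code{strand} column; zero rows
#'   for an empty file.
#' @export
readBlastTab <- function(path) {
  empty <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, .BLAST_COLS)))
  if (file.size(path) == 0) {
    empty$strand <- character(0)
    return(empty)
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12)
    stop("expected 12 tab-separated columns, found ", ncol(tab))
  names(tab) <- .BLAST_COLS
  tab$strand <- ifelse(tab$sstart > tab$send, "-", "+")
  tab
}

#' Write hits as 12-column tabular alignment output
#'
#' @param hits data.frame with the 12 standard columns (extra columns such
#'   as \code{strand} are dropped).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBlastTab <- function(hits, path) {
  utils::write.table(hits[, .BLAST_COLS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Decompose BAC-end-sequence ids
#'
#' BES ids have the form \code{CLONE.f} / \code{CLONE.r} (forward/reverse
#' end of the clone insert).
#'
#' @param bes_ids character vector of BES ids.
#' @return data.frame with columns \code{bes_id}, \code{clone_id},
#'   \code{end}.
#' @examples
#' besTable(c("CYC037J02.r", "CYC054K09.f"))
#' @export
besTable <- function(bes_ids) {
  ok <- grepl("\\.[fr]$", bes_ids)
  if (!all(ok))
    stop("BES id without .f/.r suffix: ", bes_ids[!ok][1])
  data.frame(bes_id = bes_ids,
             clone_id = sub("\\.[fr]$", "", bes_ids),
             end = sub("^.*\\.", "", bes_ids),
             stringsAsFactors = FALSE)
}
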