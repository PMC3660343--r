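test_that("seed-and-extend aligner finds embedded queries exactly", {
  set.seed(9)
  host <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  q <- substr(host, 101, 300)   # 200 bp embedded verbatim
  bes <- Biostrings::DNAStringSet(c(CL1.f = host))
  hits <- naiveAlign(c(m1 = q), bes)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity_pct, 100)
  expect_equal(hits$align_len, 200L)
  expect_equal(hits$sstart, 101L)
  expect_equal(hits$send, 300L)

  # absent query: no hits
  absent <- paste(rep("ACGTT", 40), collapse = "")
  expect_equal(nrow(naiveAlign(c(m2 = absent), bes)), 0L)

  # 3 substitutions in 200 bp -> 98.5% identity
  qm <- q
  for (p in c(50, 100, 150)) {
    old <- substr(qm, p, p)
    substr(qm, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  hm <- naiveAlign(c(m3 = qm), bes)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$identity_pct, 98.5)
  expect_equal(hm$mismatch, 3L)

  # reverse-complement embedding is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  hr <- naiveAlign(stats::setNames(rc, "m4"), bes)
  expect_equal(hr$strand, "-")
  expect_true(hr$sstart > hr$send)

  expect_error(naiveAlign(c(bad = ""), bes), "empty")
})

test_that("anchoring thresholds follow the stated boundary semantics", {
  mk <- function(len, id, ev = 0) data.frame(
    query_id = "m", subject_id = "CL1.f", identity_pct = id,
    align_len = len, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
    sstart = 1L, send = len, evalue = ev, bitscore = 2 * len,
    stringsAsFactors = FALSE)
  cfg <- pipelineConfig()
  f <- filterAnchorHits(mk(160, 96), c(m = "SSR"), cfg)
  expect_true(f$accepted)
  f <- filterAnchorHits(mk(150, 96), c(m = "SSR"), cfg)
  expect_true(f$accepted)                       # "larger than 150" read >= 150
  f <- filterAnchorHits(mk(140, 99), c(m = "SSR"), cfg)
  expect_equal(f$reject_reason, "below_length")
  f <- filterAnchorHits(mk(100, 95.0), c(m = "SNP"), cfg)
  expect_equal(f$reject_reason, "below_identity")  # strict > 95
  f <- filterAnchorHits(mk(100, 96), c(m = "SNP"), cfg)
  expect_true(f$accepted)
  f <- filterAnchorHits(mk(160, 96, ev = 1e-3), c(m = "SSR"), cfg)
  expect_equal(f$reject_reason, "above_evalue")
})

test_that("filtering is monotone in the SSR length threshold", {
  set.seed(10)
  hits <- data.frame(
    query_id = sprintf("m%02d", 1:40),
    subject_id = "CL1.f",
    identity_pct = round(stats::runif(40, 90, 100), 2),
    align_len = sample(80:260, 40, TRUE), mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 1L, sstart = 1L, send = 2L,
    evalue = 0, bitscore = stats::runif(40, 50, 500),
    stringsAsFactors = FALSE)
  prev <- NULL
  for (thr in c(100, 150, 200, 250)) {
    cfg <- pipelineConfig(ssrMinAlignBp = thr)
    acc <- hits$query_id[filterAnchorHits(hits, NULL, cfg)$accepted]
    if (!is.null(prev)) expect_true(all(acc %in% prev))
    prev <- acc
  }
})

test_that("targets resolve to contigs and singleton BACs; ties are flagged", {
  pm <- new("PhysicalMap",
            contigs = {
              ct <- data.frame(contig_id = c("ctg1", "ctg2"),
                               cb_length = c(100L, 200L))
              ct$clone_ids <- list(c("CLA", "CLB"), "CLC")
              ct
            },
            singletons = "SBC1")
  mk <- function(q, s, score) data.frame(
    query_id = q, subject_id = s, identity_pct = 100, align_len = 200L,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 200L, sstart = 1L,
    send = 200L, evalue = 0, bitscore = score, accepted = TRUE,
    reject_reason = "none", stringsAsFactors = FALSE)
  filt <- rbind(mk("m1", "CLA.f", 400), mk("m2", "SBC1.r", 400),
                mk("m3", "CLA.f", 400), mk("m3", "CLC.f", 400),
                mk("m4", "NOPE.f", 400))
  res <- resolveTargets(filt, pm)
  expect_equal(res$target_kind[res$marker_id == "m1"], "contig")
  expect_equal(res$target_id[res$marker_id == "m1"], "ctg1")
  expect_equal(res$target_kind[res$marker_id == "m2"], "single_bac")
  expect_false("m3" %in% res$marker_id)         # tie across two contigs
  expect_true("m3" %in% attr(res, "ambiguous"))
  expect_true("NOPE.f" %in% attr(res, "unresolved"))
})

test_that("anchoring on clean synthetic data has perfect recall and precision", {
  cfg <- tinySimConfig(12L, chimericFraction = 0)
  g <- simulateTrueGenome(cfg)
  phys <- simulatePhysicalBES(g, cfg)
  hits <- naiveAlign(phys$markerSeqs, phys$bes)
  types <- stats::setNames(g@markers$marker_type, g@markers$marker_id)
  filt <- filterAnchorHits(hits, types, pipelineConfig())
  res <- resolveTargets(filt, phys$physicalMap)
  got <- unique(res[, c("marker_id", "target_id")])
  truth <- unique(phys$truth[, c("marker_id", "target_id")])
  expect_setequal(paste(got$marker_id, got$target_id),
                  paste(truth$marker_id, truth$target_id))
})

test_that("microsatellite locus screen enforces size, motif and flank rules", {
  # repeat-free filler (period 9, no perfect 2-4 bp repeat of 12+ bp)
  flank <- function(n) substr(strrep("ACGGTCATT", ceiling(n / 9)), 1, n)
  ca10 <- paste(rep("CA", 10), collapse = "")
  good <- paste0(flank(80), ca10, flank(100))       # 200 bp, centred motif
  edge <- paste0(substr(flank(10), 1, 10), ca10, flank(180))
  pm <- new("PhysicalMap",
            contigs = {
              ct <- data.frame(contig_id = c("big", "small"),
                               cb_length = c(800L, 600L))  # 1142 kb / 857 kb
              ct$clone_ids <- list("CLX", "CLY")
              ct
            }, singletons = character(0))
  bes <- c(CLX.f = good, CLX.r = edge, CLY.f = good)
  loci <- selectCandidateLoci(pm, bes, pipelineConfig())
  expect_true(all(loci$contig_id == "big"))         # 0.86 Mb contig excluded
  expect_true("CLX.f" %in% loci$bes_id)
  expect_false("CLX.r" %in% loci$bes_id)            # < 50 bp left flank
  expect_equal(loci$unit[loci$bes_id == "CLX.f"], "CA")

  # homopolymer-period units are not microsatellites here
  mono <- paste0(flank(80), strrep("AA", 10), flank(80))
  expect_equal(nrow(carpmap:::.findSSRMotifs(mono)), 0L)
})
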