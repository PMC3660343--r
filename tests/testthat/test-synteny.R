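mkHit <- function(q, chr, s, e, ev, score) {
  data.frame(query_id = q, subject_id = chr, identity_pct = 98,
             align_len = abs(e - s) + 1L, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = 100L, sstart = s, send = e, evalue = ev,
             bitscore = score, stringsAsFactors = FALSE)
}

test_that("placement keeps one sub-cutoff top hit with deterministic ties", {
  hits <- rbind(mkHit("q1", "chr1", 100, 300, 1e-3, 80),
                mkHit("q1", "chr2", 500, 700, 1e-8, 200),
                mkHit("q2", "chr2", 10, 100, 1e-9, 150),
                mkHit("q2", "chr5", 900, 990, 1e-9, 150),
                mkHit("q3", "chr3", 100, 1, 1e-9, 99))
  pl <- placeQueries(hits, pipelineConfig())
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$chromosome[pl$query_id == "q1"], "chr2")   # e-3 dropped
  expect_equal(pl$chromosome[pl$query_id == "q2"], "chr2")   # tie -> chr2
  # 0-based half-open conversion and strand
  expect_equal(pl$start[pl$query_id == "q3"], 0)
  expect_equal(pl$end[pl$query_id == "q3"], 100)
  expect_equal(pl$strand[pl$query_id == "q3"], "-")
})

test_that("homology assignment uses the modal chromosome and a fraction floor", {
  pl <- data.frame(query_id = sprintf("q%02d", 1:13),
                   chromosome = c(rep("chr1", 8), rep("chr5", 2),
                                  rep("chr2", 3)),
                   start = 0, end = 100, strand = "+", evalue = 1e-9,
                   bitscore = 100,
                   source_lg = c(rep("LG1", 10), rep("LG2", 3)),
                   stringsAsFactors = FALSE)
  hom <- assignLgHomology(pl, pipelineConfig())
  expect_equal(hom$chromosome[hom$lg_id == "LG1"], "chr1")
  expect_equal(hom$fraction[hom$lg_id == "LG1"], 0.8)
  expect_true(hom$assigned[hom$lg_id == "LG2"])
  tto <- attr(hom, "two_to_one")
  expect_false(any(tto$is_two_to_one))          # one LG per chromosome here
})

test_that("block merging follows the gap rule and is idempotent", {
  mkPl <- function(s, e) data.frame(
    query_id = sprintf("b%02d", seq_along(s)), chromosome = "chr1",
    start = s, end = e, strand = "+", evalue = 1e-9, bitscore = 100,
    source_lg = "LG1", source_cM = seq_along(s) * 10,
    stringsAsFactors = FALSE)
  cfg <- pipelineConfig()
  one <- mergeSyntenyBlocks(mkPl(c(1.0e6, 1.5e6, 2.2e6) - 1,
                                 c(1.0e6, 1.5e6, 2.2e6) + 499), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_support, 3L)
  expect_equal(one$cM_start, 10); expect_equal(one$cM_end, 30)

  two <- mergeSyntenyBlocks(mkPl(c(1.0e6, 5.0e6), c(1.0e6 + 499, 5.0e6 + 499)),
                            cfg)
  expect_equal(nrow(two), 2L)

  single <- mergeSyntenyBlocks(mkPl(1e6, 1e6 + 499), cfg)
  expect_equal(single$bp_end - single$bp_start, 499)   # the hit's own span

  # idempotence: merging the block intervals again changes nothing
  asPl <- data.frame(query_id = sprintf("x%d", seq_len(nrow(two))),
                     chromosome = two$chromosome, start = two$bp_start,
                     end = two$bp_end, strand = "+", evalue = 1e-9,
                     bitscore = 1, source_lg = two$lg_id,
                     source_cM = two$cM_start, stringsAsFactors = FALSE)
  again <- mergeSyntenyBlocks(asPl, cfg)
  expect_equal(again$bp_start, two$bp_start)
  expect_equal(again$bp_end, two$bp_end)
})

test_that("support totals are conserved and block counts are monotone in the gap", {
  set.seed(15)
  pl <- data.frame(query_id = sprintf("q%03d", 1:60),
                   chromosome = sample(c("chr1", "chr2"), 60, TRUE),
                   start = sort(sample(1:5e6, 60)), strand = "+",
                   evalue = 1e-9, bitscore = 100,
                   source_lg = sample(c("LG1", "LG2"), 60, TRUE),
                   stringsAsFactors = FALSE)
  pl$end <- pl$start + 400
  pl$source_cM <- stats::runif(60, 0, 80)
  prev <- Inf
  for (gap in c(2e6, 1e6, 2e5, 1e4)) {
    bl <- mergeSyntenyBlocks(pl, pipelineConfig(syntenyMaxGapBp = gap))
    expect_equal(sum(bl$n_support), nrow(pl))
    agg <- tapply(bl$n_support, bl$lg_id, sum)
    cnt <- table(pl$source_lg)
    expect_equal(as.integer(agg[names(cnt)]), as.integer(cnt))
    expect_gte(nrow(bl), ifelse(is.finite(prev), prev, 0))
    prev <- nrow(bl)
  }
})

test_that("segmental loss flags low chromosome coverage", {
  cfg <- simConfig(nLgs = 2L, markersPerLg = 12L, nContigs = 16L,
                   nSingletonBacs = 6L, dupMarkerCount = 0L,
                   clonesPerContigRange = c(6, 10),
                   lossFractions = c(0.5, 0), decoyRate = 0, seed = 16L)
  g <- simulateTrueGenome(cfg)
  phys <- simulatePhysicalBES(g, cfg)
  hits <- simulateReferencePlacements(g, phys, cfg)
  src <- data.frame(query_id = phys$besInfo$bes_id,
                    lg_id = phys$besInfo$lg_id, cM = phys$besInfo$cM)
  pl <- placeQueries(hits, pipelineConfig(), sourceMap = src)
  hom <- assignLgHomology(pl, pipelineConfig())
  chromLen <- stats::setNames(cfg@chromMb * 1e6, unique(g@homology))
  loss <- detectSegmentalLoss(hom, pl, pipelineConfig(), chromLen)
  l1 <- loss[loss$lg_id == "LG1", ]
  l2 <- loss[loss$lg_id == "LG2", ]
  expect_lt(l1$covered_fraction, 0.65)   # half the chromosome is lost
  expect_gt(l1$covered_fraction, 0.2)
  expect_true(l1$flagged)
  expect_gte(l2$covered_fraction, 0.8)
  expect_false(l2$flagged)

  # a group with no placements is reported flagged at fraction 0
  empty <- data.frame(lg_id = "LG9", chromosome = NA_character_,
                      supporting_hits = 0L, n_placed = 0L,
                      fraction = NA_real_, assigned = FALSE)
  l0 <- detectSegmentalLoss(empty, pl, pipelineConfig(), chromLen)
  expect_equal(l0$covered_fraction, 0)
  expect_true(l0$flagged)
})
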