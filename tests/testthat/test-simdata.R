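test_that("true-genome generator: counts, homology pairing, determinism", {
  cfg <- simConfig(nLgs = 2L, markersPerLg = 3L, nContigs = 2L,
                   nSingletonBacs = 1L, dupMarkerCount = 0L, seed = 1L)
  g <- simulateTrueGenome(cfg)
  expect_equal(nrow(g@lgs), 2L)
  expect_equal(nrow(g@markers), 6L)
  expect_equal(length(unique(g@homology)), 1L)

  g2 <- simulateTrueGenome(cfg)
  expect_identical(g@markers, g2@markers)
  expect_identical(g@contigPlacements, g2@contigPlacements)

  cfg10 <- simConfig(seed = 2L)
  g10 <- simulateTrueGenome(cfg10)
  tab <- table(g10@homology)
  expect_length(tab, 5L)
  expect_true(all(tab == 2L))
  # positions start at 0, nondecreasing (validity)
  expect_true(validObject(g10))
})

test_that("zero-cM markers co-segregate perfectly", {
  g <- new("TrueGenome",
           lgs = data.frame(lg_id = "LG1", length_cM = 0),
           markers = data.frame(marker_id = c("x1", "x2"), lg_id = "LG1",
                                position_cM = c(0, 0),
                                segregation_type = "lmxll",
                                marker_type = "SSR",
                                stringsAsFactors = FALSE),
           contigPlacements = data.frame(), bacPlacements = data.frame(),
           homology = c(LG1 = "chr1", LG2 = "chr1"),
           lossIntervals = data.frame(), dupPairs = data.frame())
  cfg <- simConfig(nOffspring = 200L, missingRate = 0, distortionFrac = 0,
                   seed = 3L)
  gt <- simulateCPFamily(g, cfg)
  a <- genotypeCodes(gt)[1, ]; b <- genotypeCodes(gt)[2, ]
  # identical or complementary depending on the random phases
  expect_true(all(a == b) || all(a != b))
})

test_that("adjacent recombination matches the inverse Kosambi of the gap", {
  g <- new("TrueGenome",
           lgs = data.frame(lg_id = "LG1", length_cM = 20),
           markers = data.frame(marker_id = c("x1", "x2"), lg_id = "LG1",
                                position_cM = c(0, 20),
                                segregation_type = "abxcd",
                                marker_type = "SSR",
                                stringsAsFactors = FALSE),
           contigPlacements = data.frame(), bacPlacements = data.frame(),
           homology = c(LG1 = "chr1", LG2 = "chr1"),
           lossIntervals = data.frame(), dupPairs = data.frame())
  cfg <- simConfig(nOffspring = 10000L, missingRate = 0,
                   distortionFrac = 0, seed = 4L)
  gt <- simulateCPFamily(g, cfg)
  est <- estimateRF(gt, "x1", "x2")
  expect_equal(est$rf, inverseKosambi(20), tolerance = 0.01)  # 0.18997
})

test_that("family generator respects alphabets, missingness and distortion power", {
  cfg <- simConfig(nLgs = 2L, markersPerLg = 10L, nContigs = 4L,
                   nSingletonBacs = 2L, dupMarkerCount = 0L,
                   missingRate = 0.05, distortionFrac = 0.2, seed = 5L)
  g <- simulateTrueGenome(cfg)
  gt <- simulateCPFamily(g, cfg)
  info <- markerInfo(gt)
  for (i in seq_len(nMarkers(gt))) {
    alpha <- c(carpmap:::.CP_ALPHABET[[info$segregation_type[i]]], "--")
    expect_true(all(genotypeCodes(gt)[i, ] %in% alpha))
  }
  expect_equal(mean(genotypeCodes(gt) == "--"), 0.05, tolerance = 0.02)
  # 4 of 20 markers distorted at bias 0.75: most must fail the chi-square
  seg <- segregationTest(gt)
  expect_gte(sum(seg$p < 0.01), 2L)
})

test_that("BES ids are well-formed and anchors embed marker sequences", {
  cfg <- tinySimConfig(6L, chimericFraction = 0.5)
  g <- simulateTrueGenome(cfg)
  phys <- simulatePhysicalBES(g, cfg)
  expect_true(all(grepl("\\.[fr]$", names(phys$bes))))
  bt <- besTable(names(phys$bes))
  members <- unlist(contigTable(phys$physicalMap)$clone_ids)
  expect_true(all(bt$clone_id %in%
                    c(members, singletonClones(phys$physicalMap))))
  expect_equal(sum(g@contigPlacements$chimeric),
               round(0.5 * cfg@nContigs))
  # every truth anchor's marker sequence occurs verbatim in some BES
  seqs <- as.character(phys$bes)
  for (m in phys$truth$marker_id) {
    q <- as.character(phys$markerSeqs[[m]])
    expect_true(any(vapply(seqs, function(s)
      grepl(q, s, fixed = TRUE), logical(1))), label = m)
  }
})

test_that("reference placements are collinear and honour loss intervals", {
  cfg <- simConfig(nLgs = 2L, markersPerLg = 8L, nContigs = 8L,
                   nSingletonBacs = 2L, dupMarkerCount = 0L,
                   lossFractions = c(0.5, 0), decoyRate = 0, seed = 7L)
  g <- simulateTrueGenome(cfg)
  phys <- simulatePhysicalBES(g, cfg)
  hits <- simulateReferencePlacements(g, phys, cfg)
  cfgP <- pipelineConfig()
  lost <- g@lossIntervals[g@lossIntervals$lg_id == "LG1", ]
  expect_equal(lost$frac, 0.5)
  # by construction, exactly the BES whose relative position falls inside
  # the loss interval lack a sub-cutoff hit
  bi1 <- phys$besInfo[phys$besInfo$lg_id == "LG1", ]
  rel <- bi1$cM / g@lgs$length_cM[g@lgs$lg_id == "LG1"]
  predictedLost <- bi1$bes_id[rel >= lost$start_frac &
                                rel < lost$start_frac + lost$frac]
  sub <- hits[hits$query_id %in% bi1$bes_id &
                hits$evalue <= cfgP@evalueCutoff, ]
  expect_setequal(setdiff(bi1$bes_id, sub$query_id), predictedLost)
  expect_gt(length(predictedLost) / nrow(bi1), 0.15)
  # collinearity on the intact group
  bes2 <- phys$besInfo[phys$besInfo$lg_id == "LG2", ]
  sub2 <- hits[hits$query_id %in% bes2$bes_id &
                 hits$evalue <= cfgP@evalueCutoff, ]
  pos <- pmin(sub2$sstart, sub2$send)
  cm <- bes2$cM[match(sub2$query_id, bes2$bes_id)]
  expect_gte(cor(cm, pos, method = "spearman"), 0.95)
})

test_that("a full simulated dataset writes every interchange format", {
  dir <- withr::local_tempdir()
  cfg <- tinySimConfig(8L)
  out <- writeSimulatedDataset(cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genotypes.txt", "physical_map.tsv", "bes.fasta", "markers.fasta",
      "reference_hits.tsv", "truth/anchors.tsv", "truth/homology.tsv")))))
  gt <- readGenotypes(file.path(dir, "genotypes.txt"))
  expect_equal(nMarkers(gt), nrow(out$genome@markers))
  pm <- readPhysicalMap(file.path(dir, "physical_map.tsv"))
  expect_equal(nrow(contigTable(pm)), cfg@nContigs)
})
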