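mkAnchors <- function(marker, target, kind = "contig") {
  data.frame(marker_id = marker, bes_id = paste0(target, "X.f"),
             clone_id = paste0(target, "X"), target_kind = kind,
             target_id = target, accepted = TRUE, reject_reason = "none",
             stringsAsFactors = FALSE)
}
mkPM <- function(ids, cb) {
  ct <- data.frame(contig_id = ids, cb_length = as.integer(cb))
  ct$clone_ids <- as.list(paste0(ids, "X"))
  new("PhysicalMap", contigs = ct, singletons = character(0))
}

test_that("elements attach at their markers' positions; conflicts are flagged", {
  gmap <- new("GeneticMap",
              lgs = data.frame(lg_id = c("LG1", "LG1", "LG2"),
                               marker_id = c("m1", "m2", "m3"),
                               position_cM = c(0, 12.5, 0)),
              excluded = data.frame(marker_id = "m9", reason = "unlinked"))
  pm <- mkPM(c("ctg1", "ctg2"), c(1000, 500))
  an <- rbind(mkAnchors(c("m1", "m2"), c("ctg1", "ctg1")),
              mkAnchors("m3", "ctg2"), mkAnchors("m9", "ctg2"))
  imap <- integrateMap(gmap, an, pm, pipelineConfig())
  tab <- anchorTable(imap)
  expect_equal(nrow(tab), 3L)           # m9 unmapped, not placed
  expect_equal(imap@unplacedMarkers, "m9")
  expect_equal(tab$position_cM[tab$marker_id == "m2"], 12.5)
  expect_equal(unique(tab$length_kb[tab$element_id == "ctg1"]),
               1000 * 1.428)
  expect_false(any(tab$conflict))       # two markers on ONE group: no conflict

  # same contig on two groups -> conflict on every row of that contig
  an2 <- rbind(mkAnchors("m1", "ctg1"), mkAnchors("m3", "ctg1"))
  imap2 <- integrateMap(gmap, an2, pm, pipelineConfig())
  expect_true(all(anchorTable(imap2)$conflict))

  expect_error(integrateMap(gmap, mkAnchors("m1", "ghost"), pm,
                            pipelineConfig()), "unknown contig")
})

test_that("coverage counts redundancy per group but elements once in totals", {
  gmap <- new("GeneticMap",
              lgs = data.frame(lg_id = c("LG1", "LG2"),
                               marker_id = c("m1", "m2"),
                               position_cM = c(0, 0)),
              excluded = data.frame(marker_id = character(),
                                    reason = character()))
  pm <- mkPM("ctg1", 1000)
  an <- rbind(mkAnchors("m1", "ctg1"), mkAnchors("m2", "ctg1"))
  imap <- integrateMap(gmap, an, pm, pipelineConfig())
  cov <- physicalCoverage(imap, pipelineConfig())
  expect_equal(cov$totals$total_redundant_mb, 2.86)      # 2 x 1.428 Mb
  expect_equal(cov$totals$total_nonredundant_mb, 1.43)
  expect_equal(cov$totals$n_contigs, 1L)
  expect_equal(sum(cov$per_lg$anchored_kb) / 1000,
               cov$totals$total_redundant_mb, tolerance = 0.005)

  empty <- new("IntegratedMap",
               anchors = anchorTable(imap)[0, ],
               unplacedMarkers = character(0))
  expect_equal(physicalCoverage(empty, pipelineConfig())$totals$
                 total_nonredundant_mb, 0)
})

test_that("coverage conservation holds exactly on a simulated run", {
  cfg <- tinySimConfig(13L, chimericFraction = 0.5)
  g <- simulateTrueGenome(cfg)
  phys <- simulatePhysicalBES(g, cfg)
  hits <- naiveAlign(phys$markerSeqs, phys$bes)
  types <- stats::setNames(g@markers$marker_type, g@markers$marker_id)
  res <- resolveTargets(filterAnchorHits(hits, types, pipelineConfig()),
                        phys$physicalMap)
  gmap <- new("GeneticMap",
              lgs = data.frame(lg_id = g@markers$lg_id,
                               marker_id = g@markers$marker_id,
                               position_cM = ave(g@markers$position_cM,
                                                 g@markers$lg_id,
                                                 FUN = function(x) x - x[1])),
              excluded = data.frame(marker_id = character(),
                                    reason = character()))
  imap <- integrateMap(gmap, res, phys$physicalMap, pipelineConfig())
  cov <- physicalCoverage(imap, pipelineConfig())
  a <- anchorTable(imap)
  el <- unique(a[, c("lg_id", "element_id", "length_kb")])
  extra <- sum(el$length_kb) -
    sum(unique(a[, c("element_id", "length_kb")])$length_kb)
  expect_equal(cov$totals$total_redundant_mb -
                 cov$totals$total_nonredundant_mb,
               round(sum(el$length_kb) / 1000, 2) -
                 round((sum(el$length_kb) - extra) / 1000, 2),
               tolerance = 0.011)
  # redundant extra equals one extra placement per chimeric contig
  conf <- detectConflicts(imap)
  chim <- g@contigPlacements$contig_id[g@contigPlacements$chimeric]
  expect_setequal(conf$conflicting, chim)
})

test_that("conflict rate is an integer percentage of anchored contigs", {
  lgs <- data.frame(
    lg_id = c(rep("LG1", 463), rep("LG2", 13)),
    marker_id = sprintf("m%03d", 1:476),
    position_cM = c(seq_len(463), seq_len(13)) - 1,
    stringsAsFactors = FALSE)
  gmap <- new("GeneticMap", lgs = lgs,
              excluded = data.frame(marker_id = character(),
                                    reason = character()))
  # 463 contigs; 13 get a second marker on the other group
  pm <- mkPM(sprintf("c%03d", 1:463), rep(100, 463))
  an <- mkAnchors(lgs$marker_id[1:463], sprintf("c%03d", 1:463))
  an <- rbind(an, mkAnchors(lgs$marker_id[464:476], sprintf("c%03d", 1:13)))
  imap <- integrateMap(gmap, an, pm, pipelineConfig())
  conf <- detectConflicts(imap)
  expect_equal(conf$n_anchored_contigs, 463L)
  expect_length(conf$conflicting, 13L)
  expect_equal(conf$error_rate_pct, 3L)

  imap0 <- integrateMap(gmap, an[1:463, ], pm, pipelineConfig())
  expect_equal(detectConflicts(imap0)$error_rate_pct, 0L)
})

test_that("duplicated markers classify by linkage-group identity", {
  pairs <- data.frame(base_id = c("CAFS2910", "CAFS3169", "CAFSX"),
                      lg_a = c("LG19", "LG8", "LG3"),
                      lg_b = c("LG50", "LG8", NA),
                      stringsAsFactors = FALSE)
  hom <- data.frame(lg_id = c("LG19", "LG50", "LG8"),
                    chromosome = c("chr11", "chr11", "chr15"))
  cl <- classifyDuplicatedMarkers(pairs, hom)
  expect_equal(cl$classification,
               c("wgd_consistent", "intra_lg", "unclassifiable"))
  expect_equal(cl$orthologous_chromosome[1], "chr11")
  expect_equal(attr(cl, "counts")[["wgd_consistent"]], 1L)

  gmap <- new("GeneticMap",
              lgs = data.frame(lg_id = c("LG1", "LG2", "LG1", "LG1"),
                               marker_id = c("D1-1", "D1-2", "D2-1", "D2-2"),
                               position_cM = c(0, 0, 1, 2)),
              excluded = data.frame(marker_id = character(),
                                    reason = character()))
  dp <- dupPairsFromMap(gmap)
  expect_equal(dp$base_id, c("D1", "D2"))
  expect_equal(classifyDuplicatedMarkers(dp)$classification,
               c("wgd_consistent", "intra_lg"))
})
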