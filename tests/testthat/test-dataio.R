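test_that("genotype dialect parses, validates codes and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c(
    "name = fam1", "popt = CP", "nloc = 3", "nind = 4",
    "m1\t<lmxll>\t0-\tlm ll lm --",
    "m2\t<hkxhk>\t--\thh hk kk hk",
    "m3\t<abxcd>\t01\tac ad bc bd"), f)
  gt <- readGenotypes(f)
  expect_s4_class(gt, "CPGenotypes")
  expect_equal(nOffspring(gt), 4L)
  expect_equal(nMarkers(gt), 3L)
  expect_equal(unname(segregationTypes(gt)["m2"]), "hkxhk")
  expect_equal(unname(genotypeCodes(gt)["m1", 4]), "--")

  # illegal code reported with its line number
  writeLines(c(
    "name = fam1", "popt = CP", "nloc = 1", "nind = 2",
    "m1\t<lmxll>\t--\tlq ll"), f)
  expect_error(readGenotypes(f), "line 5.*illegal code 'lq'")

  # write-then-read identity on a simulated 20-marker table
  cfg <- simConfig(nLgs = 2L, markersPerLg = 10L, nContigs = 4L,
                   nSingletonBacs = 2L, dupMarkerCount = 0L, seed = 11L)
  sim <- simulateCPFamily(simulateTrueGenome(cfg), cfg)
  writeGenotypes(sim, f)
  back <- readGenotypes(f)
  expect_identical(genotypeCodes(back), genotypeCodes(sim))
  expect_identical(markerInfo(back)$segregation_type,
                   markerInfo(sim)$segregation_type)
  expect_identical(markerInfo(back)$phase, markerInfo(sim)$phase)
  # the second write is byte-identical (canonical form)
  f2 <- withr::local_tempfile()
  writeGenotypes(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("physical map TSV reader enforces invariants and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("contig_id\tcb_length\tclone_ids",
               "ctg1\t120\tA01;A02;A03",
               "ctg2\t45\tB01;B02",
               "SINGLETON\t0\tS01;S02"), f)
  pm <- readPhysicalMap(f)
  expect_equal(nrow(contigTable(pm)), 2L)
  expect_setequal(singletonClones(pm), c("S01", "S02"))
  expect_equal(contigTable(pm)$cb_length, c(120L, 45L))

  writeLines(c("contig_id\tcb_length\tclone_ids", "ctg1\t0\tA01"), f)
  expect_error(readPhysicalMap(f), "cb_length")

  writeLines(c("contig_id\tcb_length\tclone_ids",
               "ctg1\t10\tA01", "ctg2\t10\tA01"), f)
  expect_error(readPhysicalMap(f), "two contigs")

  cfg <- tinySimConfig(5L)
  phys <- simulatePhysicalBES(simulateTrueGenome(cfg), cfg)
  writePhysicalMap(phys$physicalMap, f)
  back <- readPhysicalMap(f)
  expect_equal(contigTable(back)$contig_id,
               contigTable(phys$physicalMap)$contig_id)
  expect_equal(contigTable(back)$cb_length,
               contigTable(phys$physicalMap)$cb_length)
  expect_identical(contigTable(back)$clone_ids,
                   contigTable(phys$physicalMap)$clone_ids)
})

test_that("tabular alignment reader infers strand and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("q1\ts1\t98.5\t200\t3\t0\t1\t200\t500\t300\t1e-20\t350",
               "q2\ts2\t100\t150\t0\t0\t1\t150\t101\t250\t1e-30\t300"), f)
  hits <- readBlastTab(f)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$strand, c("-", "+"))
  expect_equal(hits$identity_pct[1], 98.5)
  expect_equal(hits$evalue[2], 1e-30)

  file.create(f2 <- withr::local_tempfile())
  expect_equal(nrow(readBlastTab(f2)), 0L)

  writeLines("q1\ts1\t98.5\t200", f)
  expect_error(readBlastTab(f), "12")

  writeBlastTab(hits, f)
  expect_equal(readBlastTab(f), hits)
})

test_that("BES ids decompose into clone and end", {
  bt <- besTable(c("CYC037J02.r", "CYC054K09.f"))
  expect_equal(bt$clone_id, c("CYC037J02", "CYC054K09"))
  expect_equal(bt$end, c("r", "f"))
  expect_error(besTable("CYC037J02"), "suffix")
})
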