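#' Create a pipeline configuration
#'
#' All thresholds used across the pipeline, with the defaults of the common
#' carp integrated-map protocol: linkage groups formed at LOD 5 (diagnostic
#' sweep 5-15 in steps of 1) with recombination fractions capped at 0.4 and
#' Kosambi map distances; marker-to-BES anchoring requires >= 150 bp
#' (microsatellite) or >= 100 bp (SNP) alignments at > 95% identity below an
#' e-value of 1e-5; physical lengths convert at 1.428 kb per consensus band
#' with 141 kb assumed per single BAC; synteny blocks merge reference hits
#' closer than 1 Mb and a linkage group is assigned to a chromosome when at
#' least half of its placed queries land there.
#'
#' @param lodGroupThreshold LOD at which linkage groups are formed.
#' @param lodSweep increasing LOD vector for the diagnostic grouping sweep.
#' @param maxRf maximum recombination fraction accepted as linkage evidence.
#' @param distortionAlpha significance level of the segregation filter.
#' @param ssrMinAlignBp,snpMinAlignBp minimum anchoring alignment lengths (bp).
#' @param minIdentityPct anchoring identity threshold (strict, percent).
#' @param evalueCutoff alignment e-value cutoff.
#' @param kbPerCb kilobases per consensus band.
#' @param bacInsertKb assumed single-BAC insert length (kb).
#' @param syntenyMaxGapBp maximum merged gap (bp) within a synteny block.
#' @param homologyMinFraction minimum modal-chromosome fraction for a
#'   homology assignment.
#' @param lossFlagFraction coverage fraction below which a linkage group is
#'   flagged as candidate segmental loss.
#' @param genomeMb assumed genome size in Mb.
#' @param rngSeed integer seed stored with the configuration.
#' @return A validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@kbPerCb
#' @export
pipelineConfig <- function(lodGroupThreshold = 5.0,
                           lodSweep = seq(5, 15, by = 1),
                           maxRf = 0.4,
                           distortionAlpha = 0.01,
                           ssrMinAlignBp = 150,
                           snpMinAlignBp = 100,
                           minIdentityPct = 95.0,
                           evalueCutoff = 1e-5,
                           kbPerCb = 1.428,
                           bacInsertKb = 141,
                           syntenyMaxGapBp = 1e6,
                           homologyMinFraction = 0.5,
                           lossFlagFraction = 0.8,
                           genomeMb = 1700,
                           rngSeed = 1L) {
  new("PipelineConfig",
      lodGroupThreshold = lodGroupThreshold, lodSweep = lodSweep,
      maxRf = maxRf, distortionAlpha = distortionAlpha,
      ssrMinAlignBp = ssrMinAlignBp, snpMinAlignBp = snpMinAlignBp,
      minIdentityPct = minIdentityPct, evalueCutoff = evalueCutoff,
      kbPerCb = kbPerCb, bacInsertKb = bacInsertKb,
      syntenyMaxGapBp = syntenyMaxGapBp,
      homologyMinFraction = homologyMinFraction,
      lossFlagFraction = lossFlagFraction,
      genomeMb = genomeMb, rngSeed = as.integer(rngSeed))
}

#' Create a simulation configuration
#'
#' Defaults emulate the study design of the carp integration analysis at
#' desk scale: an F1 family of 107 offspring; linkage groups of ~80 cM
#' carrying ~20 markers; a microsatellite-dominated marker panel in which
#' most loci are informative in both outbred parents; contigs of 100-2,200
#' consensus bands; a 2.8% chimeric-contig rate (the assembly error rate the
#' integration stage is meant to estimate); and a diploid reference genome in
#' which every chromosome is homologous to exactly two linkage groups.
#'
#' @param nLgs even number of linkage groups.
#' @param meanLgCm mean linkage-group length (cM).
#' @param markersPerLg markers per linkage group.
#' @param nOffspring family size.
#' @param segtypeMix named proportions over the five CP segregation types.
#' @param snpFraction fraction of SNP markers.
#' @param missingRate missing-genotype rate.
#' @param distortionFrac fraction of markers with injected distortion.
#' @param distortionBias transmission bias at distorted markers.
#' @param genotypingErrorRate random miscall rate.
#' @param minSpacingCm minimum adjacent-marker spacing (cM).
#' @param nContigs anchored contig count.
#' @param cbLengthRange contig length range in consensus bands.
#' @param clonesPerContigRange clones per contig.
#' @param nSingletonBacs anchored singleton BAC count.
#' @param chimericFraction fraction of contigs made chimeric.
#' @param besLengthBp BES read length.
#' @param ssrSeqLengthBp,snpSeqLengthBp marker sequence lengths.
#' @param besErrorRate substitution rate in embedded marker copies.
#' @param dupMarkerCount duplicated-marker pairs to simulate.
#' @param dupIntraFraction fraction of duplicated pairs kept on one LG.
#' @param chromMb reference chromosome length (Mb).
#' @param jitterBpSd reference placement jitter (bp, sd).
#' @param lossFractions per-LG fraction of the homologous chromosome lost.
#' @param decoyRate rate of extra above-cutoff decoy hits.
#' @param seed integer seed; every generator is deterministic given it.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nLgs = 2L, markersPerLg = 5L, seed = 7L)
#' @export
simConfig <- function(nLgs = 10L,
                      meanLgCm = 80,
                      markersPerLg = 20L,
                      nOffspring = 107L,
                      segtypeMix = c(lmxll = 0.20, nnxnp = 0.20,
                                     hkxhk = 0.15, efxeg = 0.25,
                                     abxcd = 0.20),
                      snpFraction = 0.1,
                      missingRate = 0.02,
                      distortionFrac = 0.05,
                      distortionBias = 0.75,
                      genotypingErrorRate = 0,
                      minSpacingCm = 0,
                      nContigs = 30L,
                      cbLengthRange = c(100, 2200),
                      clonesPerContigRange = c(6, 12),
                      nSingletonBacs = 8L,
                      chimericFraction = 0.028,
                      besLengthBp = 500L,
                      ssrSeqLengthBp = 300L,
                      snpSeqLengthBp = 120L,
                      besErrorRate = 0,
                      dupMarkerCount = 6L,
                      dupIntraFraction = 0.4,
                      chromMb = 5,
                      jitterBpSd = 5e4,
                      lossFractions = 0,
                      decoyRate = 0.05,
                      seed = 1L) {
  new("SimConfig",
      nLgs = as.integer(nLgs), meanLgCm = meanLgCm,
      markersPerLg = as.integer(markersPerLg),
      nOffspring = as.integer(nOffspring), segtypeMix = segtypeMix,
      snpFraction = snpFraction, missingRate = missingRate,
      distortionFrac = distortionFrac, distortionBias = distortionBias,
      genotypingErrorRate = genotypingErrorRate,
      minSpacingCm = minSpacingCm,
      nContigs = as.integer(nContigs), cbLengthRange = cbLengthRange,
      clonesPerContigRange = clonesPerContigRange,
      nSingletonBacs = as.integer(nSingletonBacs),
      chimericFraction = chimericFraction,
      besLengthBp = as.integer(besLengthBp),
      ssrSeqLengthBp = as.integer(ssrSeqLengthBp),
      snpSeqLengthBp = as.integer(snpSeqLengthBp),
      besErrorRate = besErrorRate,
      dupMarkerCount = as.integer(dupMarkerCount),
      dupIntraFraction = dupIntraFraction,
      chromMb = chromMb, jitterBpSd = jitterBpSd,
      lossFractions = rep_len(lossFractions, as.integer(nLgs)),
      decoyRate = decoyRate, seed = as.integer(seed))
}
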