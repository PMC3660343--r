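---
title: "Models and methods behind carpmap"
author: "carpmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind carpmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`carpmap` rebuilds the computational side of a genetic–physical map
integration study in an outbred fish such as the common carp: a genetic
linkage map is estimated from a single F1 full-sib family; FPC physical-map
contigs and single BAC clones are attached to it through markers aligned to
BAC-end sequences (BES); coverage, assembly conflicts and contig
orientation potential are accounted for; and the integrated map is compared
with a diploid reference genome (zebrafish-like) to expose the 2:1
linkage-group-to-chromosome pattern expected after a lineage-specific
whole-genome duplication (WGD). A synthetic-data module generates inputs
with the same statistical structure so that every stage can be validated
against a known truth.

This vignette records the models, the parameters that matter, the numerical
choices, and the limits of what the tests demonstrate.

# The CP family model

An outbred full-sib ("CP") family segregates markers of five types, named
by the parental genotypes: `lmxll`, `nnxnp` (one parent heterozygous),
`hkxhk` (both heterozygous for the same two alleles), `efxeg` (three
alleles) and `abxcd` (four alleles). Offspring genotype codes are unordered
allele pairs; missing data is `--`. Each parent transmits one of its two
strands; between adjacent loci the strand switches with the recombination
fraction of the interval.

Two features drive everything downstream:

* a parent contributes linkage information for a marker pair only when it
  is heterozygous at *both* loci (so e.g. `lmxll` with `nnxnp` pairs carry
  no shared meioses at all and return rf 0.5 with LOD 0), and
* some codes do not identify the transmitting parent (`hk` may be h from
  either side), which makes part of the data latent.

# Two-point estimation

For a pair of markers the joint class probabilities are polynomials
$P(\mathrm{class}) = \sum_k c_k\, r^k (1-r)^{m-k}$, where $m \in \{0,1,2\}$
is the number of doubly heterozygous parents and the coefficients depend on
the segregation types and the two parental linkage phases. The MLE of $r$
is computed by EM over the ambiguous classes (expected recombinant meioses
per class, closed form in one step when nothing is ambiguous), maximized
over the at most four phase combinations, with ties broken toward coupling.
The LOD is $\log_{10} L(\hat r) - \log_{10} L(0.5)$. The test suite checks
the estimator against an independent brute-force oracle (direct enumeration
of the sixteen strand combinations, grid search over $r$ at $10^{-4}$
resolution) on hundreds of simulated pairs of all type combinations, and
its bias (< 0.01 at n = 1000 across $r \in \{0.05, 0.1, 0.2, 0.3\}$).

Phase maximization has a known side effect: on weakly linked pairs it picks
whichever phase yields the smaller $\hat r$, biasing distant-pair estimates
downward. For *ordering* (below) the package therefore first fixes each
marker's phases group-wide — propagating the ML pair phases from the
strongest pairs outward with a parity union–find, then polishing with a
joint-likelihood sweep — and re-reads every pair's $\hat r$ under those
fixed phases.

# Distortion filtering

Before mapping, each marker's genotype-class frequencies are tested against
the Mendelian expectation of its type (1:1, 1:2:1 or 1:1:1:1) by chi-square;
markers with $p <$ `distortionAlpha` (default 0.01, no multiplicity
correction) are excluded as distorted. At this sample size the test is
approximately calibrated (empirical type-I rate about 0.7–1.4%; the upper
end reflects the chi-square approximation for the 3- and 4-category types).
Note that with hundreds of markers a few false exclusions per map are an
expected property of the published protocol, not a defect.

# Grouping and the LOD sweep

Linkage groups are single-linkage connected components over edges with
LOD ≥ `lodGroupThreshold` (default 5) and rf ≤ `maxRf` (default 0.4).
The diagnostic sweep reports group counts for LOD 5 through 15 in steps
of 1; mapping always proceeds at the group threshold. Size-1 components are
reported as unlinked rather than mapped.

# Ordering and map distances

Ordering is a regression-mapping reconstruction. Markers are inserted in
decreasing information order; each insertion minimizes the weighted least
squares difference between fitted positions and pairwise Kosambi distances
(weights: squared phase-consistent LODs); a window-of-three ripple runs
after each insertion and to convergence at the end; the final order is
re-sorted by fitted position whenever that does not worsen the objective
(two markers with no mutual weight cannot be ordered by the objective
itself, but their fitted positions still separate them). Map positions are
the weighted least-squares fit with the first marker at 0, reported to
three decimals. Distances use Kosambi's function
$d = 25 \ln\!\big(\tfrac{1+2r}{1-2r}\big)$ cM throughout.

Two-point distance regression has a measurable accuracy ceiling here. At
n = 107 with markers ≥ 5 cM apart, roughly one 10-marker group in seven
retains a local transposition, almost always between markers that share few
informative meioses — and the exact joint likelihood of the genotypes
rejects most of those wrong orders decisively. The final ripple therefore
re-scores the spec-sized local moves (window-of-three permutations, short
relocations, segment reversals and block rotations) by the group's joint
likelihood: a hidden Markov chain over the four joint parental strand
states, per-interval recombination fractions re-fitted by a short EM, with
a conservative acceptance margin of 2 log-units. This keeps the search
space and reported positions of regression mapping while letting the full
genotype patterns decide local conflicts; it is not a multipoint ordering
search. With it, residual order errors are dominated by genuine likelihood
ties — cases in which the data cannot distinguish the orders at all.

A related modelling caveat: the family simulator draws recombination
independently per adjacent interval (no interference), so compound
two-point recombination over several intervals composes in the
Haldane sense, not the Kosambi sense. Kosambi distances of well-separated
pairs are therefore systematically sub-additive — exactly as in real data
whenever interference is weaker than Kosambi's assumption — which is the
reason weakly linked pairs carry little weight in the ordering objective.

# Synthetic data

`simulateTrueGenome()` draws marker positions (spacings exponential above a
configurable minimum, cumulated from 0), assigns segregation types from a
configurable mix, pairs linkage groups two-per-reference-chromosome, places
contigs and singleton BACs on distinct anchor markers, marks a configurable
fraction of contigs chimeric, and adds duplicated-marker pairs (`-1`/`-2`)
either on the two homoeologous groups or within one group.
`simulateCPFamily()` transmits parental strands per the interval model with
randomized, recorded linkage phases and injects missing data, biased
transmission (distortion, favoured allele probability 0.75) and optional
random miscalls. `simulatePhysicalBES()` gives every clone a forward and a
reverse BES; anchor clones embed the marker sequence verbatim (a
substitution knob exercises the identity filter); clones spread across the
contig's physical span. `simulateReferencePlacements()` puts each BES on
its group's homologous chromosome collinearly with its cM position
(Gaussian jitter, default sd 50 kb), drops BES inside segmental-loss
intervals to above-cutoff decoys, and emits standard 12-column tabular
alignments.

Defaults emulate the study design at desk scale: 107 offspring, 10 groups
of ~80 cM with ~20 markers (the real map averaged ~24 markers over
71.32 cM), a microsatellite-dominated mix in which 60% of markers are
informative in both outbred parents (SSRs in unrelated parents are usually
informative in both; the exact published type composition is not
recoverable), 30 contigs of 100–2,200 consensus bands (0.14–3.1 Mb at
1.428 kb/CB, matching the published anchored-contig size range), a 2.8%
chimeric fraction (the assembly error rate the integration stage is meant
to estimate), 5 Mb reference chromosomes and one chromosome per two
groups. What the simulator does *not* model: sequence-level realism beyond
embedded marker motifs, crossover interference, genotyping-error structure
beyond uniform miscalls, and real BES read-quality artifacts. Passing
tests therefore validate the estimators and bookkeeping against the stated
models, not performance on raw laboratory data.

# Anchoring

The built-in aligner exists so tests need no external binary: exact 21-mer
seeds every k bases on both strands, ungapped extension across the full
overlap, identity = matches/length, e-value reported as 0 (identity and
length are the deciding statistics). Real BLASTn tabular output drops in
anywhere its output is consumed. Acceptance thresholds follow the
integration protocol: microsatellites need ≥ 150 bp alignments, SNPs
≥ 100 bp, identity strictly > 95%, e-value ≤ 1e-5; boundary readings are
configurable because the protocol's wording ("larger than", "greater
than") is ambiguous at the boundary exactly. The best surviving hit per
marker is chosen by bitscore, then e-value, then subject id; markers whose
equally scored best hits resolve to different contigs are assigned to
neither and flagged — conservative anchoring avoids fabricating conflicts.
The candidate-locus screen for marker development keeps contigs > 1 Mb,
perfect 2–4 bp repeats totalling ≥ 12 bp (units that are themselves
repeats of a shorter unit are excluded), ≥ 50 bp flanks, at most two loci
per contig; the motif definition is this package's own, as the original
screening criteria were not published.

# Integration bookkeeping

Contigs convert to kilobases at `kbPerCb` (default 1.428 kb per consensus
band); single BACs count `bacInsertKb` (default 141 kb). Per-group sums
count every attachment ("with redundancy"); non-redundant totals count
each element once — the only reading that reproduces both published totals
(540.752 vs 498.75 Mb). A contig is conflicting iff its accepted anchors
fall on two or more *different* groups (a wide same-group span, > 20 cM by
default, only logs a warning); the conflict rate over anchored contigs is
an upper bound for the physical-map assembly error rate, since anchoring
through a duplicated locus produces the same signal. Lengths stay exact in
kb internally; Mb values round to two decimals at report time, and the
genome fraction uses a configurable assumed genome size (default
1,700 Mb). Orientation: elements with two or more anchoring markers on one
group are orientable in principle, but because BES positions along a
contig are not modelled the orientation is reported as `unoriented`.

# Comparative analysis

Query placement keeps one top hit per query below the e-value cutoff
(bitscore desc, e-value asc, chromosome, start — a deterministic
tie-break; whether the original protocol kept one or all tied best hits is
not stated). Coordinates convert to 0-based half-open internally; the
1-based inclusive convention exists only at file boundaries. A group's
homologous chromosome is its modal chromosome when the supporting fraction
reaches `homologyMinFraction` (default 0.5 — the published analysis
asserts the 2:1 pattern without stating a rule, so the rule is exposed in
configuration). Synteny blocks merge same-group placements while the
reference gap is ≤ `syntenyMaxGapBp` (default 1 Mb, also unstated in the
original; merging is idempotent and block support totals are conserved).
Segmental loss flags groups covering less than `lossFlagFraction`
(default 0.8) of their chromosome, with chromosome lengths from a supplied
table or, as a documented underestimate, the maximum placement end.
Mate-pair consistency is diagnostic only.

# Problem sizes used by the test suite

Deterministic bookkeeping is checked at the published scale (463 contigs,
340,577 CB, 88 BACs, 50 groups, 13 duplicated markers) because it is
instantaneous. Statistical checks run at desk scale chosen once: estimator
oracle equivalence on 200 pairs at n = 107; bias at n = 1000; grouping and
ordering recovery on 20 seeds of a 10-group genome with 10 markers per
group at ≥ 5 cM (error-free, matching the recovery claim's conditions);
one full end-to-end synthetic run for anchoring recall, chimera flagging,
the 2:1 homology pattern and the conservation/idempotence invariants. The
recovery bar of 95% of seeds with the group count *and* every group's
order exact is not reached: measured recovery is ~45% of seeds, limited
jointly by LOD-5 grouping splits (a group whose only cross-parent bridge
falls below LOD 5 genuinely separates) and by order ties the data cannot
resolve at n = 107 — on the failing orders the exact joint likelihood
either ties or prefers the wrong order. The corresponding test states the
bar and fails honestly rather than relaxing it.

# Known limitations

* Orders within tightly spaced marker runs are only as good as n = 107
  meioses allow; published maps at this design carry the same ambiguity.
* The aligner is ungapped and exact-seeded; indel-containing anchors
  require real BLAST output.
* No sex-specific maps, no consensus-map merging, no re-assembly of
  chimeric contigs (flagging only), no ancestral-karyotype reconstruction.
* Physical coverage assumes the published CB→kb calibration and a fixed
  BAC insert size; both are configuration, not estimates.
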