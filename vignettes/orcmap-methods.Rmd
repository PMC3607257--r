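---
title: "Mapping replication initiation against transcription units: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping replication initiation against transcription units: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The *Trypanosoma brucei* nuclear genome is transcribed as a few dozen
polycistronic directional gene clusters (DGCs) per megabase chromosome,
separated by divergent strand switch regions (SSRs, where transcription
initiates bidirectionally) and convergent SSRs (where it terminates).
The chromosome ends carry silent, subtelomeric VSG gene arrays built from
repeated cassettes.  `orcmap` implements the computational pipeline for
asking where DNA replication initiates in such a genome and how
initiation interacts with transcription:

1. **Chromosome demarcation** into core, subtelomere-proximal, and VSG
   array region classes from the gene annotation alone, plus DGC/SSR
   annotation and VSG cassette parsing.
2. **Initiator (ORC1/CDC6) binding-site calling** from tiling-array ChIP
   log2 ratios with a sliding-window detector and a randomization false
   discovery rate.
3. **Early origin mapping by marker frequency analysis (MFA)**: S/G2
   read-depth ratios in 2,500 bp bins, origin peak calling, fork-rate
   asymmetry from flank slopes, replicated fraction, and origin-density
   extrapolation; ΔΔCt quantification for targeted qPCR validation.
4. **Knockdown response**: quantile-normalized induced/uninduced depth,
   250 bp log2 ratio and presence tracks, running-median smoothing,
   per-gene fold changes, and a permutation test for boundary enrichment.
5. A **synthetic-data generator** that emits genomes, annotations, and
   all raw tracks with known ground truth, so every stage has a recovery
   test.

Coordinates are 0-based half-open throughout the package; GFF3 IO
converts to 1-based inclusive, BED/bedGraph are naturally 0-based.

# Chromosome demarcation

The scan walks the gene list inward from each chromosome end.  On each
arm, sequence up to and including the outermost run of VSG genes is
`vsg_array`; runs of RHS / VSG-related / ESAG genes adjacent to the array
are `subtelomere`; the span of the remaining annotated genes is `core`.
Two gene categories are *neutral* — they carry no class vote: hypothetical
genes (annotation noise) and ESAG3 (which occurs inside VSG arrays as
well as subtelomeres, so it cannot discriminate).  Short internal runs of
subtelomeric-category genes inside the core are relabelled `subtelomere`
(relics of chromosome fusions); the minimum run is 2 qualifying genes,
configurable via `min_island`.  Isolated internal VSGs below
`min_array_genes` are treated as island content rather than array
founders, because the trigger rule is silent about them.

Class boundaries fall at the midpoint of the inter-gene gap at each class
change; gaps within a class inherit the class.  This makes the track a
deterministic partition of `[0, chromosome length)` — interval lengths sum
to the chromosome, no overlaps, adjacent classes distinct — which the test
suite asserts as an invariant.

# ChIP site calling

The tiling-array procedure, per chromosome:

* rescale the log2 ratios to a minimum of exactly zero
  (`rescale_min_zero`); the detector is thereby invariant to additive
  shifts of the raw track;
* form the *hypothetical maximum* `M = mean + 6 SD` of the rescaled
  signal (per chromosome — the scope is a package decision, as is
  anchoring the 500 bp windows at probe positions rather than every bp,
  which matches the tiling design and is deterministic);
* a window is a hit when ≥ 4 probes within 500 bp exceed
  `cutoff_fraction × M`; overlapping hit windows are unioned into
  candidate intervals;
* cutoffs run down a grid from 90% to 15% of `M` (the grid interior —
  `{90, 80, …, 20, 15}` — is a package decision; only the endpoints are
  given);
* for each cutoff, probe values are permuted within the chromosome
  (positions fixed) 20 times and the detector re-run;
  `FDR(cutoff) = mean null candidate count / observed count`, capped at
  1. Permutation preserves the marginal signal distribution and the
  probe density, which is what the detector sees;
* a site is reported from the loosest cutoff whose FDR is within 0.2 and
  classed `high` / `mid` / `low` by the most stringent FDR bound
  (≤ 0.05, ≤ 0.1, ≤ 0.2) supported by any overlapping cutoff's
  candidates.

Sites closer than 10 kb are merged transitively into "unique" sites;
histone-mark loci are merged first and then filtered at 1 kb minimum
size (merge-then-filter order matters and is tested).  Association
tables assign each site to the category containing its midpoint, which
keeps counts additive — a site straddling a boundary is counted once.

# MFA origin mapping

Per-position depth is averaged into 2,500 bp bins (the final partial bin
over its true length).  The raw per-bin ratio S/G2 is normalized so the
unreplicated *baseline* sits at 1.  The baseline is the mode of the raw
ratio distribution; we estimate it kernel-free by seeding with the median
of the lowest quartile of bins and then taking the median of the
symmetric cluster within 3 robust SDs of the seed.  The refinement step
matters: the lowest-quartile median alone sits a fraction of a noise SD
*below* the mode (it is drawn from the lower tail), which inflates every
normalized bin and with it the replicated-fraction estimate.

Peak calling is not specified by the upstream analyses ("peaks of varying
amplitude"), so the procedure is the package's own and fully
configurable: running-median (5 bins) pre-smoothing; local maxima with
amplitude ≥ 0.15 above baseline and width at half-amplitude ≥ 10 bins;
boundaries where the smoothed track returns within one robust SD of
baseline.  Flank slopes are least-squares fits on each flank's *linear
mid-section* (between 25% and 85% of the apex amplitude), excluding the
median-flattened top and the curved tail near baseline.  The reported
peak center is the intersection of the two flank lines — for the
tent-shaped profile an origin produces, that intersection is the apex
kink, for asymmetric flanks too, and it localizes the origin to within a
bin where the raw argmax wanders by two or three.  A peak is `symmetric`
when the flank-slope magnitudes agree within [0.8, 1.25], and its name is
`OBR:<chromosome>:<Mbp to 2 decimals>`.

Under uniform sampling through S phase and constant per-cell fork speed,
the expected MFA profile declines linearly with distance from the origin
at a rate inversely proportional to the flank's fork speed; the
fork-rate asymmetry is therefore |steeper|/|shallower| of the two
slopes, with the shallow flank the faster (transcription-codirectional)
one.  Slopes are computed on the smoothed track — the choice is
documented here because the upstream description does not say.

A bin is *replicated* when its normalized ratio exceeds 1 + threshold;
the default threshold is 3 robust SDs of the sub-baseline bins.  The
threshold is exposed because no value is stated upstream; recovery is
verified against the generator's truth only.  Note the estimator has a
small structural downward bias against the truth definition (positions
reachable by any fork by the end of the sampled window): positions in
the shallow outer tail of a peak have replication probability below the
detection threshold.  At the default geometry this costs a few points of
replicated fraction, within the ±5-point recovery band the tests
enforce.

Origin-density extrapolation scales the observed peak count by the
reciprocal of the analyzed S-phase fraction (the sorted S sample is
enriched for origins firing in the first half of S), rounds to the
nearest ten, and divides the genome length by the predicted count; a
zero-intercept regression of per-chromosome peak count on chromosome
length accompanies it.

# ΔΔCt quantification

Pure ΔΔCt with amplification efficiency fixed at 2 and replicate
aggregation by mean Ct, both per the standard method the upstream work
cites; replicate dispersion propagates through the standard errors of
the four means to a quantity interval.  The closed form makes two exact
identities testable: equal mean Cts give quantity 1, and a global Ct
shift (efficiency/dilution offset) changes nothing.

# Knockdown response

Position-level comparisons (ratio and presence tracks) use quantile
normalization of the two depth tracks — each rank gets the mean of the
two rank-ordered values, ties sharing their block mean — which makes the
marginal distributions identical and the log2 ratio track centred.
Positions where either sample is zero are excluded from the ratio track;
they belong to the presence track, where zeros are substituted with
0.00001 before the ratio and a bin is flagged single-sample when its
median log2 ratio exceeds `log2(read_floor / zero_sub) / 2` (the
substitution constant is given upstream; the decision bound is a package
choice, configurable).  Both tracks use 250 bp bins with median centre
values, smoothed by a 7-bin running median with shrinking windows at the
edges.

Per-gene fold changes deliberately do *not* use the quantile-normalized
tracks: quantile normalization forces identical marginals, so it
compresses fold changes exactly at the quantiles where the two samples
genuinely differ — the derepression signal itself.  Gene-level
quantification instead uses depth scaled by total mapped signal
(`normalize_library_size`, the counts-per-million convention), the
analogue of the FPKM quantification used upstream, which preserves
within-gene ratios; the > 1.4-fold rule then flags significant genes.
No additional significance test is imposed, since none is described.

Boundary enrichment — the quantification of "elevation concentrates at
transcription-unit boundaries" — is the mean signal within 10 kb of any
DGC boundary minus the mean elsewhere, with a cyclic-shift permutation
null within the chromosome (≥ 1,000 shifts).  Shifts smaller than two
boundary-window widths are excluded from the null draw: they leave the
near-boundary mask largely intact and are not exchangeable.  Note also
that near-periodic DGC layouts make cyclic shifts that realign zones
with boundaries; the generator's Poisson-distributed DGC sizes break
exact periodicity, but p-values near the 0.01 level should be read with
that in mind.

# The synthetic-data generator

`sim_config()` holds every condition in one place.  Values stated by the
study are defaults: 61 bp probe spacing, ~4-fold ChIP enrichment over
site footprints, 2,500 bp MFA bins, an S sample spanning the first half
of S phase, 2-fold boundary elevation over 5 kb, 8-fold derepression of
metacyclic-VSG-like loci, ~30× depth, ~50 genes per DGC.  Where the
study states none, defaults are one-time choices a practitioner would
call realistic at desk scale: three chromosomes of 2/1.5/1 Mbp, 150 kb
arrays and 50 kb subtelomeres per arm, 1.4 kb genes with 1.3 kb
intergenic spacing, 5 kb SSRs, cassettes of 6 kb at 5/40/50/5%
repeat/5'-flank/ORF/3'-flank shares, AT content 55/60/65% for
core/subtelomere/array, negative-binomial depth noise (dispersion 20;
Poisson in the limit), fork speed 1.4 × 10^5 bp per S phase with a 2×
codirectional multiplier, origins at divergent SSRs spaced ≥ 450 kb
(about 37% of the genome replicated by mid-S — as close to the printed
~45% as the discrete SSR spacing allows), readthrough transcription at
10% of gene-body abundance, and silent MVSG-like loci at baseline depth
5.

Replication tracks come from a semi-analytic expectation: for each
position, the probability that some origin's fork arrives before the
cell's sampled time, integrating firing times (uniform over the firing
window, thinned by efficiency) and sampling times (uniform over the S
window) on a grid.  The expectation is piecewise linear in position, so
it is evaluated every 50 bp and interpolated (`p_step = 1` disables
this; the interpolation error is bounded well below the depth noise).
An independent per-cell Monte Carlo enumeration lives in the test suite
and must agree within Monte Carlo error.

Everything is deterministic given `(seed, config)`; each stage derives
its own seed offset so stages can be re-run independently.

## What passing tests do and do not show

The generator produces plateau-shaped ChIP enrichment, tent-shaped MFA
peaks, and block-uniform expression; real tracks carry dye bias,
mappability holes, copy-number variation, overdispersion beyond negative
binomial, and alignment artifacts, none of which are modelled (the
pipeline starts at per-position depth, taking alignment as given).
Recovery results therefore demonstrate correctness of the procedures
under the stated model, not performance on real arrays or libraries.
Genome-wide counts from the original datasets (953 sites, 42 peaks,
44.7% replicated) are not reproducible from synthetic data at desk
scale; what is checked instead is the printed-table arithmetic those
numbers imply, and truth recovery at the stated tolerances.

# Problem sizes

Routine tests run on 0.2–2 Mbp chromosomes; recovery statistics use 50
seeds for apex localization and the noise false-call rate, 5–6 seeds for
fork-rate folds, and 1,000 permutations for the boundary null.  These
sizes give the recovery bands quoted above while keeping a full suite
run in a few minutes; all are parameters, so nothing prevents re-running
at larger scale.

# Known limitations

* The demarcation scan trusts gene categories; a misannotated VSG at an
  internal locus becomes an island or, above `min_array_genes`, a
  spurious array.
* The FDR is a global per-cutoff estimate, not per-site; a site's class
  reflects the best cutoff that detects it.
* Fork-rate asymmetry assumes the flank's fork speed is constant along
  the flank; mixed-direction flanks yield an average.
* The replicated-fraction threshold and the presence bound are
  heuristics exposed as parameters; both are validated only against
  synthetic truth.
* Quantile normalization with heavy zero inflation maps tie blocks to
  block means; the sorted-distribution identity is exact only up to tie
  structure.
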