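---
title: "Methods: tiling-array CGH copy number analysis in equicnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-array CGH copy number analysis in equicnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The measurement model

Two-channel array CGH hybridizes differently labelled sample and reference
DNA to a tiled probe set and reports, per probe, the log2 ratio of the two
intensities. With a diploid reference, the expected ratio at a locus with
`c` sample copies is `log2(c/2)`: 0 for copy-neutral loci, -1 for a
heterozygous loss, +0.585 for a heterozygous gain, +1 for a four-copy
amplification. A homozygous loss is formally `-Inf`; in practice background
hybridization bounds the observable depletion, and `equicnv` represents it
with a finite floor of -4.0 (deep published deletions reach run means near
-3.5, so the floor sits safely below anything the caller must classify,
while keeping simulated profiles finite).

The package assumes probe noise is additive, Gaussian and independent
across probes, with a standard deviation set by the DNA source: around 0.14
for blood-derived (and cultured-fibroblast) DNA and around 0.41 for
hair-follicle DNA. These two operating points anchor the quality-control
bands and all calibration tests.

# Quality control

`compute_dlrsd()` estimates per-probe noise as the standard deviation of
consecutive-probe log2 differences divided by `sqrt(2)`. The normalisation
is exact for i.i.d. noise (differencing doubles the variance), and true
copy-number structure contributes only two boundary terms per variant, so
on genome-scale profiles DLRSD is an almost unbiased estimate of the noise
sd; the test suite verifies recovery within 5% at 50,000 probes for both
0.14 and 0.41. Pairs spanning chromosome boundaries are excluded (a level
shift between chromosomes is not probe-to-probe noise) and missing values
are dropped before pairing. The plain standard deviation is the default;
an IQR-based variant (`robust = TRUE`) is available because vendor QC
implementations sometimes use robust spread estimators, but the plain form
is the one for which the calibration property holds exactly. Quality bands
follow the platform convention: below 0.2 excellent, 0.2-0.3 (inclusive)
good, above 0.3 poor.

A self-to-self hybridization carries no true copy-number signal, so every
call made on it is a false positive; `self_to_self_fdr()` expresses the
self-to-self call count as a percentage of all calls in an experiment set.

# The calling rule

`call_cnvs()` emits one call per maximal run of at least `min_probes`
(default 5) consecutive probes whose values all strictly exceed
`+log2_threshold` (default 0.5) or all fall strictly below the negative
threshold. Design choices worth stating explicitly:

* **Per-probe exceedance, not window means.** Commercial interval-score
  segmentation (e.g. ADM-2) weighs mean shift against interval length; its
  scoring is proprietary. The published calling contract this package
  implements - "more than 0.5 in absolute log2 over 5 neighbouring
  probes" - is realised here as every probe in the run exceeding the
  threshold. This is deterministic, exactly testable against a brute-force
  run enumeration, and conservative: any probe dipping inside the band
  splits or destroys a call (a property the tests assert). The choice is a
  deliberate divergence from proprietary segmentation, and `min_probes` /
  `log2_threshold` are configurable.
* **Strict inequality.** A probe at exactly +/-0.5 does not qualify, per
  the "alterations of > 0.5" reading; ties therefore break toward fewer
  calls.
* **Missing probes** are removed before adjacency is computed, so a run may
  bridge the position of a missing probe but never a probe that
  contradicts it. Runs never cross chromosome boundaries.
* **Zygosity from the run mean.** Calls with |mean log2| > 2.0 are flagged
  putative homozygous; using the mean rather than single probes prevents
  one noise spike from flipping the flag. At 5+ probes of sd 0.14 noise the
  mean's sampling error (< 0.07 sd) is negligible against the 1-vs-4 log2
  separation between heterozygous and homozygous losses.
* With sex-matched references, X-linked calls are ordinary calls; the
  simulator's `sex_effect` option exists to reproduce the
  male-vs-female-reference X shift as a positive control.

With sd 0.14 noise, the per-probe exceedance probability on a null probe is
`2 * pnorm(-0.5 / 0.14) ~ 3.6e-4`, so five consecutive same-sign
exceedances are vanishingly rare: a 400,000-probe null genome stays
call-free in virtually every seed (asserted over 20 seeds), and recall of
planted variants with |expected log2| >= 1 covering >= 5 probes is >= 99%.
Recall is scored against the union span of same-direction calls
overlapping a planted variant, with both boundaries required to land within
one local probe spacing (plus the 60 bp probe footprint): the conservative
run rule may split one variant at an interior noise dip, which leaves the
outer boundaries accurate, and boundary-accuracy-of-the-union is stricter
than the reciprocal-overlap scoring customary in CNV benchmarking.

# CNVR consolidation

Calls from all samples merge into copy number variable regions by
single-linkage chaining: two calls belong together iff they overlap by at
least one base or the end coordinate of one equals the start coordinate of
the next. In the package's 1-based inclusive coordinate convention that
adjacency case *is* a 1 bp overlap, so the merge relation reduces to
"share at least one base"; intervals that merely touch without sharing a
base (`end + 1 == start`) do not merge - the literal reading of the stated
adjacency rule. Because the relation is an interval overlap, a sweep over
start-sorted intervals realises the transitive closure; the tests compare
it against an explicit relation-matrix/connected-components oracle and
against `IRanges::reduce(min.gapwidth = 0)` as an independent
implementation. Single-linkage chaining can produce long composite regions
(multi-megabase CNVRs are an expected outcome, matching the largest
published horse CNVRs), and that is accepted rather than capped.

CNVR length is `end - start + 1`, used consistently in all size and
enrichment statistics. Reference animals can be excluded from
consolidation (`exclude_samples`), since a sample-vs-reference design makes
every call formally present in the reference with inverted sign; sharing
and breed counts are about the non-reference cohort.

State is `gain`/`loss` when all member calls agree and `complex` otherwise;
sharing counts distinct individuals, not calls; a breed-specific flag
requires at least two carriers, all of one breed, and no carrier of any
other breed. These rules are asserted against enumerated truth tables of up
to four calls.

# Annotation and summary statistics

A CNVR is genic if it overlaps any gene interval by at least one base - no
minimum overlap fraction, since none is part of the contract - and
sub-telomeric if it overlaps the terminal 1 Mb window at either chromosome
end (a single-end option exists for acrocentric karyotypes). Genic status
depends on the gene set supplied: a conservative single-annotation gene
list and a broader any-mammal evidence list legitimately give different
genic/intergenic splits, which is why the gene set is an input rather than
a constant. Chromosome enrichment is 100 x total CNVR length / chromosome
length (CNVRs are disjoint after consolidation, so lengths add); genome
enrichment uses the total assembly length including the unplaced-contig
pseudo-chromosome, and equals the length-weighted mean of the
per-chromosome values. Reporting rounds enrichment to 2 decimals and
per-sample means to 1 decimal, the precision of the published tables;
unrounded values are retained. The blood-vs-hair comparison of per-sample
call counts is an equal-variance two-sided Student's t test, with
fibroblast-derived samples excluded as a third source class.

# Cross-study integration

Published CNV tables mix coordinate conventions, so every input must
declare `one_based_inclusive` or `bed_half_open`; records are normalized
before merging, clipped to chromosome bounds with a warning, and rejected
on unknown chromosomes. Integration applies the identical positional merge
relation; gain/loss state is carried as metadata but never blocks a merge,
because the stated consolidation rule is purely positional. A study
contributing several records to one composite region counts once for that
region; a region is `shared` with two or more contributing studies and
`novel` otherwise, and shared + novel = total by construction. Re-deriving
the published composite horse dataset itself is out of scope (it requires
the external studies' supplementary files); the module is validated by
brute-force recounting on random instances, order invariance and
self-integration identities.

# The simulator: what it does and does not emulate

`design_probe_map()` places 60-mer probes on a jittered regular grid with
three spacing tiers - 7.5 kb genome-wide, 4 kb in the terminal 1 Mb of each
chromosome end, 20 kb on a chromosome named Y - and labels interior probes
genic at a fixed 21% (the approximate share of gene-derived probes on a
400K whole-genome design). Jitter is uniform within +/-30% of the tier
spacing by default; below 50% the probe order is provably preserved.
Sequence-aware probe selection (uniqueness screening, cross-hybridization
filters) is not modelled.

`plant_truth_cnvs()` draws per-sample variant counts from
Poisson(26.4) - the published cohort mean - with sizes log-uniform on
1 kb-2.5 Mb (the published size range), 72% losses (19.1 of 26.4 calls),
1.7% homozygous/high-amplitude states (16 of 950 calls), 30% of variants
shared into additional samples, and 2% breed-restricted. Shared copies fill
the recipients' Poisson quotas, so cohort totals remain
Poisson-consistent; a 36-sample cohort lands within 3 standard deviations
of 950 total calls. The shared fraction is the one parameter not directly
printed in a table: it was set once to 0.30, between the region-level
shared proportion (114 of 258) and the lower call-level sharing implied by
private regions, and not revisited. Truth variants of one sample never
overlap, which keeps recall scoring unambiguous. The chromosome named Y
receives probes but no planted variants (no Y CNVs exist in the discovery
dataset this emulates); the unplaced-contig class is simulated as one
pseudo-chromosome.

`simulate_hybridization()` adds i.i.d. Gaussian noise to the expected log2
baseline; the reference channel is treated as copy-neutral, with the
reference's own variant content left to an optional user-supplied truth
set, since sample-vs-reference data cannot distinguish the two. Per-sample
seeds derive deterministically from the master seed as
`(seed * 1000003 + i) mod 2147483629`, so any single sample can be
regenerated without simulating the cohort.

Not emulated: GC and dye bias, spatial and wave artifacts, probe-specific
affinity, segmental-duplication-driven clustering of variants, and real
EquCab2 sequence. Passing tests therefore demonstrate that the analysis
chain is correct under the stated noise model and study conditions - not
that the caller is robust to the correlated artifacts of real arrays,
which is what the DLRSD gate and conservative thresholds are for in
practice.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere inside the package; BED's
  0-based half-open convention is converted only at the file boundary, and
  coordinates are written without scientific notation.
* Chromosome order is authoritative from the genome build and reused for
  all sorting; interval ties sort by start, then end.
* Empty inputs: an empty profile yields an empty call set; consolidating
  zero calls yields an empty CNVR set; an empty interval set writes a
  valid empty BED. Profiles with fewer than two usable probes are an error
  for DLRSD. Chromosomes shorter than one spacing unit get zero probes
  with a warning. A planted variant covering zero probes is kept in the
  truth (it is a real, undetectable variant) with a warning.
* The pipeline writes no timestamps or environment-dependent strings, so
  two runs with one config and seed produce byte-identical bundles - a
  property the acceptance tests assert with checksums.

# Problem sizes

The test and acceptance workloads are sized for a single CPU: 50,000-probe
null profiles for QC calibration; a 10-sample cohort on the full
EquCab2-scale probe map (~340,000 probes) for recall; 20 seeds of a
400,000-probe null genome for the false-call rate; 200 random instances of
up to 20 intervals for the merge oracles; and the 3-chromosome toy genome
for end-to-end determinism.

# Known limitations

The caller's per-probe exceedance rule is intentionally stricter than
interval-score segmentation and will miss variants whose mean shift clears
the threshold only on average; with the default noise levels this costs
little (recall >= 99% for variants of at least 5 probes and |log2| >= 1)
but hair-grade noise (sd 0.41) pushes per-probe exceedance on *null*
probes to ~22%, so short spurious runs become possible and the DLRSD gate,
not the caller, is the safeguard for such samples. Allele-aware copy-number
genotyping, GO/pathway analysis and wet-lab validation workflows are out of
scope.
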