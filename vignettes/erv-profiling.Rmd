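---
title: "Profiling repressive chromatin over endogenous retroviruses: methods and design"
author: "ervprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling repressive chromatin over endogenous retroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervprofiler)
```

# The problem

Endogenous retroviruses (ERVs) — IAP, MusD/ETn, MMERVK10C, MLV and related
families in the mouse — are kept transcriptionally silent in embryonic stem
cells by repressive chromatin: H3K9me3 written by SETDB1 over the elements
themselves, DNA methylation of the LTR, and marks such as H4K20me3 that can
spread into the flanking genome. Quantifying that silencing raises a set of
recurring computational tasks, all of which this package implements at desk
scale with synthetic, ground-truth-bearing inputs:

1. average a ChIP-seq signal over the hundreds of genomic copies of a
   family by aligning reads to the family **consensus sequence** (a
   metaprofile), despite most reads mapping to many copies at once;
2. measure how the signal **decays with distance** from element boundaries
   in the single-copy flanking genome;
3. call **per-molecule CpG methylation** from bisulphite-sequenced clones,
   with conversion-efficiency QC;
4. reduce qPCR and ChIP-qPCR readouts to **fold changes and significance
   flags**.

# Consensus metaprofiles

## Model and conventions

Reads (50 bp by default) are placed on the consensus with the exact
Hamming-distance aligner; every minimum-distance placement is kept, and
`assign_multimappers()` retains exactly one per read, chosen uniformly at
random — the standard policy when LTRs and internal repeats make placements
ambiguous. Placements are then **directionally extended** 150 bp at the 3'
end, so each 50-bp read stands in for its ~200-bp sequenced fragment, and
per-position coverage is normalised as

RPKM(bin) = mean per-base depth in bin × 10⁹ / library size,

where the library size is the total number of reads uniquely mapped to the
reference genome for that library (not to the consensus). With a 1-bp bin
this is the familiar reads-per-kilobase-per-million convention applied
per position: one footprint of depth 1 with a library of 10⁶ gives
RPKM = 1000.

Three conventions are fixed here and exposed as parameters:

* **Extension** extends the 3' end (footprint = read length + extension);
  the alternative reading (total footprint = 150 bp) would discard the
  read's own 3' bases and is rejected.
* **Footprints are clipped** at the consensus/element boundaries rather
  than wrapped.
* All internal coordinates are 0-based half-open; SAM POS is converted at
  ingestion and nowhere else.

The multi-mapper RNG draws one uniform per read from a single seeded
stream after sorting groups canonically by read id, so selections are
deterministic given the seed and invariant to input row order.

## What recovery means, and edge effects

The simulator samples fragment starts from a known per-base weight field:
background everywhere, plus `enrichment_fold × body_profile` through each
planted copy, attenuated by `ko_attenuation` in the KO condition. Two
quantities connect profile to truth:

* the **mean body RPKM ratio** between conditions, whose closed-form
  expectation (`expected_body_ratio()`) is the ratio of body-weight shares
  of the two weight fields;
* the **shape correlation** between the per-position profile and the
  planted body profile.

Coverage is structurally deficient within one footprint (~200 bp) of the
consensus ends: a read only aligns if it lies entirely inside a copy, so
fragments beginning upstream of the element contribute nothing.
`profile_shape_correlation()` therefore excludes one footprint at each end
by default. Interior correlation on the default study condition (2-kb
consensus, 3 copies at 2% divergence, 2 × 10⁵ reads, 10-fold enrichment)
is ≈ 0.97, and the recovered wt/KO ratio is within a few percent of the
closed form.

# Flank density profiles

## Pipeline

Flank analysis uses reads aligned to the *genome*, not the consensus, and
applies three filters in a fixed order before agglomeration:

1. keep reads with map quality **strictly above 7** and a **unique**
   placement (`n_hits == 1`);
2. collapse reads mapped to the same (chrom, start, strand) to a single
   copy — positional deduplication. The dedup key includes strand (the
   less lossy convention; configurable);
3. map extended footprints overlapping the ±`flank_size` windows of each
   intact element to element-relative coordinates, orientation-flipping
   minus-strand elements so negative positions are always the biological
   5' flank, and sum counts over elements.

Density = counts / n_elements / (library_size / 10⁶). Doubling the element
set with identical reads leaves the density unchanged; doubling the library
size halves it. Reads overlapping the element body contribute only their
in-flank positions. Intactness is parameterised as minimum length and
maximum divergence — the catalogue-specific thresholds of any real element
set remain user inputs.

A k-mer **mappability** track (1 where the 50-mer starting at a position
occurs exactly once in the genome over both strands) verifies that flank
windows are not confounded by non-unique sequence; on random synthetic
genomes it is ≈ 1 away from planted duplications.

## Decay recovery and the genome-size choice

The simulator adds `enrichment_fold × exp(−d/λ)` to the weight at distance
d from the nearest element boundary. `fit_flank_decay()` bins the
agglomerated density by distance (250-bp bins pooled over both flanks) and
fits `C + A·exp(−d/λ)` by nonlinear least squares; C absorbs the uniform
background.

One condition matters for faithful recovery: **coverage sparsity**. Real
flank analyses place tens of millions of reads on a gigabase genome, so
positional deduplication removes almost nothing. If the same 2 × 10⁵-read
library is squeezed onto a toy genome of ~10⁵ bp, several reads fall on
every position, dedup collapses half the library, near-boundary bins
saturate, and the apparent decay scale inflates severalfold. The default
flank study condition therefore plants the elements in a 2-Mb genome,
where duplicates are ~4% and the fitted λ lands within the expected
sampling error of the planted 2 kb (Spearman correlation of density with
distance ≈ −0.99; KO density below wild type at every bin within one λ).

# Bisulphite clone analysis

Clones are end-gap-free, substitution-only alignments of amplicon
sequencing products to the unconverted reference; a length mismatch errors
out rather than risking a shifted CpG register. At each reference CpG,
clone C ⇒ methylated, T ⇒ unmethylated, anything else ⇒ missing (excluded
from both numerator and denominator of the clone's methylated fraction).
The **conversion rate** — non-CpG reference Cs read as T, among unambiguous
C/T bases — is the per-clone QC statistic; clones at or below the threshold
(default **strictly > 0.98**) are removed. Clones are assumed to be
top-strand (C→T space); a clone whose reference-G positions read
predominantly as A is rejected as a bottom-strand product.

Clone binning uses equal-width quartiles of the methylated fraction
([0,0.25], (0.25,0.5], (0.5,0.75], (0.75,1]), reported as percentages per
sample. The four-category boundaries are a declared convention (the
original figure style does not state them) and are configurable; the
percentages always sum to 100 per sample.

`insilico_pcr()` enumerates the loci a primer pair can amplify — forward
primer on one strand, reverse-complemented reverse primer downstream within
the product-size cap, both orientations scanned, products deduplicated —
the computation behind "primers that detect N elements" statements.

# qPCR statistics

ΔΔCt assumes 100% amplification efficiency (2.0 per cycle, matching the
instrument validation of the assays this mirrors): ΔCt = mean Ct(target) −
mean Ct(reference gene), ΔΔCt relative to the control sample, fold =
2^(−ΔΔCt). The control's fold is exactly 1 by construction, and adding any
constant to every Ct cancels. Replicate SDs combine in Ct space
(√(sd²ₜ + sd²ᵣ)) and map through 2^(−·) at mean ± sd; with one replicate
the fold is reported and the SD is NA.

ChIP enrichment is percent of input, 100 × 2^(Ct_input − Ct_IP) with an
optional dilution factor, optionally divided by the pan-H3 percent input at
the same amplicon — both conventions in use for repeat-element ChIP-qPCR
are provided because published legends do not always distinguish them.

Significance testing is the classical equal-variance two-tailed Student's
t-test (Welch optional), flagged \* at p < 0.05 and \*\* at p < 0.01, with
no multiple-testing adjustment by default (a deliberate mirror of
common qPCR practice; the caveat of testing over technical replicates is
documented rather than silently "corrected"). Degenerate zero-variance
input is an explicit error.

# The synthetic-data generator

`build_genome()` plants substitution-mutated copies (no indels, so copies
map linearly onto the consensus, consistent with the ungapped aligner) on
random strands in a uniform-random background. `simulate_chip_reads()`
samples fragment starts from the weight field described above; each
fragment yields one read from its 5' end on a uniformly chosen strand, so
directional extension reconstructs the fragment. Reads are error-free and
fixed-length: sequencing error is irrelevant to the profiling logic under
test. `simulate_bisulfite_clones()` methylates each CpG independently and
converts unmethylated Cs with the given probability;
`simulate_ct_table()` encodes planted folds as Ct shifts (1 cycle per
two-fold) with Gaussian replicate noise. All generators are
bit-reproducible given their seed and return their ground truth.

What the generator does **not** emulate: real consensus sequences or mm9
composition, indels/SNP structure beyond uniform substitutions, sequencing
error, fragment-length variation, GC or amplification bias, and real
library depths. Passing the recovery tests therefore demonstrates that the
*computations* are correct and well-calibrated on data whose generative
process is known — not that any particular biological dataset would yield
the same numbers.

# Numerical choices and degenerate inputs

* Problem sizes in the tests and acceptance script: 2-kb consensus ×
  3 copies, 120-kb genome for consensus recovery; 2-Mb genome for flank
  recovery; 2 × 10⁵ reads per library; 200 clones per bisulphite sample;
  oracle-equivalence checks on 100 randomised instances per operation with
  genomes ≤ 2 kb. These keep full runs to a few minutes while leaving
  comfortable statistical margins.
* Ratio pseudocount in profile comparison: 10⁻⁶ × the larger profile
  maximum, reported in the result.
* The decay fit starts at λ₀ = flank/4 with non-negativity bounds; the
  exponential-plus-constant model is identifiable here because the
  simulated background is genuinely uniform.
* Aligner ties: all minimum-distance placements are returned; resolution
  is delegated to the seeded multi-mapper step, never hidden in the
  aligner. Reads with no placement are counted, not dropped silently.
* Degenerate inputs error loudly: empty replicate vectors, zero pooled
  variance, library size ≤ 0, clones without CpGs, unalignable clone
  lengths, SAM records with indel/clip CIGARs.

# Known limitations

* The Hamming-only aligner ignores gaps; real BWA alignments tolerate one
  gap. Indel-bearing reads or clones are rejected, not mis-placed.
* Flank profiles use footprint coverage; read-start counting is available
  (`mode = "starts"`) because the original description is ambiguous.
* The λ estimator has noticeable sampling variance at 2 × 10⁵ reads
  (±10–15% across genome layouts); tolerances in the tests reflect that.
* Technical-replicate t-tests quantify instrument repeatability, not
  biological variability.
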