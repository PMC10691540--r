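---
title: "Detecting and testing alternative polyadenylation from 3'-end scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing alternative polyadenylation from 3'-end scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

3'-end single-cell and spatial RNA-seq protocols (10x Chromium, Visium)
sequence the ends of polyadenylated transcripts. Reads therefore pile up
just upstream of cleavage-and-polyadenylation sites (PAs), and a gene with
several PAs in its 3' UTR shows several pileups whose relative heights
reflect isoform usage. `apaflow` turns barcoded alignments into PA-level
molecule counts and tests whether PA usage differs between cell groups —
the signature of alternative polyadenylation (APA) and, for PAs upstream of
the last exon, intronic polyadenylation.

Two artifacts make this harder than simple peak counting. First,
neighbouring PAs closer than the width of a read pileup produce overlapping
peaks that must be deconvolved rather than split at an arbitrary boundary.
Second, the oligo(dT) primer can anneal to genomically templated A-rich
tracts, producing *internal priming* pileups that look exactly like PA
peaks but are not cleavage sites.

## The model and procedure

### Peak detection

For each gene the package builds deduplicated-UMI coverage over its
*extended* 3'-UTR regions: each (cell barcode, UMI) pair is collapsed to the
read at the lower-median location (location = midpoint of the CIGAR
`M`-covered span), and only `M` bases increment coverage, so spliced
alignments do not bleed across introns. Annotated 3' UTRs are extended
downstream (default 2000 bp, `utr_extension`) and truncated at the next
same-strand gene start, because annotation 3' ends are routinely too short
for 3'-end data; antisense neighbours are ignored since the libraries are
stranded. The extension length is a package default — annotations differ in
how far their UTR ends undershoot — and is the first parameter to revisit on
a new genome.

The coverage is smoothed with a Gaussian kernel (default bandwidth 25 bp).
The kernel is evaluated over the full track rather than truncated: a
truncated kernel plants tiny spurious maxima where the truncation edges of
two distant pileups meet, which a local-maximum scan would faithfully
report. Peak modes are the strict local maxima of the smoothed curve
(plateaus report their centre, floored). Modes with fewer than 10
deduplicated UMIs or with at most 5% of the reads of the largest in-UTR
mode are removed, and surviving modes within 50 bp are merged at the floor
of their mean. Because merging sums read counts and can promote a new
largest mode, the filter-and-merge pass is iterated to a fixpoint, which
makes the operation idempotent. A mode's read mass is defined by the
nearest-mode partition of UMI locations (ties to the downstream mode);
"nearest" is the simplest rule consistent with the later μ ± 3σ region
definition.

### Peak fitting

Modes are classified *isolated* or *overlapped* by transitive closure of a
300-bp radius relation. Isolated peaks are fitted by nonlinear least
squares of `A·exp(−(x−μ)²/2σ²)` on a ±300 bp window; overlapped clusters by
a K-component Gaussian mixture fitted with EM on the per-base counts (K =
number of modes, means initialised at the modes, σ at 50 bp, equal
weights). σ is clamped to [5, 350] bp — below 5 bp a "peak" is a mapping
artifact, above 350 bp it is background — and EM stops when the relative
log-likelihood change drops below 1e-4 (at most 200 iterations). A
component that collapses onto the σ floor with negligible weight is removed
and the cluster refitted with K−1. Peaks whose modes fall outside the
extended UTR are kept *during* cluster fitting, so that a real out-of-scope
pileup does not distort its neighbours' parameters, and discarded
afterwards.

### Annotation and internal-priming filtering

The distance between a fitted peak mode and its cleavage site is a property
of the protocol (priming position, read length), so it is estimated from
the data: genes with exactly one known PA and exactly one detected peak
serve as controls, and the 5%/95% type-7 quantiles of the signed
transcription-direction distances form the standard interval of distances
(SID); the median is kept as the best single offset. At least 50 controls
are required (`min_controls`); tiny datasets supply `sid_override()`.
Signed rather than absolute distances are used because modes sit
consistently upstream of cleavage sites in 3'-end data.

Each peak with mode *m* is then tested against three rules:

1. a known PA within `[m + lower, m + upper]`;
2. a polyadenylation-signal hexamer — AATAAA, ATTAAA or one of ten common
   variants — *starting* within the SID shifted 20 bp upstream,
   `[m + lower − 20, m + upper − 20]`, since the PAS sits ~20 bp upstream
   of the cleavage site it drives;
3. thirteen consecutive adenosines (an A-stretch) within the SID.

A peak is retained iff (rule 1 or rule 2) and not rule 3. Rule 3 searches
the SID itself, not a wider downstream window, keeping the filter aligned
with where the apparent cleavage site would be. Retained peaks are assigned
the known PA nearest `m + median(SID)` (ties downstream), or a *de novo* PA
at `m + median(SID)` when only the PAS motif supports them. Placing the de
novo site at the median control offset, rather than at the motif, uses the
estimated protocol geometry instead of assuming a fixed PAS-to-cleavage
distance.

### Quantification

Peak regions are `μ ± 3σ` from the fitted parameters. Each deduplicated UMI
is assigned by overlap of its representative read's `M` blocks: one
overlapping region wins outright; several are resolved by the maximum
posterior `w_k · N(x | μ_k, σ_k)` at the representative location (ties to
the downstream peak); none leaves the UMI unassigned but QC-tallied, so
that assigned + unassigned + tag-dropped equals the UMIs observed.
Isolated peaks take part in the posterior with weight 1 and their fitted
(μ, σ). The result is a sparse peak-by-cell matrix (MatrixMarket on disk);
Visium spot barcodes are treated exactly as cell barcodes.

### Differential testing

For gene *g* with J retained peaks, the counts of cell *i* are modelled as
`X_ig ~ Multinomial(n_ig, p_ig)`. A Pearson chi-square test on the pooled
group-by-peak table assumes `p_ig ≡ p_g` under the null — ignoring
biological cell-to-cell variability, which inflates false positives (the
acceptance run measures ~60% chi-square rejections at nominal 5% under an
overdispersed null). The package therefore also fits
`p_ig ~ Dirichlet(α_kg)` per group and tests `H_0: α_1g = … = α_Kg` with a
likelihood-ratio test: maximum-likelihood α by the digamma fixed-point
iteration (tolerance 1e-6, ≤500 iterations, α floored at 1e-8 and capped at
1e6, cells with `n_ig = 0` excluded, moment-based initialisation), and
`2(Σ_k ll_k − ll_pooled)` referred to chi-square with `(K−1)·J` degrees of
freedom. Zero between-cell variability makes the MLE diverge; such fits
return the capped α and are flagged as boundary fits. The final per-gene
p-value is the *maximum* of the two tests' p-values — a gene must fail both
nulls — followed by Benjamini–Hochberg correction across the genes of the
comparison.

Two effect sizes accompany the test:

* **WARM** (weighted average relative mode position): peaks get relative
  positions 0 (most proximal) to 1 (most distal); linear interpolation of
  genomic mode positions when all peaks share one 3' UTR, rank-based
  spacing `(rank−1)/(n−1)` otherwise, so that the endpoints are exactly 0
  and 1 in both schemes. WARM is the count-weighted mean; higher means
  longer 3' UTRs. Per-cell WARM averages over expressed multipeak genes
  with equal or expression weights.
* **MPRO** (maximum difference in proportion change): per peak,
  `δ = proportion in base − proportion in alt`; over all ordered pairs
  (upstream j, downstream i) the extreme `δ_i − δ_j`, signed. Positive
  means the base group uses more distal peaks. For two peaks MPRO equals
  twice the change in distal proportion, so its range is [−2, 2] — it is
  deliberately *not* rescaled to [−1, 1], and truth tables and results
  store the enumerated value.

A gene is a final differential signal iff its BH-adjusted p ≤ 0.05
(inclusive), every group expresses at least one peak in strictly more than
5% of its cells, and |MPRO| > 0.2 (strict). With more than two groups MPRO
is reported as the extreme value over all group pairs.

Hierarchical comparisons over a cell-type taxonomy test every node against
the other cells of its parent, repeating up to the root; nodes that fill
their parent completely are skipped (their comparison is empty), and BH is
applied within each comparison.

## The simulator, and what passing its tests shows

`simulate_apa_dataset()` generates a random-base genome with genes on both
strands and two chromosomes, an `AATAAA` planted 20 bp upstream of every
cleavage site, a GTF, a PA BED (withholding the de novo fraction), and a
tagged, sorted, indexed BAM. Per cell and gene, UMI counts are negative
binomial (mean 15, size 2), peak choice is multinomial with per-cell
Dirichlet proportions (precision 10; differential genes flip a
proximal-biased profile between the groups), and read positions are rounded
Gaussians around each peak mode (σ = 30 bp), truncated at ±2σ. The
truncation is part of the generative model: it makes every molecule
assignable to its μ ± 3σ region, so the count matrix can be compared to
truth *exactly*; its cost is that fitted σ estimates undershoot the nominal
σ by ~12% (the sd of a ±2σ-truncated Gaussian). 30% of UMIs emit a
duplicate read jittered within ±5 bp; 10% of reads are written with spliced
`30M100N61M` CIGARs to exercise M-only counting; internal-priming genes
plant a 13-A stretch 60 bp downstream of a decoy mode between the first two
cleavage sites and pile extra reads there. Accidental A/T homopolymers of
13+ in transcribed regions are broken so rule 3 fires only where planted.

The defaults (20 genes, 2–3 PAs at 400 bp spacing, 2 × 100 cells) are the
reference study conditions used by the test-suite; the tests scale the cell
count to 60 per group to keep the default run inside a few minutes, stated
here as the package's choice of problem size.

What the simulator does **not** emulate: mapping ambiguity and soft
clipping, barcode errors and collisions, sequencing errors, gene-level
expression structure, overlapping genes on the same strand, and pileup
shapes that deviate from a (truncated) Gaussian. Passing the end-to-end
tests therefore demonstrates that the algorithmic chain is correct under
its own model assumptions — not that real tissue data will be this clean.
On real data the SID is wider, peaks are skewed, and a fraction of UMIs is
legitimately unassignable.

## Numerical and design choices

* Coordinates are 1-based closed internally (the GenomicRanges convention);
  BED is converted at its read/write boundary. GTF/BED writers are
  canonical so write→read→write round-trips are byte-stable.
* Lower-median dedup, floored merge positions, floored plateau centres, and
  downstream tie-breaks (nearest-mode partition, posterior assignment,
  known-PA choice) make every path deterministic; reruns are
  byte-identical.
* The EM log-likelihood is non-decreasing (asserted per iteration in the
  tests) except, in principle, when the σ clamps engage; exactly
  superimposed initial means converge without error (the split between the
  two identical components is unidentifiable, their total mass is not).
* `sample()`'s scalar-range gotcha is avoided in the simulator
  (`pool[sample.int(length(pool), …)]`), so `peaks_min == peaks_max`
  configurations behave as written.
* Degenerate inputs: genes with no coverage are skipped; degenerate pooled
  tables give p = 1 with a flag; groups with no expressing cells drop out
  of the DM fit and flag the gene; zero-count WARM/MPRO are `NA`, never 0.

## Known limitations

* Peak shapes are symmetric Gaussians; strongly skewed pileups (common at
  high-usage PAs) shift μ slightly downstream and widen σ.
* The chi-square component uses the pooled contingency table; a cell-level
  score test would be an alternative with different small-sample behaviour.
* The DM LRT's `(K−1)·J` reference distribution is asymptotic; with very
  few expressing cells per group the combined test leans on the chi-square
  component's conservatism under the max-p rule.
* Multi-UTR genes are testable (rank-based WARM), but the peak caller does
  not deconvolve overlapping transcripts that share genomic 3' ends.
* BH correction in hierarchical mode is per comparison; signals replicated
  across many nodes are reported per node, not jointly corrected.
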