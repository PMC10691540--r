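# apaflow

Detection, quantification and differential testing of alternative
polyadenylation (APA) from barcoded 3'-end single-cell and spatial RNA-seq
alignments (10x Chromium / Visium conventions: `CB`/`UB` tags,
coordinate-sorted indexed BAM).

3'-end protocols sequence transcript ends, so reads pile up just upstream
of each polyadenylation site (PA). `apaflow` turns those pileups into
PA-level molecule counts per cell and asks whether PA usage shifts between
cell groups — the readout of 3'-UTR shortening/lengthening and intronic
polyadenylation. For readers of the code, the pipeline is:

1. **Peak calling** — deduplicated-UMI coverage over extended 3' UTRs,
   Gaussian-kernel smoothing, local-maximum modes, read-count filtering
   (≥10 UMIs, >5% of the largest mode) and 50-bp merging. Isolated peaks
   are fitted as `A·exp(−(x−μ)²/2σ²)` by least squares; peaks within 300 bp
   of each other are deconvolved jointly with a K-component Gaussian
   mixture fitted by EM.
2. **Annotation** — the peak-mode→cleavage-site distance interval (SID: 5%
   and 95% quantiles) is estimated from single-PA/single-peak control
   genes. A peak is retained iff it has a known PA in the SID (rule 1) or a
   polyadenylation-signal hexamer (AATAAA and 11 variants) in the SID
   shifted 20 bp upstream (rule 2), and no 13-adenosine stretch in the SID
   (rule 3, the internal-priming filter).
3. **Quantification** — each UMI's representative read (lower-median
   location) is assigned to a peak region `μ ± 3σ`, multi-overlaps resolved
   by the mixture posterior `w_k · N(x|μ_k, σ_k)`; output is a sparse
   peak-by-cell matrix (MatrixMarket).
4. **Differential testing** — per multipeak gene, a pooled chi-square test
   and a Dirichlet-multinomial likelihood-ratio test
   (`X_ig ~ Multinomial(n_ig, p_ig)`, `p_ig ~ Dirichlet(α_kg)`,
   `H_0: α_1g = … = α_Kg`) combined by the **maximum** p-value, BH-adjusted.
   Effect sizes: **WARM** (count-weighted mean relative mode position,
   0 = proximal, 1 = distal) and **MPRO** (extreme downstream-minus-upstream
   difference in proportion change; positive = base group more distal).
   A signal requires adjusted p ≤ 0.05, each group expressing a peak in
   >5% of cells, and |MPRO| > 0.2. Hierarchical mode walks a cell-type
   taxonomy, testing each node against the rest of its parent.

A bundled simulator (`simulate_apa_dataset()`) generates fully
ground-truthed FASTA/GTF/BED/BAM inputs — planted PAS hexamers,
internal-priming A-stretches, withheld "de novo" PAs, per-cell
Dirichlet-multinomial usage — so every stage is testable without downloads.

See `vignettes/apa-detection.Rmd` for the methods account and the
modelling assumptions.

## Worked example

Simulate a small dataset and run the whole pipeline (the 20-gene defaults
live in `sim_config()`; here 6 genes, 2 × 40 cells):

```r
library(apaflow)

cfg <- sim_config(seed = 42, n_genes = 6, cells_per_group = 40)
sim <- simulate_apa_dataset(cfg, "readme-sim")
out <- run_apa_pipeline(
  bam = sim$bam, gtf = sim$gtf, pa_bed = sim$pa_bed, fasta = sim$fasta,
  barcodes = sim$barcodes_file, groups = sim$groups_file,
  out_dir = "readme-out",
  sid = sid_override(40, 90, 65))   # tiny fixture: no SID control genes

print(out$counts)
#> apa_counts: 14 peaks x 80 cells, 7625 UMIs assigned (36 unassigned)

as.data.frame(out$results)[, c("gene_id", "n_peaks", "p_adj", "mpro",
                               "warm_g1", "warm_g2", "significant")]
#>   gene_id n_peaks    p_adj    mpro warm_g1 warm_g2 significant
#> 1     g01       2 4.19e-12 -0.6917   0.299   0.645        TRUE
#> 2     g02       2 5.91e-01  0.0703   0.611   0.576       FALSE
#> 3     g03       2 7.00e-01 -0.0411   0.447   0.468       FALSE
#> 4     g04       2 1.36e-12 -0.8350   0.296   0.713        TRUE
#> 5     g05       3 7.00e-01  0.1050   0.489   0.450       FALSE
#> 6     g06       3 3.49e-12 -0.5511   0.358   0.633        TRUE
```

The three significant genes are exactly the three the simulator planted
with flipped peak usage (`sim$truth$genes$differential`). Reading one row:
g01's group g1 has WARM 0.30 vs 0.65 in g2 — g1 favours the proximal peak —
and MPRO −0.69 means the base group (g1) shifted usage toward proximal
peaks by an extreme pairwise proportion change of 0.69. `readme-out/`
contains every stage as TSV/BED/MTX plus the parameter echo, and
`render_gene_report()` draws the per-gene coverage with fitted peak regions
and PA ticks (with a TSV twin of the plotted data).

A thin CLI over the same functions is installed at `inst/cli/apa.R`
(subcommands `simulate`, `run-all`, `report`).

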