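# Shared fixtures, built in code. The full simulated dataset is expensive
# (BAM writing + indexing), so it is memoised for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

# Reference simulated dataset at the study conditions: 20 genes, 2-3 PAs
# each, >= 300 bp separation, ~10% internal-priming and de novo genes.
ref_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    dir <- file.path(tempdir(), "apaflow-ref-sim")
    cfg <- sim_config(seed = 11, n_genes = 20, cells_per_group = 60)
    .fixture_cache$sim <- simulate_apa_dataset(cfg, dir)
    .fixture_cache$models <- extend_utrs(load_gene_models(.fixture_cache$sim$gtf), 2000)
  }
  list(sim = .fixture_cache$sim, models = .fixture_cache$models)
}

# Pipeline objects derived from the reference simulation (SID overridden
# with the generator's known mode->cleavage offset; 20 multi-PA genes
# contain no single-PA control genes).
ref_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    fx <- ref_sim()
    peaks <- call_peaks(fx$sim$bam, fx$models)
    pa <- load_pa_reference(fx$sim$pa_bed)
    ann <- annotate_peaks(peaks, sid_override(40, 90, 65), pa, fx$sim$fasta)
    counts <- count_peaks(fx$sim$bam, ann, fx$models, fx$sim$barcodes)
    .fixture_cache$pipe <- list(peaks = peaks, pa = pa, ann = ann, counts = counts)
  }
  c(ref_sim(), .fixture_cache$pipe)
}

# Minimal hand-written GTF for coordinate-convention tests.
write_toy_gtf <- function(path, lines) {
  writeLines(lines, path)
  path
}

# Tiny FASTA with given chromosome sequences; indexed.
write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  Rsamtools::indexFa(path)
  path
}

# A bare gene model (single interval UTR), for unit tests that need one.
toy_model <- function(gene_id = "g", chrom = "chr1", strand = "+",
                      utr_start = 1000, utr_end = 2000) {
  utr <- data.frame(start = utr_start, end = utr_end)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = list(), utr = utr, ext = utr),
            class = "apa_gene_model")
}

# Build an apa_counts object directly from a cells x J count matrix (one
# gene), bypassing the BAM layer, for statistical tests.
counts_from_matrix <- function(X, mu = NULL, strand = "+", gene_id = "g1") {
  J <- ncol(X)
  if (is.null(mu)) mu <- 1000 + (0:(J - 1)) * 400
  cells <- sprintf("c%04d", seq_len(nrow(X)))
  peaks <- data.frame(gene_id = gene_id,
                      peak_id = sprintf("%s:P%d", gene_id, 1:J),
                      chrom = "chr1", strand = strand, mu = mu, sigma = 30,
                      weight = 1 / J, stringsAsFactors = FALSE)
  m <- methods::as(Matrix::Matrix(t(X), sparse = TRUE,
                                  dimnames = list(peaks$peak_id, cells)),
                   "CsparseMatrix")
  structure(list(matrix = m, peaks = peaks, barcodes = cells, qc = list()),
            class = "apa_counts")
}

# Dirichlet-multinomial count sampler used by the statistical tests (the
# same generative model the simulator uses, at the count layer).
rdm_counts <- function(ncell, alpha, umi_mean = 15, umi_size = 2) {
  J <- length(alpha)
  n_i <- stats::rnbinom(ncell, mu = umi_mean, size = umi_size)
  g <- matrix(stats::rgamma(ncell * J, shape = rep(alpha, each = ncell)), ncol = J)
  P <- g / rowSums(g)
  t(vapply(seq_len(ncell), function(c) {
    if (n_i[c] > 0) stats::rmultinom(1, n_i[c], P[c, ])[, 1] else integer(J)
  }, integer(J)))
}
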