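# UMI-to-peak assignment and the peak-by-cell count matrix. Peak regions
# are mu +/- 3*sigma from the fitted shapes; multi-overlap reads go to the
# component with the maximum posterior under the fitted mixture.

#' Assign a deduplicated UMI to a peak
#'
#' Overlap is computed on the representative read's M-covered blocks against
#' each retained peak's region `[mu - 3 sigma, mu + 3 sigma]`. A single
#' overlap wins outright; multiple overlaps are resolved by the maximum
#' posterior `weight_k * N(loc | mu_k, sigma_k)` at the representative
#' location, ties broken to the transcription-downstream peak.
#'
#' @param loc representative location (midpoint of the M-covered span)
#' @param blocks 2-column matrix of M-block `start`/`end` positions
#' @param peaks data.frame of the gene's retained peaks (`mu`, `sigma`,
#'   `weight`, `strand`)
#' @return the row index of the assigned peak, or `NA` if no region overlaps
#' @export
assign_peak <- function(loc, blocks, peaks) {
  if (nrow(peaks) == 0) return(NA_integer_)
  lo <- floor(peaks$mu - 3 * peaks$sigma)
  hi <- ceiling(peaks$mu + 3 * peaks$sigma)
  ov <- vapply(seq_len(nrow(peaks)), function(k) {
    any(blocks[, "start"] <= hi[k] & blocks[, "end"] >= lo[k])
  }, logical(1))
  hits <- which(ov)
  if (length(hits) == 0) return(NA_integer_)
  if (length(hits) == 1) return(hits)
  post <- peaks$weight[hits] * stats::dnorm(loc, peaks$mu[hits], peaks$sigma[hits])
  best <- which(post == max(post))
  if (length(best) > 1) {
    best <- if (peaks$strand[1] == "+") best[which.max(peaks$mu[hits][best])] else
      best[which.min(peaks$mu[hits][best])]
  }
  hits[best]
}

#' Build the peak-by-cell count matrix
#'
#' One pass per gene over the BAM: reads are collapsed per (cell, UMI) to
#' the lower-median representative, each representative is assigned to one
#' retained peak (or left unassigned), and counts are accumulated for the
#' supplied barcodes.
#'
#' @param bam path to a coordinate-sorted, indexed BAM
#' @param peaks annotated peaks; only rows with `status == "retained"` are
#'   quantified (a plain `apa_peaks` table is accepted and used as-is)
#' @param models extended gene models
#' @param barcodes character vector of cell barcodes (matrix columns)
#' @param cb_tag,ub_tag,min_mapq read filters (see [build_coverage()])
#' @return an `apa_counts` object: sparse `matrix` (peaks x cells), the
#'   `peaks` metadata, `barcodes`, and a `qc` list whose per-gene tallies
#'   satisfy assigned + unassigned + dropped = total UMIs
#' @export
count_peaks <- function(bam, peaks, models, barcodes, cb_tag = "CB",
                        ub_tag = "UB", min_mapq = 255) {
  if (length(barcodes) == 0) stop("barcode list is empty")
  if ("status" %in% names(peaks)) peaks <- peaks[peaks$status == "retained", , drop = FALSE]
  peaks <- as.data.frame(peaks)
  rownames(peaks) <- NULL
  np <- nrow(peaks)
  cell_idx <- seq_along(barcodes)
  names(cell_idx) <- barcodes
  ii <- integer(0); jj <- integer(0)
  qc <- list(assigned = 0L, unassigned = 0L, dropped_tag = 0L,
             unlisted_barcode = 0L, total_umis = 0L)
  for (g in unique(peaks$gene_id)) {
    model <- models[[g]]
    gp <- which(peaks$gene_id == g)
    tab <- gene_umi_table(bam, model, cb_tag, ub_tag, min_mapq)
    qc$dropped_tag <- qc$dropped_tag + tab$qc$dropped_tag
    qc$total_umis <- qc$total_umis + nrow(tab$umi) + tab$qc$dropped_tag
    if (nrow(tab$umi) == 0) next
    gpeaks <- peaks[gp, , drop = FALSE]
    ks <- vapply(seq_len(nrow(tab$umi)), function(u) {
      assign_peak(tab$umi$loc[u], tab$blocks[[u]], gpeaks)
    }, integer(1))
    qc$unassigned <- qc$unassigned + sum(is.na(ks))
    ok <- !is.na(ks)
    cj <- cell_idx[tab$umi$cell]
    qc$unlisted_barcode <- qc$unlisted_barcode + sum(ok & is.na(cj))
    use <- ok & !is.na(cj)
    qc$assigned <- qc$assigned + sum(use)
    ii <- c(ii, gp[ks[use]]); jj <- c(jj, unname(cj[use]))
  }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                              dims = c(np, length(barcodes)),
                              dimnames = list(peaks$peak_id, barcodes))
  structure(list(matrix = methods::as(mat, "CsparseMatrix"), peaks = peaks,
                 barcodes = barcodes, qc = qc),
            class = "apa_counts")
}

#' @export
print.apa_counts <- function(x, ...) {
  cat(sprintf("apa_counts: %d peaks x %d cells, %d UMIs assigned (%d unassigned)\n",
              nrow(x$matrix), ncol(x$matrix), x$qc$assigned, x$qc$unassigned))
  invisible(x)
}

#' Write a peak-by-cell matrix to a directory
#'
#' MatrixMarket `matrix.mtx` plus `peaks.tsv` (row metadata) and
#' `barcodes.tsv`.
#'
#' @param counts an `apa_counts` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_peak_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts$matrix, file.path(dir, "matrix.mtx"))
  utils::write.table(counts$peaks, file.path(dir, "peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(counts$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a peak-by-cell matrix written by [write_peak_counts()]
#'
#' @param dir directory containing `matrix.mtx`, `peaks.tsv`, `barcodes.tsv`
#' @return an `apa_counts` object
#' @export
read_peak_counts <- function(dir) {
  mat <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  peaks <- utils::read.table(file.path(dir, "peaks.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(mat) <- list(peaks$peak_id, barcodes)
  structure(list(matrix = mat, peaks = peaks, barcodes = barcodes,
                 qc = list()),
            class = "apa_counts")
}
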