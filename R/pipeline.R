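# Pipeline orchestration and per-gene reporting: prepare -> callpeaks ->
# annotate -> count -> test, with every stage output written as a reusable
# text file and the effective parameters echoed for provenance.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full APA pipeline
#'
#' Executes all stages in order and writes `peaks.tsv`,
#' `annotated_peaks.tsv`, `assigned_pa.bed`, the count matrix directory
#' `counts/`, `results.tsv`, `cell_warm.tsv` and the parameter echo
#' `params.dcf` into `out_dir`.
#'
#' @param bam tagged, coordinate-sorted, indexed BAM
#' @param gtf gene models GTF
#' @param pa_bed known-PA BED6
#' @param fasta indexed genome FASTA
#' @param barcodes barcode file (one per line) or character vector
#' @param groups cell-to-group TSV (`cell`, `group`) or data.frame; NULL
#'   skips the testing stage
#' @param out_dir output directory
#' @param utr_extension 3'-UTR extension in bp (default 2000)
#' @param bandwidth,min_reads,min_frac,merge_dist,radius peak-calling
#'   parameters (see [call_peaks()])
#' @param sid optional `apa_sid` override; NULL estimates it from
#'   single-PA/single-peak control genes
#' @param min_controls minimum control genes for SID estimation
#' @param pas_shift,a_stretch_len annotation parameters
#' @param alpha,min_frac_expr,mpro_min final-signal thresholds
#' @param taxonomy optional taxonomy data.frame for hierarchical testing
#' @param cb_tag,ub_tag,min_mapq BAM read filters
#' @return invisibly, a list with all stage objects and output paths
#' @export
run_apa_pipeline <- function(bam, gtf, pa_bed, fasta, barcodes, groups = NULL,
                             out_dir, utr_extension = 2000, bandwidth = 25,
                             min_reads = 10, min_frac = 0.05, merge_dist = 50,
                             radius = 300, sid = NULL, min_controls = 50,
                             pas_shift = 20, a_stretch_len = 13, alpha = 0.05,
                             min_frac_expr = 0.05, mpro_min = 0.2,
                             taxonomy = NULL, cb_tag = "CB", ub_tag = "UB",
                             min_mapq = 255) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(utr_extension = utr_extension, bandwidth = bandwidth,
                 min_reads = min_reads, min_frac = min_frac,
                 merge_dist = merge_dist, radius = radius,
                 min_controls = min_controls, pas_shift = pas_shift,
                 a_stretch_len = a_stretch_len, alpha = alpha,
                 min_frac_expr = min_frac_expr, mpro_min = mpro_min,
                 cb_tag = cb_tag, ub_tag = ub_tag, min_mapq = min_mapq)
  write.dcf(as.data.frame(params), file.path(out_dir, "params.dcf"))

  message("[prepare] reading gene models and PA reference")
  models <- run_stage("prepare", {
    if (!file.exists(pa_bed)) stop("PA BED not found: '", pa_bed,
                                   "' (supply via pa_bed=)")
    m <- load_gene_models(gtf)
    extend_utrs(m, utr_extension)
  })
  pa_sites <- run_stage("prepare", load_pa_reference(pa_bed))
  if (is.character(barcodes) && length(barcodes) == 1 && file.exists(barcodes)) {
    barcodes <- readLines(barcodes)
  }

  message("[callpeaks] building coverage and fitting peaks")
  peaks <- run_stage("callpeaks", {
    call_peaks(bam, models, bandwidth = bandwidth, min_reads = min_reads,
               min_frac = min_frac, merge_dist = merge_dist, radius = radius,
               cb_tag = cb_tag, ub_tag = ub_tag, min_mapq = min_mapq,
               keep_coverage = TRUE)
  })
  utils::write.table(as.data.frame(peaks), file.path(out_dir, "peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[annotate] estimating SID and applying retention rules")
  annotated <- run_stage("annotate", {
    if (is.null(sid)) sid <- estimate_sid(peaks, pa_sites, models, min_controls)
    annotate_peaks(peaks, sid, pa_sites, fasta, pas_shift, a_stretch_len)
  })
  utils::write.table(as.data.frame(annotated),
                     file.path(out_dir, "annotated_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ret <- annotated[annotated$status == "retained", , drop = FALSE]
  if (nrow(ret) > 0) {
    bed <- data.frame(chrom = ret$chrom, pos = ret$pa_pos, strand = ret$strand,
                      source = ret$pa_source, stringsAsFactors = FALSE)
    class(bed) <- c("apa_pa_sites", "data.frame")
    write_pa_sites(bed, file.path(out_dir, "assigned_pa.bed"))
  }

  message("[count] assigning UMIs to peaks")
  counts <- run_stage("count", count_peaks(bam, annotated, models, barcodes,
                                           cb_tag, ub_tag, min_mapq))
  write_peak_counts(counts, file.path(out_dir, "counts"))

  results <- NULL
  hier <- NULL
  if (!is.null(groups)) {
    message("[test] differential PA testing")
    if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
      groups <- utils::read.table(groups, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    }
    results <- run_stage("test", test_pa(counts, groups, alpha = alpha,
                                         min_frac = min_frac_expr,
                                         mpro_min = mpro_min))
    utils::write.table(as.data.frame(results), file.path(out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cw <- compute_cell_warm(counts)
    utils::write.table(data.frame(cell = names(cw), warm = unname(cw)),
                       file.path(out_dir, "cell_warm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(taxonomy)) {
      message("[test] hierarchical taxonomy tests")
      hier <- run_stage("test", hierarchical_test_pa(counts, taxonomy,
                                                     alpha = alpha,
                                                     min_frac = min_frac_expr,
                                                     mpro_min = mpro_min))
      if (!is.null(hier$results)) {
        utils::write.table(hier$results, file.path(out_dir, "results_hierarchical.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(list(models = models, pa_sites = pa_sites, peaks = peaks,
                 annotated = annotated, counts = counts, results = results,
                 hierarchical = hier, out_dir = out_dir,
                 tracks = attr(peaks, "tracks")))
}

#' Render a per-gene coverage/peak report
#'
#' Plots the raw and smoothed coverage with peak regions (mu +/- 3 sigma),
#' assigned PA ticks and retained/discarded styling, and writes the data
#' behind the plot as a TSV twin so the figure is never the only record.
#'
#' @param gene_id gene to report
#' @param tracks named list of `apa_coverage` tracks (e.g. from
#'   `run_apa_pipeline()$tracks`)
#' @param annotated annotated peak table
#' @param out_prefix output path prefix; writes `<prefix>.pdf` and
#'   `<prefix>.tsv`
#' @param bandwidth smoothing bandwidth for the displayed curve
#' @return list with the two output paths
#' @export
render_gene_report <- function(gene_id, tracks, annotated, out_prefix,
                               bandwidth = 25) {
  if (!gene_id %in% names(tracks)) {
    near <- utils::head(agrep(gene_id, names(tracks), value = TRUE,
                              max.distance = 0.3), 5)
    stop("unknown gene '", gene_id, "'",
         if (length(near) > 0) paste0("; did you mean: ",
                                      paste(near, collapse = ", ")) else "")
  }
  track <- tracks[[gene_id]]
  pos <- track$start:track$end
  curve <- smooth_coverage(track, bandwidth)
  tsv <- paste0(out_prefix, ".tsv")
  utils::write.table(data.frame(pos = pos, coverage = track$counts,
                                smoothed = round(curve, 6)),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  pk <- annotated[annotated$gene_id == gene_id, , drop = FALSE]
  pdf_path <- paste0(out_prefix, ".pdf")
  grDevices::pdf(pdf_path, width = 8, height = 4)
  on.exit(grDevices::dev.off())
  if (sum(track$counts) == 0) {
    graphics::plot.new()
    graphics::title(main = paste0(gene_id, " (", track$strand, "): no coverage"))
  } else {
    graphics::plot(pos, track$counts, type = "h", col = "grey70",
                   xlab = paste0(track$chrom, " position"), ylab = "UMI coverage",
                   main = paste0(gene_id, " (", track$strand, ")"))
    graphics::lines(pos, curve, col = "steelblue", lwd = 2)
    if (nrow(pk) > 0) {
      for (i in seq_len(nrow(pk))) {
        kept <- pk$status[i] == "retained"
        col <- if (kept) "darkgreen" else "firebrick"
        graphics::rect(pk$mu[i] - 3 * pk$sigma[i], 0, pk$mu[i] + 3 * pk$sigma[i],
                       max(track$counts) * 0.05, border = NA,
                       col = grDevices::adjustcolor(col, 0.3))
        if (!kept) {
          graphics::text(pk$mu[i], max(track$counts) * 0.1, pk$status[i],
                         col = col, cex = 0.6)
        }
        if (!is.na(pk$pa_pos[i])) {
          graphics::abline(v = pk$pa_pos[i], col = "red", lty = 2)
        }
      }
    }
  }
  list(pdf = pdf_path, tsv = tsv)
}
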