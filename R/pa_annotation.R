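# Peak annotation and internal-priming filtering: estimate the peak-mode to
# cleavage-site distance interval (SID) from single-PA single-peak control
# genes, then retain peaks supported by a known PA (rule 1) or a
# polyadenylation-signal hexamer (rule 2) unless an A-stretch marks them as
# internal-priming artifacts (rule 3).

#' Polyadenylation-signal hexamers
#'
#' The canonical A\[A/T\]TAAA signals plus the ten common single-base
#' variants scanned by [scan_pas_motifs()].
#' @export
PAS_HEXAMERS <- c("AATAAA", "ATTAAA", "TTTAAA", "AAGAAA", "AACAAA", "TATAAA",
                  "AATGAA", "AGTAAA", "AATATA", "CATAAA", "ACTAAA", "GATAAA")

#' Estimate the standard interval of peak-mode to PA distance (SID)
#'
#' Control genes are those with exactly one known PA inside their extended
#' 3'-UTR regions and exactly one peak called. The SID is the 5% and 95%
#' quantile (type 7) of the signed transcription-direction distances
#' `cleavage site - peak mode`; the median is kept for de novo PA placement.
#'
#' @param peaks an `apa_peaks` data.frame from [call_peaks()]
#' @param pa_sites known PA sites from [load_pa_reference()]
#' @param models extended gene models
#' @param min_controls minimum number of control genes (default 50)
#' @return an `apa_sid` object: `lower`, `upper`, `median`, `n`, `distances`
#' @export
estimate_sid <- function(peaks, pa_sites, models, min_controls = 50) {
  cnt <- table(peaks$gene_id)
  single_peak <- names(cnt)[cnt == 1]
  d <- numeric(0)
  for (g in single_peak) {
    m <- models[[g]]
    if (is.null(m)) next
    hit <- pa_sites$chrom == m$chrom & pa_sites$strand == m$strand &
      in_regions(pa_sites$pos, m$ext)
    if (sum(hit) != 1) next
    mu <- peaks$mu[peaks$gene_id == g]
    d <- c(d, txn_offset(mu, m$strand, pa_sites$pos[hit]))
  }
  if (length(d) < min_controls) {
    stop("only ", length(d), " single-PA/single-peak control genes (need ",
         min_controls, "); supply an explicit SID via sid_override()")
  }
  q <- stats::quantile(d, c(0.05, 0.95), type = 7, names = FALSE)
  structure(list(lower = q[1], upper = q[2], median = stats::median(d),
                 n = length(d), distances = d),
            class = "apa_sid")
}

#' Construct an SID manually
#'
#' For small fixtures or datasets without enough control genes.
#'
#' @param lower,upper signed transcription-direction offsets in bp
#' @param median offset used for de novo PA placement (defaults to the
#'   interval midpoint)
#' @return an `apa_sid` object
#' @export
sid_override <- function(lower, upper, median = (lower + upper) / 2) {
  stopifnot(lower <= upper)
  structure(list(lower = lower, upper = upper, median = median,
                 n = 0L, distances = numeric(0)),
            class = "apa_sid")
}

#' @export
print.apa_sid <- function(x, ...) {
  cat(sprintf("SID [%g, %g] bp (median %g, %d control genes)\n",
              x$lower, x$upper, x$median, x$n))
  invisible(x)
}

#' Scan a sequence for polyadenylation-signal hexamers
#'
#' All (possibly overlapping) occurrences of the 12 PAS hexamers
#' ([PAS_HEXAMERS]) in a sequence given in transcription orientation.
#' `N` never matches; characters outside `ACGTN` are rejected.
#'
#' @param seq nucleotide string
#' @return data.frame with `motif` and `pos` (1-based start)
#' @export
scan_pas_motifs <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside ACGTN")
  n <- nchar(seq)
  if (n < 6) return(data.frame(motif = character(0), pos = integer(0)))
  subs <- substring(seq, 1:(n - 5), 6:n)
  hit <- subs %in% PAS_HEXAMERS
  data.frame(motif = subs[hit], pos = which(hit), stringsAsFactors = FALSE)
}

#' Detect an A-stretch (internal-priming signature)
#'
#' @param seq nucleotide string in transcription orientation
#' @param min_len minimum run of consecutive adenosines (default 13)
#' @return list with `found` and, when found, 1-based `start`/`end` of the
#'   first qualifying run
#' @export
detect_a_stretch <- function(seq, min_len = 13) {
  ch <- strsplit(toupper(seq), "")[[1]]
  r <- rle(ch == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_len)
  if (length(hit) == 0) return(list(found = FALSE, start = NA_integer_, end = NA_integer_))
  list(found = TRUE, start = starts[hit[1]], end = ends[hit[1]])
}

#' Peak retention logic
#'
#' A peak is retained iff it satisfies rule 1 (known PA in the SID) or rule
#' 2 (PAS hexamer in the upstream-shifted SID) and not rule 3 (A-stretch in
#' the SID).
#'
#' @param rule1,rule2,rule3 logical vectors
#' @return character vector: `"retained"`, `"discarded_internal_priming"`
#'   (rule 3 fired) or `"discarded_no_evidence"`
#' @export
retention_status <- function(rule1, rule2, rule3) {
  ifelse(rule3, "discarded_internal_priming",
         ifelse(rule1 | rule2, "retained", "discarded_no_evidence"))
}

#' Annotate fitted peaks against the PA reference and genome
#'
#' For a peak with mode `m` (SID offsets in transcription direction):
#' rule 1 looks for a known PA within `[m + lower, m + upper]`; rule 2 scans
#' for PAS hexamers starting within the SID shifted `pas_shift` bp upstream,
#' `[m + lower - 20, m + upper - 20]`; rule 3 looks for `a_stretch_len`
#' consecutive adenosines within the SID. Retained peaks are assigned a PA:
#' the known PA nearest to `m + median(SID)` (ties broken downstream) under
#' rule 1, else a de novo PA at `m + median(SID)`.
#'
#' @param peaks an `apa_peaks` data.frame
#' @param sid an `apa_sid` object
#' @param pa_sites known PA sites
#' @param fasta indexed genome FASTA (path or `FaFile`)
#' @param pas_shift upstream shift of the rule-2 window in bp (default 20)
#' @param a_stretch_len rule-3 A-run length (default 13)
#' @return an `apa_annotated_peaks` data.frame: the peak table plus `rule1`,
#'   `rule2`, `rule3`, `pas_motif`, `status`, `pa_pos`, `pa_source`
#' @export
annotate_peaks <- function(peaks, sid, pa_sites, fasta, pas_shift = 20,
                           a_stretch_len = 13) {
  fa <- if (inherits(fasta, "FaFile")) fasta else {
    if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
    Rsamtools::FaFile(fasta)
  }
  n <- nrow(peaks)
  rule1 <- rule2 <- rule3 <- logical(n)
  pas_motif <- rep(NA_character_, n)
  pa_pos <- rep(NA_integer_, n)
  pa_source <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    m <- round(peaks$mu[i])
    strand <- peaks$strand[i]
    chrom <- peaks$chrom[i]
    w1 <- txn_window(m, strand, sid$lower, sid$upper)
    cand <- pa_sites$chrom == chrom & pa_sites$strand == strand &
      pa_sites$pos >= w1[1] & pa_sites$pos <= w1[2]
    rule1[i] <- any(cand)
    w2 <- txn_window(m, strand, sid$lower - pas_shift, sid$upper - pas_shift + 5)
    s2 <- suppressWarnings(fetch_seq(fa, chrom, w2[1], w2[2], strand))
    hits <- scan_pas_motifs(s2)
    hits <- hits[hits$pos <= (sid$upper - sid$lower) + 1, , drop = FALSE]
    rule2[i] <- nrow(hits) > 0
    if (rule2[i]) pas_motif[i] <- hits$motif[1]
    s3 <- suppressWarnings(fetch_seq(fa, chrom, w1[1], w1[2], strand))
    rule3[i] <- detect_a_stretch(s3, a_stretch_len)$found
    if (!rule3[i] && (rule1[i] || rule2[i])) {
      target <- m + if (strand == "+") sid$median else -sid$median
      if (rule1[i]) {
        pos <- pa_sites$pos[cand]
        dd <- abs(pos - target)
        best <- which(dd == min(dd))
        if (length(best) > 1) best <- if (strand == "+") best[which.max(pos[best])] else
          best[which.min(pos[best])]
        pa_pos[i] <- pos[best]
        pa_source[i] <- "known"
      } else {
        pa_pos[i] <- as.integer(round(target))
        pa_source[i] <- "de_novo"
      }
    }
  }
  out <- peaks
  out$rule1 <- rule1
  out$rule2 <- rule2
  out$rule3 <- rule3
  out$pas_motif <- pas_motif
  out$status <- retention_status(rule1, rule2, rule3)
  out$pa_pos <- pa_pos
  out$pa_source <- pa_source
  class(out) <- c("apa_annotated_peaks", "data.frame")
  out
}
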