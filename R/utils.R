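# Shared small helpers. All genomic coordinates inside the package are
# 1-based closed (GenomicRanges convention); BED is converted at read/write.

#' Lower median
#'
#' Median with the even-count tie broken to the lower of the two central
#' values, as used for UMI read-collapse.
#'
#' @param x numeric vector, length >= 1
#' @return the lower median of `x`
#' @export
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

# Genomic interval corresponding to transcription-direction offsets
# [from, to] relative to an anchor position. Returns c(start, end), 1-based.
txn_window <- function(anchor, strand, from, to) {
  stopifnot(from <= to)
  if (strand == "+") c(anchor + from, anchor + to) else c(anchor - to, anchor - from)
}

# Signed transcription-direction offset of pos relative to anchor
# (positive = downstream of anchor).
txn_offset <- function(anchor, strand, pos) {
  if (strand == "+") pos - anchor else anchor - pos
}

# Dirichlet sampler (gamma construction).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), ncol = k, byrow = TRUE)
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
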