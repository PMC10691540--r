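# Peak calling from deduplicated-UMI coverage: per-gene coverage tracks,
# Gaussian-kernel smoothing, local-maximum mode detection, read-count
# filtering and proximity merging, then shape fitting (isolated Gaussian
# least squares / K-component mixture EM for overlapped clusters).

# Extract the per-gene deduplicated UMI table from a BAM: one representative
# alignment per (cell barcode, UMI), with its M-covered blocks and location
# (midpoint of the M-covered genomic span). Multiple reads sharing a UMI are
# collapsed to the read at the lower-median location.
gene_umi_table <- function(bam, model, cb_tag = "CB", ub_tag = "UB", min_mapq = 255) {
  region <- GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(min(model$ext$start), max(model$ext$end))
  )
  param <- Rsamtools::ScanBamParam(
    which = region,
    what = c("pos", "cigar", "strand", "mapq"),
    tag = c(cb_tag, ub_tag),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_rec <- length(res$pos)
  cb <- res$tag[[cb_tag]] %||% rep(NA_character_, n_rec)
  ub <- res$tag[[ub_tag]] %||% rep(NA_character_, n_rec)
  qc <- list(n_records = n_rec, dropped_tag = 0L, dropped_mapq = 0L, dropped_strand = 0L)
  empty <- function() {
    list(umi = data.frame(cell = character(0), umi = character(0), loc = integer(0)),
         blocks = list(), qc = qc)
  }
  if (n_rec == 0) return(empty())
  has_tag <- !is.na(cb) & !is.na(ub)
  qc$dropped_tag <- sum(!has_tag)
  ok_mapq <- !is.na(res$mapq) & res$mapq >= min_mapq
  qc$dropped_mapq <- sum(has_tag & !ok_mapq)
  ok_strand <- as.character(res$strand) == model$strand
  qc$dropped_strand <- sum(has_tag & ok_mapq & !ok_strand)
  keep <- which(has_tag & ok_mapq & ok_strand)
  if (length(keep) == 0) return(empty())

  irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    res$cigar[keep], pos = res$pos[keep], ops = "M"
  )
  rng <- unlist(range(irl))
  loc <- as.integer(floor((IRanges::start(rng) + IRanges::end(rng)) / 2))
  key <- paste(cb[keep], ub[keep], sep = "\r")
  # lower-median representative per (cell, UMI)
  o <- order(key, loc)
  key_o <- key[o]
  grp_end <- c(which(key_o[-1] != key_o[-length(key_o)]), length(key_o))
  grp_start <- c(1L, grp_end[-length(grp_end)] + 1L)
  rep_idx_o <- grp_start + ceiling((grp_end - grp_start + 1L) / 2) - 1L
  rep_idx <- o[rep_idx_o]
  umi <- data.frame(
    cell = cb[keep][rep_idx], umi = ub[keep][rep_idx], loc = loc[rep_idx],
    stringsAsFactors = FALSE
  )
  blocks <- lapply(rep_idx, function(i) {
    b <- irl[[i]]
    cbind(start = IRanges::start(b), end = IRanges::end(b))
  })
  ord <- order(umi$loc, umi$cell, umi$umi)
  list(umi = umi[ord, , drop = FALSE], blocks = blocks[ord], qc = qc)
}

#' Build a per-gene deduplicated-UMI coverage track
#'
#' Reads overlapping the gene's extended 3'-UTR regions (matching the gene
#' strand, passing the mapping-quality filter, carrying both barcode tags)
#' are collapsed to one representative per (cell, UMI) at the lower-median
#' location; only the representative's M-covered (CIGAR `M`) bases increment
#' the coverage.
#'
#' @param bam path to a coordinate-sorted, indexed BAM
#' @param model a single gene model from [load_gene_models()] /
#'   [extend_utrs()]
#' @param cb_tag,ub_tag cell-barcode and UMI tag names (10x defaults)
#' @param min_mapq minimum mapping quality (255 = 10x unique mappers)
#' @return an `apa_coverage` object: per-base counts over the extended
#'   region, the deduplicated UMI table (cell, UMI, location, M-blocks) and
#'   QC tallies for dropped records
#' @export
build_coverage <- function(bam, model, cb_tag = "CB", ub_tag = "UB", min_mapq = 255) {
  tab <- gene_umi_table(bam, model, cb_tag, ub_tag, min_mapq)
  rstart <- min(model$ext$start)
  rend <- max(model$ext$end)
  n <- rend - rstart + 1L
  counts <- integer(n)
  for (b in tab$blocks) {
    s <- pmax(b[, "start"], rstart) - rstart + 1L
    e <- pmin(b[, "end"], rend) - rstart + 1L
    for (j in seq_along(s)) {
      if (s[j] <= e[j]) counts[s[j]:e[j]] <- counts[s[j]:e[j]] + 1L
    }
  }
  structure(
    list(gene_id = model$gene_id, chrom = model$chrom, strand = model$strand,
         start = rstart, end = rend, counts = counts,
         umi = tab$umi, blocks = tab$blocks,
         n_umis = nrow(tab$umi), qc = tab$qc),
    class = "apa_coverage"
  )
}

#' Smooth a coverage track with a Gaussian kernel
#'
#' Discrete Gaussian convolution with a kernel truncated at 4 bandwidths;
#' total mass is conserved up to truncation at the region boundaries.
#'
#' @param track an `apa_coverage` object or a numeric vector of counts
#' @param bandwidth kernel standard deviation in bp (default 25)
#' @return a numeric vector, same length as the input counts
#' @export
smooth_coverage <- function(track, bandwidth = 25) {
  stopifnot(bandwidth > 0)
  x <- if (inherits(track, "apa_coverage")) track$counts else track
  n <- length(x)
  if (n == 0) return(numeric(0))
  # full-support kernel (FFT convolution): a truncated kernel would plant
  # tiny artifact maxima where two pileups' truncation edges meet
  h <- n - 1L
  k <- stats::dnorm(-h:h, sd = bandwidth)
  k <- k / sum(k)
  if (n == 1) return(x)
  s <- stats::convolve(c(numeric(h), x, numeric(h)), rev(k), type = "filter")
  as.numeric(s)
}

#' Detect peak modes as local maxima of a smoothed curve
#'
#' Strict local maxima in curve-index order; a flat plateau of equal maxima
#' reports its centre position (floor). Monotone stretches and boundary
#' values produce no modes; modes require positive height.
#'
#' @param curve numeric vector from [smooth_coverage()]
#' @return a data.frame with `idx` (1-based index into the curve) and
#'   `height`
#' @export
detect_modes <- function(curve) {
  n <- length(curve)
  out <- data.frame(idx = integer(0), height = numeric(0))
  if (n < 3) return(out)
  r <- rle(curve)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3) return(out)
  for (i in 2:(nr - 1)) {
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1] && r$values[i] > 0) {
      idx <- as.integer(floor((starts[i] + ends[i]) / 2))
      out <- rbind(out, data.frame(idx = idx, height = r$values[i]))
    }
  }
  out
}

# Partition deduplicated UMIs among modes by nearest genomic distance;
# equidistant UMIs go to the transcription-downstream mode.
mode_raw_reads <- function(mode_pos, locs, strand) {
  if (length(mode_pos) == 0) return(integer(0))
  if (length(locs) == 0) return(integer(length(mode_pos)))
  d <- abs(outer(locs, mode_pos, "-"))
  nearest <- apply(d, 1, function(row) {
    cand <- which(row == min(row))
    if (length(cand) > 1) {
      cand <- if (strand == "+") max(cand) else min(cand)
    }
    cand
  })
  as.integer(tabulate(nearest, nbins = length(mode_pos)))
}

#' Find raw peak modes on a gene's coverage track
#'
#' Smooths the track, detects local maxima, and attributes to each mode the
#' deduplicated UMIs whose representative location is nearest to it.
#'
#' @param track an `apa_coverage` object
#' @param bandwidth smoothing bandwidth in bp
#' @return data.frame with `pos` (genomic), `height` (smoothed coverage) and
#'   `raw_reads` (nearest-mode UMI count)
#' @export
find_peak_modes <- function(track, bandwidth = 25) {
  curve <- smooth_coverage(track, bandwidth)
  m <- detect_modes(curve)
  pos <- track$start + m$idx - 1L
  data.frame(pos = pos, height = m$height,
             raw_reads = mode_raw_reads(pos, track$umi$loc, track$strand))
}

in_regions <- function(pos, regions) {
  vapply(pos, function(p) any(p >= regions$start & p <= regions$end), logical(1))
}

#' Filter and merge peak modes
#'
#' Modes with fewer than `min_reads` deduplicated UMIs, or with at most
#' `min_frac` of the reads of the largest mode inside the extended 3' UTR,
#' are dropped. Surviving modes within `merge_dist` bp are merged
#' left-to-right into a single mode at the floor of the mean of the two
#' positions, with reads summed. Modes outside the extended UTR regions are
#' flagged (`in_utr = FALSE`) but retained here so that overlapped clusters
#' can be fitted with them; they are discarded after fitting.
#'
#' @param modes data.frame from [find_peak_modes()]
#' @param model the gene model (for the extended UTR regions)
#' @param min_reads minimum deduplicated UMIs per mode (default 10)
#' @param min_frac minimum fraction of the largest in-UTR mode's reads
#'   (default 0.05; the comparison is `<=`, i.e. exactly 5% is dropped)
#' @param merge_dist merge radius in bp (default 50)
#' @return filtered data.frame with an added `in_utr` flag
#' @export
filter_modes <- function(modes, model, min_reads = 10, min_frac = 0.05, merge_dist = 50) {
  if (nrow(modes) == 0) {
    modes$in_utr <- logical(0)
    return(modes)
  }
  pass <- function(modes) {
    modes <- modes[order(modes$pos), , drop = FALSE]
    modes$in_utr <- in_regions(modes$pos, model$ext)
    if (!any(modes$in_utr)) return(modes[0, , drop = FALSE])
    largest <- max(modes$raw_reads[modes$in_utr])
    keep <- modes$raw_reads >= min_reads & modes$raw_reads > min_frac * largest
    modes <- modes[keep, , drop = FALSE]
    if (nrow(modes) <= 1) {
      rownames(modes) <- NULL
      return(modes)
    }
    # sequential left-to-right pairwise merging
    acc <- modes[1, , drop = FALSE]
    for (i in 2:nrow(modes)) {
      last <- nrow(acc)
      if (modes$pos[i] - acc$pos[last] <= merge_dist) {
        acc$pos[last] <- as.integer(floor((acc$pos[last] + modes$pos[i]) / 2))
        acc$raw_reads[last] <- acc$raw_reads[last] + modes$raw_reads[i]
        acc$height[last] <- max(acc$height[last], modes$height[i])
        acc$in_utr[last] <- in_regions(acc$pos[last], model$ext)
      } else {
        acc <- rbind(acc, modes[i, ])
      }
    }
    rownames(acc) <- NULL
    acc
  }
  # iterate to a fixpoint: merging sums reads, which can raise the largest
  # mode and re-trigger the relative-fraction filter
  modes$in_utr <- if (is.null(modes$in_utr)) NA else modes$in_utr
  out <- pass(modes)
  repeat {
    nxt <- pass(out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out
}

#' Group peak modes into isolated/overlapped clusters
#'
#' Transitive closure of the "within `radius` bp" relation: modes chained by
#' gaps of at most `radius` form one overlapped cluster; singletons are
#' isolated.
#'
#' @param modes data.frame of modes sorted by position
#' @param radius clustering radius in bp (default 300)
#' @return `modes` with added `cluster` (integer id) and `kind`
#'   (`"isolated"`/`"overlapped"`) columns
#' @export
cluster_modes <- function(modes, radius = 300) {
  n <- nrow(modes)
  if (n == 0) {
    modes$cluster <- integer(0)
    modes$kind <- character(0)
    return(modes)
  }
  modes <- modes[order(modes$pos), , drop = FALSE]
  cl <- integer(n)
  cl[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      cl[i] <- if (modes$pos[i] - modes$pos[i - 1] <= radius) cl[i - 1] else cl[i - 1] + 1L
    }
  }
  modes$cluster <- cl
  sizes <- tabulate(cl)
  modes$kind <- ifelse(sizes[cl] > 1, "overlapped", "isolated")
  rownames(modes) <- NULL
  modes
}

#' Fit a single Gaussian peak by nonlinear least squares
#'
#' Fits `y ~ A * exp(-(x - mu)^2 / (2 * sigma^2))` with Levenberg-Marquardt
#' least squares, initialised at the mode position and the empirical local
#' spread; `sigma` is box-constrained. On non-convergence the initial values
#' are returned with `converged = FALSE`.
#'
#' @param x positions, `y` counts over the local window
#' @param y counts
#' @param mode initial mode position
#' @param sigma_bounds lower/upper clamp for sigma in bp (default c(5, 350))
#' @return list with `mu`, `sigma`, `amplitude`, `converged`
#' @export
fit_gaussian_peak <- function(x, y, mode, sigma_bounds = c(5, 350)) {
  tot <- sum(y)
  emp_sd <- if (tot > 0) sqrt(sum(y * (x - mode)^2) / tot) else sigma_bounds[1]
  emp_sd <- min(max(emp_sd, sigma_bounds[1]), sigma_bounds[2])
  fallback <- list(mu = mode, sigma = emp_sd, amplitude = max(y, 1), converged = FALSE)
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sig^2)),
      start = list(A = max(y), mu = mode, sig = emp_sd),
      lower = c(1e-8, min(x), sigma_bounds[1]),
      upper = c(Inf, max(x), sigma_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    )
    co <- stats::coef(f)
    list(mu = unname(co["mu"]), sigma = unname(co["sig"]),
         amplitude = unname(co["A"]), converged = TRUE)
  }, error = function(e) fallback)
  fit
}

#' Fit a K-component Gaussian mixture to positions by EM
#'
#' Weighted EM on position observations (per-base counts act as integer
#' weights). Means are initialised at the supplied raw modes, spreads at
#' `sigma_init`, mixing weights equal. Convergence is declared when the
#' relative change in log-likelihood drops below `tol`. A component that
#' collapses (sigma at the lower clamp with negligible weight) is removed
#' and the mixture refitted with K-1 components, flagged.
#'
#' @param x numeric positions
#' @param K number of components
#' @param mu_init initial means (length K)
#' @param w optional non-negative observation weights (default 1)
#' @param sigma_init initial component sd in bp (default 50)
#' @param sigma_bounds sigma clamps (default c(5, 350))
#' @param tol relative log-likelihood tolerance (default 1e-4)
#' @param max_iter maximum EM iterations (default 200)
#' @param weight_floor component weight below which a collapsed component is
#'   dropped (default 1e-3)
#' @return list with `mu`, `sigma`, `lambda` (mixing weights summing to 1),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `dropped`
#' @export
fit_gmm_em <- function(x, K, mu_init, w = NULL, sigma_init = 50,
                       sigma_bounds = c(5, 350), tol = 1e-4, max_iter = 200,
                       weight_floor = 1e-3) {
  stopifnot(length(mu_init) == K, length(x) > 0)
  if (is.null(w)) w <- rep(1, length(x))
  W <- sum(w)
  mu <- as.numeric(mu_init)
  sigma <- rep(sigma_init, K)
  sigma <- pmin(pmax(sigma, sigma_bounds[1]), sigma_bounds[2])
  lambda <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  dropped <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    ld <- vapply(seq_len(K), function(k) {
      log(lambda[k]) + stats::dnorm(x, mu[k], sigma[k], log = TRUE)
    }, numeric(length(x)))
    ld <- matrix(ld, ncol = K)
    m <- apply(ld, 1, max)
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(w * lse)
    trace <- c(trace, ll)
    r <- exp(ld - lse)
    nk <- colSums(w * r)
    lambda <- nk / W
    for (k in seq_len(K)) {
      if (nk[k] > 0) {
        mu[k] <- sum(w * r[, k] * x) / nk[k]
        sigma[k] <- sqrt(sum(w * r[, k] * (x - mu[k])^2) / nk[k])
      }
      sigma[k] <- min(max(sigma[k], sigma_bounds[1]), sigma_bounds[2])
    }
    collapse <- which(sigma <= sigma_bounds[1] + 1e-9 & lambda < weight_floor)
    if (length(collapse) > 0 && K > 1) {
      sub <- fit_gmm_em(x, K - length(collapse), mu[-collapse], w = w,
                        sigma_init = sigma_init, sigma_bounds = sigma_bounds,
                        tol = tol, max_iter = max_iter, weight_floor = weight_floor)
      sub$dropped <- TRUE
      return(sub)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  o <- order(mu)
  list(mu = mu[o], sigma = sigma[o], lambda = lambda[o],
       loglik = trace[length(trace)], loglik_trace = trace,
       n_iter = iter, converged = converged, dropped = dropped, K = K)
}

#' Fit all peak shapes on one gene's track
#'
#' Isolated modes are fitted by Gaussian least squares on a local window;
#' overlapped clusters by a K-component mixture EM on the per-base counts of
#' the cluster region. Fitted peaks whose modes fall outside the extended
#' 3'-UTR regions are discarded after fitting.
#'
#' @param track an `apa_coverage` object
#' @param modes clustered modes from [cluster_modes()]
#' @param window half-window for isolated fits and cluster-region padding
#'   (default 300 bp)
#' @param sigma_init EM initial sd (default 50)
#' @param sigma_bounds sigma clamps (default c(5, 350))
#' @param em_tol,em_max_iter EM controls
#' @param model gene model providing the UTR regions (for the post-fit drop)
#' @return data.frame of fitted peaks (one row per retained peak): `gene_id`,
#'   `peak_id`, `chrom`, `strand`, `mu`, `sigma`, `weight`, `amplitude`,
#'   `kind`, `cluster`, `raw_reads`, `converged`
#' @export
fit_peaks <- function(track, modes, model, window = 300, sigma_init = 50,
                      sigma_bounds = c(5, 350), em_tol = 1e-4, em_max_iter = 200) {
  if (nrow(modes) == 0) {
    return(data.frame(gene_id = character(0), peak_id = character(0),
                      chrom = character(0), strand = character(0),
                      mu = numeric(0), sigma = numeric(0), weight = numeric(0),
                      amplitude = numeric(0), kind = character(0),
                      cluster = integer(0), raw_reads = integer(0),
                      converged = logical(0)))
  }
  xs <- track$start:track$end
  rows <- list()
  for (cl in unique(modes$cluster)) {
    cm <- modes[modes$cluster == cl, , drop = FALSE]
    lo <- max(track$start, min(cm$pos) - window)
    hi <- min(track$end, max(cm$pos) + window)
    sel <- xs >= lo & xs <= hi
    x <- xs[sel]; y <- track$counts[sel]
    if (nrow(cm) == 1) {
      f <- fit_gaussian_peak(x, y, cm$pos, sigma_bounds)
      rows[[length(rows) + 1]] <- data.frame(
        mu = f$mu, sigma = f$sigma, weight = 1, amplitude = f$amplitude,
        kind = "isolated", cluster = cl, raw_reads = cm$raw_reads,
        converged = f$converged
      )
    } else {
      pos <- x[y > 0]; wt <- y[y > 0]
      f <- fit_gmm_em(pos, K = nrow(cm), mu_init = cm$pos, w = wt,
                      sigma_init = sigma_init, sigma_bounds = sigma_bounds,
                      tol = em_tol, max_iter = em_max_iter)
      kk <- length(f$mu)
      rr <- if (kk == nrow(cm)) cm$raw_reads else {
        mode_raw_reads(round(f$mu), track$umi$loc[track$umi$loc >= lo & track$umi$loc <= hi],
                       track$strand)
      }
      rows[[length(rows) + 1]] <- data.frame(
        mu = f$mu, sigma = f$sigma, weight = f$lambda,
        amplitude = f$lambda * sum(wt), kind = "overlapped", cluster = cl,
        raw_reads = rr, converged = f$converged & !f$dropped
      )
    }
  }
  pk <- do.call(rbind, rows)
  pk <- pk[in_regions(round(pk$mu), model$ext), , drop = FALSE]
  if (nrow(pk) == 0) return(pk)
  # transcription order, proximal -> distal
  pk <- pk[order(if (model$strand == "+") pk$mu else -pk$mu), , drop = FALSE]
  pk <- data.frame(gene_id = model$gene_id,
                   peak_id = sprintf("%s:P%d", model$gene_id, seq_len(nrow(pk))),
                   chrom = model$chrom, strand = model$strand, pk,
                   stringsAsFactors = FALSE)
  rownames(pk) <- NULL
  pk
}

#' Call PA peaks for all genes in a BAM
#'
#' Runs the full per-gene chain: coverage, smoothing, mode detection,
#' filtering/merging, clustering and shape fitting.
#'
#' @param bam path to a coordinate-sorted, indexed BAM
#' @param models `apa_gene_models` (extended; see [extend_utrs()])
#' @param bandwidth smoothing bandwidth (default 25 bp)
#' @param min_reads,min_frac,merge_dist mode filters (see [filter_modes()])
#' @param radius cluster radius (default 300 bp)
#' @param cb_tag,ub_tag,min_mapq BAM read filters
#' @param keep_coverage if TRUE, attach the per-gene coverage tracks as
#'   attribute `"tracks"` (used for reporting)
#' @param ... passed to [fit_peaks()]
#' @return an `apa_peaks` data.frame of fitted, UTR-retained peaks
#' @export
call_peaks <- function(bam, models, bandwidth = 25, min_reads = 10, min_frac = 0.05,
                       merge_dist = 50, radius = 300, cb_tag = "CB", ub_tag = "UB",
                       min_mapq = 255, keep_coverage = FALSE, ...) {
  out <- list()
  tracks <- list()
  for (g in names(models)) {
    model <- models[[g]]
    track <- build_coverage(bam, model, cb_tag, ub_tag, min_mapq)
    if (keep_coverage) tracks[[g]] <- track
    if (track$n_umis == 0) next
    modes <- find_peak_modes(track, bandwidth)
    modes <- filter_modes(modes, model, min_reads, min_frac, merge_dist)
    if (nrow(modes) == 0) next
    modes <- cluster_modes(modes, radius)
    out[[g]] <- fit_peaks(track, modes, model, ...)
  }
  pk <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(gene_id = character(0), peak_id = character(0),
               chrom = character(0), strand = character(0),
               mu = numeric(0), sigma = numeric(0), weight = numeric(0),
               amplitude = numeric(0), kind = character(0),
               cluster = integer(0), raw_reads = integer(0),
               converged = logical(0))
  rownames(pk) <- NULL
  class(pk) <- c("apa_peaks", "data.frame")
  if (keep_coverage) attr(pk, "tracks") <- tracks
  pk
}
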