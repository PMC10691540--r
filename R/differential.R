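# Differential PA testing. Per gene: a Pearson chi-square test on the
# pooled cell-type-by-peak table and a Dirichlet-multinomial likelihood
# ratio test that models between-cell variability in peak usage; the two
# are combined by taking the maximum p-value. Effect sizes are WARM
# (count-weighted mean relative mode position) and MPRO (extreme
# downstream-minus-upstream difference in proportion change).

#' Pooled chi-square test of PA usage homogeneity
#'
#' Pearson chi-square on the K x J table of per-group summed peak counts.
#' Zero-total rows and columns are dropped (degrees of freedom adjust
#' accordingly); a table degenerate after dropping returns p = 1, flagged.
#'
#' @param X integer matrix, cells x peaks
#' @param groups factor/character of group labels, one per row of `X`
#' @return list with `stat`, `df`, `p`, `flagged`
#' @export
pa_chisq_test <- function(X, groups) {
  tab <- rowsum(X, group = as.character(groups))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(stat = 0, df = 0L, p = 1, flagged = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(stat = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), flagged = FALSE)
}

# Dirichlet-multinomial log-likelihood (multinomial coefficient omitted; it
# cancels in likelihood ratios).
dm_loglik <- function(X, alpha) {
  n <- rowSums(X)
  a0 <- sum(alpha)
  sum(lgamma(a0) - lgamma(n + a0)) +
    sum(lgamma(sweep(X, 2, alpha, "+")) ) - nrow(X) * sum(lgamma(alpha))
}

#' Maximum-likelihood Dirichlet-multinomial fit
#'
#' Fixed-point iteration on the DM log-likelihood (digamma ratio update),
#' initialised from moment estimates of the mean proportions and precision.
#' Cells with zero total count are excluded. Alpha components are floored
#' and capped; a fit driven to the cap (e.g. all counts on one peak, or no
#' overdispersion at all) is flagged as a boundary fit.
#'
#' @param X integer matrix, cells x peaks
#' @param tol relative alpha-change convergence tolerance (default 1e-6)
#' @param max_iter maximum iterations (default 500)
#' @param alpha_floor,alpha_cap box constraints on alpha (1e-8, 1e6)
#' @return list with `alpha`, `loglik`, `n_iter`, `converged`, `boundary`,
#'   `n_cells`
#' @export
dm_fit <- function(X, tol = 1e-6, max_iter = 500, alpha_floor = 1e-8,
                   alpha_cap = 1e6) {
  X <- as.matrix(X)
  n <- rowSums(X)
  X <- X[n > 0, , drop = FALSE]
  n <- n[n > 0]
  J <- ncol(X)
  N <- nrow(X)
  if (J < 2 || N == 0) {
    return(list(alpha = rep(1, max(J, 1)), loglik = 0, n_iter = 0L,
                converged = TRUE, boundary = FALSE, n_cells = N))
  }
  p <- X / n
  m <- colMeans(p)
  m <- pmax(m, 1e-8); m <- m / sum(m)
  v <- apply(p, 2, stats::var)
  if (N < 2 || max(v, na.rm = TRUE) < 1e-12) {
    # no between-cell variability: the MLE diverges (zero overdispersion);
    # return the capped boundary fit
    alpha <- pmin(pmax(m * alpha_cap, alpha_floor), alpha_cap)
    return(list(alpha = alpha, loglik = dm_loglik(X, alpha), n_iter = 0L,
                converged = TRUE, boundary = TRUE, n_cells = N))
  }
  s_j <- m * (1 - m) / pmax(v, 1e-12) - 1
  s_j <- s_j[is.finite(s_j) & v > 1e-12]
  s <- if (length(s_j) > 0) stats::median(s_j) else 1e4
  s <- min(max(s, 0.5), 1e4)
  alpha <- pmax(m * s, alpha_floor)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    a0 <- sum(alpha)
    num <- colSums(digamma(sweep(X, 2, alpha, "+"))) - N * digamma(alpha)
    den <- sum(digamma(n + a0)) - N * digamma(a0)
    new_alpha <- alpha * num / den
    new_alpha[!is.finite(new_alpha) | new_alpha < alpha_floor] <- alpha_floor
    new_alpha <- pmin(new_alpha, alpha_cap)
    rel <- max(abs(new_alpha - alpha) / pmax(alpha, alpha_floor))
    alpha <- new_alpha
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(alpha = alpha, loglik = dm_loglik(X, alpha), n_iter = iter,
       converged = converged,
       boundary = any(alpha >= alpha_cap * 0.999) || !converged,
       n_cells = N)
}

#' Dirichlet-multinomial likelihood ratio test
#'
#' Tests equality of the per-group Dirichlet parameters
#' (alpha_1 = ... = alpha_K) against group-specific fits. The statistic
#' 2 * (sum of group log-likelihoods - pooled log-likelihood) is referred to
#' a chi-square with (K - 1) * J degrees of freedom.
#'
#' @param X integer matrix, cells x peaks
#' @param groups group label per row
#' @param ... passed to [dm_fit()]
#' @return list with `stat`, `df`, `p`, `flagged` (boundary or degenerate
#'   fits)
#' @export
dm_lrt <- function(X, groups, ...) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  n <- rowSums(X)
  keep <- n > 0
  X <- X[keep, , drop = FALSE]
  groups <- groups[keep]
  J <- ncol(X)
  lv <- unique(groups)
  lv <- lv[vapply(lv, function(g) sum(groups == g) > 0, logical(1))]
  K <- length(lv)
  if (K < 2 || nrow(X) == 0) {
    return(list(stat = 0, df = 0L, p = 1, flagged = TRUE))
  }
  pooled <- dm_fit(X, ...)
  fits <- lapply(lv, function(g) dm_fit(X[groups == g, , drop = FALSE], ...))
  stat <- max(0, 2 * (sum(vapply(fits, `[[`, numeric(1), "loglik")) - pooled$loglik))
  df <- (K - 1L) * J
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  flagged <- pooled$boundary || any(vapply(fits, `[[`, logical(1), "boundary"))
  list(stat = stat, df = df, p = p, flagged = flagged)
}

#' Combine test p-values and adjust across genes
#'
#' The per-gene combined p-value is the maximum of the chi-square and DM
#' p-values; Benjamini-Hochberg correction is applied across all tested
#' genes of the comparison.
#'
#' @param p_chisq,p_dm numeric vectors of per-gene p-values
#' @return list with `p_combined` and `p_adj`
#' @export
combine_and_adjust <- function(p_chisq, p_dm) {
  p <- pmax(p_chisq, p_dm)
  list(p_combined = p, p_adj = stats::p.adjust(p, method = "BH"))
}

#' Weighted average relative mode position (WARM)
#'
#' Peak relative positions run from 0 (most proximal) to 1 (most distal) in
#' transcription direction. Peaks of a single shared 3' UTR are placed by
#' linear interpolation of their genomic mode positions; peaks from
#' different 3' UTRs are evenly spaced by rank, `(rank - 1) / (n - 1)`.
#' WARM is the count-weighted mean relative position.
#'
#' @param positions peak mode positions in transcription-direction order
#'   (strictly increasing transcription coordinates, proximal first)
#' @param counts per-peak read totals
#' @param same_utr TRUE when all peaks share one 3' UTR (linear
#'   interpolation); FALSE for rank-based spacing
#' @return WARM in `[0, 1]`, or `NA` when total counts are zero
#' @export
compute_warm <- function(positions, counts, same_utr = TRUE) {
  stopifnot(length(positions) == length(counts), length(positions) >= 2)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing in transcription order")
  }
  tot <- sum(counts)
  if (tot <= 0) return(NA_real_)
  n <- length(positions)
  rel <- if (same_utr) {
    (positions - positions[1]) / (positions[n] - positions[1])
  } else {
    (seq_len(n) - 1) / (n - 1)
  }
  sum(counts * rel) / tot
}

#' Maximum difference in proportion change (MPRO)
#'
#' For each peak, `delta = proportion in base - proportion in alt`. For each
#' ordered pair (j upstream, i downstream) the difference in proportion
#' change is `delta_i - delta_j`; MPRO is the one with the largest absolute
#' value, signed. Positive MPRO means the base group uses more distal peaks.
#'
#' @param base_counts,alt_counts per-peak totals in transcription order
#'   (proximal first)
#' @return MPRO value with attribute `pair = c(upstream, downstream)` peak
#'   indices; `NA` when either condition has zero total
#' @export
compute_mpro <- function(base_counts, alt_counts) {
  J <- length(base_counts)
  stopifnot(J >= 2, length(alt_counts) == J)
  if (sum(base_counts) <= 0 || sum(alt_counts) <= 0) return(NA_real_)
  delta <- base_counts / sum(base_counts) - alt_counts / sum(alt_counts)
  best <- 0
  pair <- c(NA_integer_, NA_integer_)
  for (j in 1:(J - 1)) {
    for (i in (j + 1):J) {
      dd <- delta[i] - delta[j]
      if (abs(dd) > abs(best)) {
        best <- dd
        pair <- c(j, i)
      }
    }
  }
  structure(best, pair = pair)
}

# Transcription-direction offsets of a gene's peaks (proximal first) and
# the cells x peaks count matrix in that order.
gene_peak_layout <- function(counts, gene) {
  pk <- counts$peaks[counts$peaks$gene_id == gene, , drop = FALSE]
  strand <- pk$strand[1]
  o <- order(if (strand == "+") pk$mu else -pk$mu)
  pk <- pk[o, , drop = FALSE]
  pos_txn <- abs(pk$mu - pk$mu[1])
  X <- t(as.matrix(counts$matrix[pk$peak_id, , drop = FALSE]))
  list(peaks = pk, pos = pos_txn, X = X)
}

#' Test differential PA usage across cell groups
#'
#' Runs the combined chi-square + Dirichlet-multinomial test on every
#' multipeak gene (>= 2 retained peaks), computes per-group WARM and MPRO,
#' applies BH correction across genes and the three final-signal rules:
#' adjusted p <= `alpha`, at least one peak expressed (count > 0) in more
#' than `min_frac` of each group's cells, and |MPRO| > `mpro_min`.
#'
#' @param counts an `apa_counts` object
#' @param groups named vector (names = barcodes) or data.frame
#'   (`cell`, `group`) of group labels
#' @param base_group group treated as "base" for MPRO sign (default: first
#'   level); with more than two groups MPRO is the extreme value over all
#'   ordered group pairs
#' @param same_utr logical, peaks share one 3' UTR (default TRUE)
#' @param alpha BH-adjusted significance threshold (default 0.05,
#'   inclusive)
#' @param min_frac expressed-cell fraction threshold (default 0.05, strict)
#' @param mpro_min |MPRO| threshold (default 0.2, strict)
#' @return an `apa_test` data.frame, one row per multipeak gene
#' @export
test_pa <- function(counts, groups, base_group = NULL, same_utr = TRUE,
                    alpha = 0.05, min_frac = 0.05, mpro_min = 0.2) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]), groups[[1]])
  }
  groups <- groups[counts$barcodes]
  lv <- unique(as.character(groups[!is.na(groups)]))
  if (!is.null(base_group)) lv <- c(base_group, setdiff(lv, base_group))
  K <- length(lv)
  stopifnot(K >= 2)
  tab <- table(counts$peaks$gene_id)
  genes <- names(tab)[tab >= 2]
  rows <- list()
  for (g in genes) {
    lay <- gene_peak_layout(counts, g)
    J <- ncol(lay$X)
    use <- !is.na(groups)
    X <- lay$X[use, , drop = FALSE]
    grp <- as.character(groups[use])
    ct <- pa_chisq_test(X, grp)
    dm <- dm_lrt(X, grp)
    warm_g <- vapply(lv, function(k) {
      compute_warm(lay$pos, colSums(X[grp == k, , drop = FALSE]), same_utr)
    }, numeric(1))
    # expressed fraction: per group, max over peaks of fraction of cells
    # with a nonzero count
    expr_frac <- vapply(lv, function(k) {
      Xi <- X[grp == k, , drop = FALSE]
      if (nrow(Xi) == 0) return(0)
      max(colMeans(Xi > 0))
    }, numeric(1))
    if (K == 2) {
      mp <- compute_mpro(colSums(X[grp == lv[1], , drop = FALSE]),
                         colSums(X[grp == lv[2], , drop = FALSE]))
    } else {
      mp <- 0
      for (a in seq_len(K - 1)) for (b in (a + 1):K) {
        m_ab <- compute_mpro(colSums(X[grp == lv[a], , drop = FALSE]),
                             colSums(X[grp == lv[b], , drop = FALSE]))
        if (!is.na(m_ab) && abs(m_ab) > abs(mp)) mp <- as.numeric(m_ab)
      }
    }
    row <- data.frame(gene_id = g, n_peaks = J,
                      p_chisq = ct$p, p_dm = dm$p,
                      mpro = as.numeric(mp),
                      flagged = ct$flagged || dm$flagged,
                      stringsAsFactors = FALSE)
    for (k in seq_along(lv)) {
      row[[paste0("warm_", lv[k])]] <- warm_g[k]
      row[[paste0("expr_frac_", lv[k])]] <- expr_frac[k]
    }
    rows[[g]] <- row
  }
  if (length(rows) == 0) {
    res <- data.frame(gene_id = character(0))
    class(res) <- c("apa_test", "data.frame")
    return(res)
  }
  res <- do.call(rbind, rows)
  comb <- combine_and_adjust(res$p_chisq, res$p_dm)
  res$p_combined <- comb$p_combined
  res$p_adj <- comb$p_adj
  expr_ok <- Reduce(`&`, lapply(lv, function(k) res[[paste0("expr_frac_", k)]] > min_frac))
  res$significant <- res$p_adj <= alpha & expr_ok & !is.na(res$mpro) &
    abs(res$mpro) > mpro_min
  rownames(res) <- NULL
  attr(res, "groups") <- lv
  class(res) <- c("apa_test", "data.frame")
  res
}

#' @export
print.apa_test <- function(x, ...) {
  cat(sprintf("apa_test: %d multipeak genes, %d significant\n",
              nrow(x), sum(x$significant %||% logical(0))))
  NextMethod()
}

#' Apply the final differential-signal rules to precomputed statistics
#'
#' @param p_adj BH-adjusted combined p-values
#' @param expr_ok logical: each group has at least one peak expressed in
#'   more than the required fraction of its cells
#' @param mpro per-gene MPRO values
#' @param alpha adjusted-p threshold (inclusive, default 0.05)
#' @param mpro_min |MPRO| threshold (strict, default 0.2)
#' @return logical significance calls
#' @export
call_signals <- function(p_adj, expr_ok, mpro, alpha = 0.05, mpro_min = 0.2) {
  p_adj <= alpha & expr_ok & !is.na(mpro) & abs(mpro) > mpro_min
}

#' Per-cell average WARM over multipeak genes
#'
#' For every cell, WARM is computed for each expressed multipeak gene and
#' averaged with equal weights or with the cell's per-gene counts as
#' weights. Cells expressing no multipeak gene get `NA`.
#'
#' @param counts an `apa_counts` object
#' @param weighting `"equal"` or `"expression"`
#' @param same_utr passed to [compute_warm()]
#' @return named numeric vector of per-cell WARM values
#' @export
compute_cell_warm <- function(counts, weighting = c("equal", "expression"),
                              same_utr = TRUE) {
  weighting <- match.arg(weighting)
  tab <- table(counts$peaks$gene_id)
  genes <- names(tab)[tab >= 2]
  nc <- length(counts$barcodes)
  num <- matrix(0, nrow = length(genes), ncol = nc)
  den <- matrix(0, nrow = length(genes), ncol = nc)
  for (gi in seq_along(genes)) {
    lay <- gene_peak_layout(counts, genes[gi])
    n <- length(lay$pos)
    rel <- if (same_utr) (lay$pos - lay$pos[1]) / (lay$pos[n] - lay$pos[1]) else
      (seq_len(n) - 1) / (n - 1)
    Xg <- t(lay$X)                       # peaks x cells
    num[gi, ] <- as.numeric(rel %*% Xg)
    den[gi, ] <- Matrix::colSums(Xg)
  }
  warm_gc <- num / den                   # NaN where den == 0
  out <- vapply(seq_len(nc), function(j) {
    ok <- den[, j] > 0
    if (!any(ok)) return(NA_real_)
    if (weighting == "equal") mean(warm_gc[ok, j]) else
      sum(warm_gc[ok, j] * den[ok, j]) / sum(den[ok, j])
  }, numeric(1))
  stats::setNames(out, counts$barcodes)
}

#' Hierarchical differential PA tests over a cell-type taxonomy
#'
#' Cells carry a root-to-leaf label path (columns of `taxonomy` beyond the
#' first are the levels, shallow to deep). For every node whose complement
#' within its parent is non-empty, the node's cells are tested against all
#' other cells of the parent; the walk repeats up to the root. Nodes with an
#' empty complement are skipped with a note.
#'
#' @param counts an `apa_counts` object
#' @param taxonomy data.frame: first column cell barcode, remaining columns
#'   level-1..level-L labels (NA for cells not annotated at a level)
#' @param ... passed to [test_pa()]
#' @return list with `results` (row-bound `apa_test` tables tagged with
#'   `node` and `level`), `comparisons` (one row per node tested) and
#'   `skipped`
#' @export
hierarchical_test_pa <- function(counts, taxonomy, ...) {
  cells <- taxonomy[[1]]
  levels <- names(taxonomy)[-1]
  results <- list()
  comparisons <- list()
  skipped <- character(0)
  for (li in seq_along(levels)) {
    lab <- as.character(taxonomy[[li + 1]])
    parent_lab <- if (li == 1) rep("root", length(cells)) else
      apply(taxonomy[2:li], 1, paste, collapse = "/")
    for (node in unique(lab[!is.na(lab)])) {
      for (par in unique(parent_lab[lab == node & !is.na(lab)])) {
        node_cells <- cells[!is.na(lab) & lab == node & parent_lab == par]
        parent_cells <- cells[parent_lab == par & !is.na(lab)]
        comp_cells <- setdiff(parent_cells, node_cells)
        tag <- paste(par, node, sep = "/")
        if (length(comp_cells) == 0) {
          skipped <- c(skipped, tag)
          next
        }
        grp <- stats::setNames(
          ifelse(cells %in% node_cells, node,
                 ifelse(cells %in% comp_cells, paste0("non_", node), NA)),
          cells
        )
        res <- test_pa(counts, grp, base_group = node, ...)
        if (nrow(res) > 0) {
          res$node <- tag
          res$level <- li
          results[[length(results) + 1]] <- as.data.frame(res)
        }
        comparisons[[length(comparisons) + 1]] <- data.frame(
          node = tag, level = li, n_node = length(node_cells),
          n_complement = length(comp_cells)
        )
      }
    }
  }
  all_cols <- unique(unlist(lapply(results, names)))
  results <- lapply(results, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  })
  list(results = if (length(results) > 0) do.call(rbind, results) else NULL,
       comparisons = if (length(comparisons) > 0) do.call(rbind, comparisons) else NULL,
       skipped = skipped)
}
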