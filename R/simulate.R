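# Synthetic, fully ground-truthed data generator: a random genome with
# genes on both strands, planted PAS hexamers upstream of every cleavage
# site, optional internal-priming A-stretches and unannotated (de novo)
# PAs, and a tagged BAM of 3'-end reads whose pileups follow the Gaussian
# peak model with Dirichlet-multinomial peak usage per cell.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 20 genes with 2-3 cleavage sites 400 bp apart, read
#' pileups of spread 30 bp truncated at two spreads, Dirichlet-multinomial
#' peak usage with precision 10, two groups of 100 cells averaging 15 UMIs
#' per gene, 30% UMI duplication, and 10% of genes carrying a planted
#' internal-priming A-stretch or an unannotated PA.
#'
#' @param n_genes number of genes
#' @param peaks_min,peaks_max range of cleavage sites per gene (sampled
#'   uniformly)
#' @param spacing distance between adjacent cleavage sites (bp)
#' @param sigma read-position spread around each peak mode (bp)
#' @param mode_offset distance from peak mode to cleavage site (bp,
#'   transcription direction)
#' @param precision Dirichlet precision (sum of alpha)
#' @param frac_differential fraction of genes with opposite proximal/distal
#'   usage bias between the two groups (the rest are null genes)
#' @param alpha_base,alpha_alt explicit per-group Dirichlet alphas applied
#'   to every gene whose peak count matches their length (overrides the
#'   precision/bias scheme); NULL to use the scheme
#' @param cells_per_group cells per group
#' @param group_names two group labels
#' @param umi_mean,umi_size negative-binomial UMIs per cell per gene
#' @param dup_rate probability a UMI emits one duplicate read (jittered
#'   position)
#' @param frac_internal_priming fraction of genes with a planted A-stretch
#'   and reads piled on it
#' @param ip_read_frac expected internal-priming UMIs per cell relative to
#'   `umi_mean`
#' @param frac_de_novo fraction of genes with one PA withheld from the
#'   emitted PA BED (still present in the truth tables)
#' @param read_length read length (bp, 10x-like single-end)
#' @param spliced_frac fraction of reads written with a spliced
#'   (`30M100N61M`-style) CIGAR to exercise M-only counting
#' @param seed mandatory RNG seed
#' @return an `apa_sim_config` list
#' @export
sim_config <- function(n_genes = 20, peaks_min = 2, peaks_max = 3, spacing = 400,
                       sigma = 30, mode_offset = 65, precision = 10,
                       frac_differential = 0.5, alpha_base = NULL, alpha_alt = NULL,
                       cells_per_group = 100, group_names = c("g1", "g2"),
                       umi_mean = 15, umi_size = 2, dup_rate = 0.3,
                       frac_internal_priming = 0.1, ip_read_frac = 0.3,
                       frac_de_novo = 0.1, read_length = 91, spliced_frac = 0.1,
                       seed) {
  stopifnot(!missing(seed),
            frac_differential >= 0 && frac_differential <= 1,
            frac_internal_priming >= 0 && frac_internal_priming <= 1,
            frac_de_novo >= 0 && frac_de_novo <= 1,
            dup_rate >= 0 && dup_rate <= 1)
  structure(as.list(environment()), class = "apa_sim_config")
}

# Truncated normal on [-b, b] * sd via inverse CDF.
rtrunc_norm <- function(n, sd, b = 2) {
  u <- stats::runif(n, stats::pnorm(-b), stats::pnorm(b))
  stats::qnorm(u) * sd
}

# Replace any A (or T) run of >= 13 in a chromosome string, avoiding
# planted intervals, so rule 3 can never fire on unplanted sequence.
break_homopolymers <- function(seq_chr, protected) {
  for (base in c("A", "T")) {
    repeat {
      m <- gregexpr(paste0(base, "{13,}"), seq_chr)[[1]]
      if (m[1] == -1) break
      fixed_any <- FALSE
      for (i in seq_along(m)) {
        s <- m[i]; e <- s + attr(m, "match.length")[i] - 1
        if (nrow(protected) > 0 &&
            any(protected$start <= s & protected$end >= e)) next
        cand <- setdiff(s:e, unlist(mapply(seq, protected$start, protected$end,
                                           SIMPLIFY = FALSE)))
        if (length(cand) == 0) next
        pos <- cand[ceiling(length(cand) / 2)]
        substr(seq_chr, pos, pos) <- if (base == "A") "C" else "G"
        fixed_any <- TRUE
      }
      if (!fixed_any) break
    }
  }
  seq_chr
}

#' Build a synthetic reference (FASTA + GTF + PA BED + truth)
#'
#' Genes alternate strand across two chromosomes. Every cleavage site gets
#' an `AATAAA` planted 20 bp upstream; internal-priming genes get a 13-A
#' stretch planted 60 bp downstream of a decoy pileup mode between the
#' first two cleavage sites; de novo genes have their distal PA withheld
#' from the emitted BED. Accidental A/T homopolymers of 13+ outside the
#' planted stretches are broken so internal-priming flags are fully
#' controlled.
#'
#' @param config an `apa_sim_config`
#' @param dir output directory
#' @return list with paths (`fasta`, `gtf`, `pa_bed`), the constructed
#'   `models` (`apa_gene_models`), and `truth` tables (`genes`, `pa`,
#'   `ip_sites`)
#' @export
simulate_apa_reference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_genes
  pool <- seq(config$peaks_min, config$peaks_max)
  J <- pool[sample.int(length(pool), n, replace = TRUE)]
  strand <- rep(c("+", "-"), length.out = n)
  chrom <- rep(c("chr1", "chr2"), each = ceiling(n / 2))[1:n]
  ip_gene <- rep(FALSE, n)
  if (config$frac_internal_priming > 0) {
    ip_gene[sample(n, round(config$frac_internal_priming * n))] <- TRUE
  }
  dn_gene <- rep(FALSE, n)
  cand <- which(!ip_gene)
  if (config$frac_de_novo > 0 && length(cand) > 0) {
    dn_gene[sample(cand, min(length(cand), round(config$frac_de_novo * n)))] <- TRUE
  }
  diff_gene <- rep(FALSE, n)
  if (config$frac_differential > 0) {
    diff_gene[sample(n, round(config$frac_differential * n))] <- TRUE
  }

  gap <- 1200
  pre <- 700   # exon1 + intron + CDS part of the last exon
  genes <- list(); pa_rows <- list(); ip_rows <- list()
  models <- list()
  cursor <- stats::setNames(c(200L, 200L), c("chr1", "chr2"))
  layout <- list()
  for (i in seq_len(n)) {
    utr_len <- 150 + (J[i] - 1) * config$spacing
    glen <- pre + utr_len
    g0 <- cursor[[chrom[i]]]
    g1 <- g0 + glen - 1L
    cursor[[chrom[i]]] <- g1 + gap + 1L
    gid <- sprintf("g%02d", i)
    if (strand[i] == "+") {
      utr <- c(g0 + pre, g1)
      cleav <- utr[1] + 150 + (seq_len(J[i]) - 1) * config$spacing
      exon1 <- c(g0, g0 + 199L)
      exon2 <- c(g0 + 500L, g1)
    } else {
      utr <- c(g0, g1 - pre)
      cleav <- utr[2] - 150 - (seq_len(J[i]) - 1) * config$spacing
      exon1 <- c(g1 - 199L, g1)
      exon2 <- c(g0, g1 - 500L)
    }
    modes <- if (strand[i] == "+") cleav - config$mode_offset else cleav + config$mode_offset
    layout[[gid]] <- list(i = i, gid = gid, chrom = chrom[i], strand = strand[i],
                          g0 = g0, g1 = g1, utr = utr, cleav = cleav, modes = modes)
    tx <- list(transcript_id = paste0(gid, ".t1"),
               exons = data.frame(start = c(min(exon1[1], exon2[1]), max(exon1[1], exon2[1])),
                                  end = c(min(exon1[2], exon2[2]), max(exon1[2], exon2[2]))),
               utr = data.frame(start = utr[1], end = utr[2]))
    models[[gid]] <- structure(
      list(gene_id = gid, chrom = chrom[i], strand = strand[i],
           transcripts = stats::setNames(list(tx), tx$transcript_id),
           utr = tx$utr, ext = tx$utr),
      class = "apa_gene_model"
    )
    annotated <- rep(TRUE, J[i])
    if (dn_gene[i]) annotated[J[i]] <- FALSE   # withhold the distal PA
    genes[[gid]] <- data.frame(gene_id = gid, chrom = chrom[i], strand = strand[i],
                               J = J[i], ip = ip_gene[i], de_novo = dn_gene[i],
                               differential = diff_gene[i])
    pa_rows[[gid]] <- data.frame(gene_id = gid, peak = seq_len(J[i]),
                                 cleavage = cleav, mode = modes,
                                 annotated = annotated)
    if (ip_gene[i]) {
      ip_mode_txn_off <- 150 + config$spacing / 2   # between cleavage 1 and 2
      ip_mode <- if (strand[i] == "+") utr[1] + ip_mode_txn_off else utr[2] - ip_mode_txn_off
      stretch <- txn_window(ip_mode, strand[i], 60, 72)
      ip_rows[[gid]] <- data.frame(gene_id = gid, ip_mode = ip_mode,
                                   stretch_start = stretch[1], stretch_end = stretch[2])
    }
  }

  chrom_len <- cursor + 2500L
  seqs <- lapply(names(chrom_len), function(cn) {
    paste(sample(c("A", "C", "G", "T"), chrom_len[[cn]], replace = TRUE), collapse = "")
  })
  names(seqs) <- names(chrom_len)

  plant <- function(seq_chr, start, txt) {
    substr(seq_chr, start, start + nchar(txt) - 1) <- txt
    seq_chr
  }
  protected <- stats::setNames(
    lapply(names(seqs), function(cn) data.frame(start = integer(0), end = integer(0))),
    names(seqs)
  )
  for (gid in names(layout)) {
    L <- layout[[gid]]
    for (c_pos in L$cleav) {
      # PAS hexamer starting 25 bp upstream of the cleavage site
      w <- txn_window(c_pos, L$strand, -25, -20)
      motif <- if (L$strand == "+") "AATAAA" else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString("AATAAA")))
      seqs[[L$chrom]] <- plant(seqs[[L$chrom]], w[1], motif)
      protected[[L$chrom]] <- rbind(protected[[L$chrom]],
                                    data.frame(start = w[1], end = w[2]))
    }
    if (!is.null(ip_rows[[gid]])) {
      ip <- ip_rows[[gid]]
      stretch_txt <- strrep(if (L$strand == "+") "A" else "T", 13)
      seqs[[L$chrom]] <- plant(seqs[[L$chrom]], ip$stretch_start, stretch_txt)
      protected[[L$chrom]] <- rbind(protected[[L$chrom]],
                                    data.frame(start = ip$stretch_start,
                                               end = ip$stretch_end))
    }
  }
  for (cn in names(seqs)) {
    seqs[[cn]] <- break_homopolymers(seqs[[cn]], protected[[cn]])
  }

  fasta <- file.path(dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, fasta, width = 70)
  if (file.exists(paste0(fasta, ".fai"))) file.remove(paste0(fasta, ".fai"))
  Rsamtools::indexFa(fasta)

  models <- structure(models, class = "apa_gene_models")
  gtf <- file.path(dir, "genes.gtf")
  write_gene_models(models, gtf)

  pa_truth <- do.call(rbind, pa_rows)
  rownames(pa_truth) <- NULL
  gene_truth <- do.call(rbind, genes)
  rownames(gene_truth) <- NULL
  strand_of <- stats::setNames(gene_truth$strand, gene_truth$gene_id)
  chrom_of <- stats::setNames(gene_truth$chrom, gene_truth$gene_id)
  ann <- pa_truth[pa_truth$annotated, , drop = FALSE]
  pa_bed_df <- data.frame(chrom = chrom_of[ann$gene_id], pos = ann$cleavage,
                          strand = strand_of[ann$gene_id], source = "simulated",
                          stringsAsFactors = FALSE)
  class(pa_bed_df) <- c("apa_pa_sites", "data.frame")
  pa_bed <- file.path(dir, "pa_sites.bed")
  write_pa_sites(pa_bed_df, pa_bed)

  list(fasta = fasta, gtf = gtf, pa_bed = pa_bed, models = models,
       layout = layout,
       truth = list(genes = gene_truth, pa = pa_truth,
                    ip_sites = if (length(ip_rows) > 0) do.call(rbind, ip_rows) else NULL),
       dir = dir)
}

# Per-gene group alphas under the configured usage scheme.
gene_alphas <- function(config, J, differential) {
  if (!is.null(config$alpha_base) && length(config$alpha_base) == J) {
    return(list(config$alpha_base,
                config$alpha_alt %||% rev(config$alpha_base)))
  }
  if (differential) {
    base <- J:1; alt <- 1:J
  } else {
    base <- alt <- rep(1, J)
  }
  list(config$precision * base / sum(base),
       config$precision * alt / sum(alt))
}

#' Simulate tagged 3'-end reads into a BAM
#'
#' Per cell and gene, the UMI count is negative-binomial, peak choice is
#' multinomial with Dirichlet proportions drawn per cell from the group's
#' alpha, and each UMI's representative position is a rounded truncated
#' normal around the peak mode. Duplicate reads are emitted with jittered
#' positions; a fraction of reads carry spliced CIGARs. Internal-priming
#' genes additionally emit reads piled on the planted A-stretch decoy mode
#' (excluded from the truth count matrices, registered separately).
#'
#' @param config an `apa_sim_config`
#' @param ref output of [simulate_apa_reference()]
#' @param dir output directory
#' @return list with `bam`, `barcodes_file`, `groups_file`, `barcodes`,
#'   `groups` (data.frame), `truth_counts` (per gene: cells x peaks matrix)
#'   and `truth_alpha`
#' @export
simulate_apa_reads <- function(config, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  groups <- config$group_names
  cells <- c(sprintf("%s_C%04d", groups[1], seq_len(config$cells_per_group)),
             sprintf("%s_C%04d", groups[2], seq_len(config$cells_per_group)))
  cell_group <- rep(groups, each = config$cells_per_group)
  fa <- Rsamtools::FaFile(ref$fasta)
  chrom_seq <- lapply(stats::setNames(nm = unique(ref$truth$genes$chrom)), function(cn) {
    as.character(Rsamtools::scanFa(fa, GenomicRanges::GRanges(
      cn, IRanges::IRanges(1, GenomeInfoDb::seqlengths(Rsamtools::seqinfo(fa))[[cn]])))[[1]])
  })
  rl <- config$read_length
  half <- floor(rl / 2)
  sam_rows <- list()
  truth_counts <- list()
  truth_alpha <- list()
  for (gid in names(ref$layout)) {
    L <- ref$layout[[gid]]
    g <- ref$truth$genes[ref$truth$genes$gene_id == gid, ]
    al <- gene_alphas(config, g$J, g$differential)
    truth_alpha[[gid]] <- al
    cnt <- matrix(0L, nrow = length(cells), ncol = g$J,
                  dimnames = list(cells, NULL))
    modes_all <- c(L$modes, if (g$ip) ref$truth$ip_sites$ip_mode[
      ref$truth$ip_sites$gene_id == gid] else NULL)
    # per-cell molecule draws
    cell_i <- integer(0); kvec <- integer(0)
    for (ci in seq_along(cells)) {
      alpha <- if (cell_group[ci] == groups[1]) al[[1]] else al[[2]]
      nu <- stats::rnbinom(1, mu = config$umi_mean, size = config$umi_size)
      ip_n <- if (g$ip) stats::rpois(1, config$ip_read_frac * config$umi_mean) else 0L
      ks <- integer(0)
      if (nu > 0) {
        p <- rdirichlet(1, alpha)[1, ]
        ks <- sample.int(g$J, nu, replace = TRUE, prob = p)
        cnt[ci, ] <- cnt[ci, ] + tabulate(ks, nbins = g$J)
      }
      ks <- c(ks, rep(g$J + 1L, ip_n))
      cell_i <- c(cell_i, rep(ci, length(ks)))
      kvec <- c(kvec, ks)
    }
    truth_counts[[gid]] <- cnt
    n_umi <- length(kvec)
    if (n_umi == 0) next
    x <- modes_all[kvec] + round(rtrunc_norm(n_umi, config$sigma, 2))
    ub <- sprintf("U%05d", seq_len(n_umi))
    dup <- stats::rbinom(n_umi, 1, config$dup_rate) == 1
    # expand duplicates (jittered position, same UMI)
    idx <- c(seq_len(n_umi), which(dup))
    rnum <- c(rep(1L, n_umi), rep(2L, sum(dup)))
    xr <- c(x, x[dup] + sample(-5:5, sum(dup), replace = TRUE))
    nr <- length(idx)
    spliced <- stats::runif(nr) < config$spliced_frac
    m1 <- 30L; gap_n <- 100L; m2 <- rl - m1
    start <- ifelse(spliced, xr - floor((m1 + gap_n + m2 - 1) / 2), xr - half)
    cigar <- ifelse(spliced, sprintf("%dM%dN%dM", m1, gap_n, m2), sprintf("%dM", rl))
    cs <- chrom_seq[[L$chrom]]
    seq_read <- ifelse(
      spliced,
      paste0(substring(cs, start, start + m1 - 1),
             substring(cs, start + m1 + gap_n, start + m1 + gap_n + m2 - 1)),
      substring(cs, start, start + rl - 1)
    )
    sam_rows[[gid]] <- data.frame(
      qname = sprintf("%s:%s:%s:%d", gid, cells[cell_i[idx]], ub[idx], rnum),
      flag = if (L$strand == "+") 0L else 16L,
      chrom = L$chrom, pos = start, cigar = cigar, seq = seq_read,
      cb = cells[cell_i[idx]], ub = ub[idx], stringsAsFactors = FALSE
    )
  }
  sam <- do.call(rbind, sam_rows)
  sam <- sam[order(sam$chrom, sam$pos), , drop = FALSE]

  info <- Rsamtools::seqinfo(fa)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", GenomeInfoDb::seqnames(info),
                   GenomeInfoDb::seqlengths(info)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s",
                  sam$qname, sam$flag, sam$chrom, sam$pos, sam$cigar,
                  sam$seq, strrep("I", nchar(sam$seq)), sam$cb, sam$ub)
  sam_path <- file.path(dir, "reads.sam")
  writeLines(c(hdr, body), sam_path)
  bam_path <- file.path(dir, "reads.bam")
  tmp <- Rsamtools::asBam(sam_path, sub("\\.bam$", "", bam_path),
                          overwrite = TRUE, indexDestination = TRUE)

  barcodes_file <- file.path(dir, "barcodes.tsv")
  writeLines(cells, barcodes_file)
  groups_df <- data.frame(cell = cells, group = cell_group, stringsAsFactors = FALSE)
  groups_file <- file.path(dir, "groups.tsv")
  utils::write.table(groups_df, groups_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bam = tmp, barcodes_file = barcodes_file, groups_file = groups_file,
       barcodes = cells, groups = groups_df, truth_counts = truth_counts,
       truth_alpha = truth_alpha, dir = dir)
}

#' Simulate a complete ground-truthed dataset
#'
#' @param config an `apa_sim_config`
#' @param dir output directory
#' @return combined list of [simulate_apa_reference()] and
#'   [simulate_apa_reads()] outputs
#' @export
simulate_apa_dataset <- function(config, dir) {
  ref <- simulate_apa_reference(config, dir)
  reads <- simulate_apa_reads(config, ref, dir)
  c(ref, reads)
}
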