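# Reference input handling: gene models from GTF, known PA sites from BED,
# genome sequence from indexed FASTA. Everything downstream works on the
# objects built here.

#' Load gene models from a GTF file
#'
#' Builds one gene model per gene, keeping per-transcript exon structure and
#' the annotated 3' UTR. The UTR is taken from `three_prime_utr` features
#' when the annotation provides them; otherwise it is derived as the part of
#' the last exon downstream of the `stop_codon` feature, and as the whole
#' last exon if no stop codon is annotated either.
#'
#' @param gtf_path path to a GTF/GFF file with gene/transcript/exon features
#' @return an object of class `apa_gene_models`: a named list of per-gene
#'   models, each holding `gene_id`, `chrom`, `strand`, per-transcript exon
#'   and UTR tables, the distinct annotated UTR intervals (`utr`) and the
#'   extended search regions (`ext`, initialised to `utr`; see
#'   [extend_utrs()]).
#' @export
load_gene_models <- function(gtf_path) {
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("failed to parse '", gtf_path, "': ", conditionMessage(e))
  )
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    transcript_id = if (!is.null(gr$transcript_id)) as.character(gr$transcript_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  gene_ids <- unique(df$gene_id[!is.na(df$gene_id)])
  models <- list()
  for (g in gene_ids) {
    sub <- df[df$gene_id == g & !is.na(df$gene_id), , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    ex <- ex[ex$strand %in% c("+", "-"), , drop = FALSE]
    if (nrow(ex) == 0) {
      warning("gene '", g, "' has no stranded exons; skipped")
      next
    }
    strand <- ex$strand[1]
    chrom <- ex$chrom[1]
    tx_ids <- unique(ex$transcript_id)
    transcripts <- list()
    for (tx in tx_ids) {
      tex <- ex[ex$transcript_id == tx, , drop = FALSE]
      tex <- tex[order(tex$start), , drop = FALSE]
      utr <- sub[sub$type == "three_prime_utr" & sub$transcript_id == tx, , drop = FALSE]
      if (nrow(utr) > 0) {
        utr_iv <- data.frame(start = utr$start, end = utr$end)
      } else {
        last_exon <- if (strand == "+") tex[nrow(tex), ] else tex[1, ]
        stopc <- sub[sub$type == "stop_codon" & sub$transcript_id == tx, , drop = FALSE]
        if (nrow(stopc) > 0) {
          utr_iv <- if (strand == "+") {
            data.frame(start = max(stopc$end) + 1, end = last_exon$end)
          } else {
            data.frame(start = last_exon$start, end = min(stopc$start) - 1)
          }
        } else {
          utr_iv <- data.frame(start = last_exon$start, end = last_exon$end)
        }
      }
      utr_iv <- utr_iv[utr_iv$start <= utr_iv$end, , drop = FALSE]
      transcripts[[tx]] <- list(
        transcript_id = tx,
        exons = data.frame(start = tex$start, end = tex$end),
        utr = utr_iv
      )
    }
    utr_all <- unique(do.call(rbind, lapply(transcripts, `[[`, "utr")))
    utr_all <- utr_all[order(utr_all$start, utr_all$end), , drop = FALSE]
    rownames(utr_all) <- NULL
    models[[g]] <- structure(
      list(gene_id = g, chrom = chrom, strand = strand,
           transcripts = transcripts, utr = utr_all, ext = utr_all),
      class = "apa_gene_model"
    )
  }
  structure(models, class = "apa_gene_models")
}

#' Extend annotated 3' UTRs downstream
#'
#' Each annotated 3' UTR is extended by `extension` bp in the transcription
#' direction and truncated at the nearest downstream same-strand annotated
#' gene start, so that extended regions never bleed into a neighbouring
#' gene's exons. Antisense neighbours are ignored (3'-end libraries are
#' stranded).
#'
#' @param models an `apa_gene_models` object
#' @param extension non-negative extension length in bp (default 2000)
#' @param boundary_models gene models used as truncation boundaries
#'   (defaults to `models`)
#' @return `models` with the `ext` component of every gene replaced by the
#'   merged extended regions
#' @export
extend_utrs <- function(models, extension = 2000, boundary_models = models) {
  stopifnot(extension >= 0)
  spans <- do.call(rbind, lapply(boundary_models, function(m) {
    ex <- do.call(rbind, lapply(m$transcripts, `[[`, "exons"))
    data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
               start = min(ex$start), end = max(ex$end))
  }))
  for (g in names(models)) {
    m <- models[[g]]
    other <- spans[spans$gene_id != g & spans$chrom == m$chrom & spans$strand == m$strand, ]
    ext <- m$utr
    for (i in seq_len(nrow(ext))) {
      if (m$strand == "+") {
        new_end <- ext$end[i] + extension
        dn <- other$start[other$start > ext$end[i]]
        if (length(dn) > 0) new_end <- min(new_end, min(dn) - 1)
        ext$end[i] <- max(new_end, ext$end[i])
      } else {
        new_start <- ext$start[i] - extension
        dn <- other$end[other$end < ext$start[i]]
        if (length(dn) > 0) new_start <- max(new_start, max(dn) + 1)
        ext$start[i] <- max(1L, min(new_start, ext$start[i]))
      }
    }
    # merge overlapping/adjacent extended intervals
    ext <- ext[order(ext$start), , drop = FALSE]
    if (nrow(ext) > 1) {
      keep <- ext[1, , drop = FALSE]
      for (i in 2:nrow(ext)) {
        if (ext$start[i] <= keep$end[nrow(keep)] + 1) {
          keep$end[nrow(keep)] <- max(keep$end[nrow(keep)], ext$end[i])
        } else {
          keep <- rbind(keep, ext[i, ])
        }
      }
      ext <- keep
    }
    rownames(ext) <- NULL
    models[[g]]$ext <- ext
  }
  models
}

#' Write gene models to GTF
#'
#' Emits gene, transcript, exon and three_prime_utr records in a canonical
#' layout so that write -> read -> write round-trips are byte-stable.
#'
#' @param models an `apa_gene_models` object
#' @param path output GTF path
#' @return `path`, invisibly
#' @export
write_gene_models <- function(models, path) {
  lines <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tapaflow\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start, end, strand, attrs)
  }
  for (m in models) {
    all_ex <- do.call(rbind, lapply(m$transcripts, `[[`, "exons"))
    gattr <- sprintf("gene_id \"%s\";", m$gene_id)
    lines <- c(lines, fmt(m$chrom, "gene", min(all_ex$start), max(all_ex$end), m$strand, gattr))
    for (tx in m$transcripts) {
      tattr <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", m$gene_id, tx$transcript_id)
      lines <- c(lines, fmt(m$chrom, "transcript", min(tx$exons$start), max(tx$exons$end),
                            m$strand, tattr))
      for (i in order(tx$exons$start)) {
        lines <- c(lines, fmt(m$chrom, "exon", tx$exons$start[i], tx$exons$end[i], m$strand, tattr))
      }
      if (!is.null(tx$utr) && nrow(tx$utr) > 0) {
        for (i in order(tx$utr$start)) {
          lines <- c(lines, fmt(m$chrom, "three_prime_utr", tx$utr$start[i], tx$utr$end[i],
                                m$strand, tattr))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load known polyadenylation sites from BED
#'
#' Interval records are collapsed to the strand-appropriate single cleavage
#' base (the 3'-most base in transcription direction), and duplicate
#' (chrom, position, strand) records across sources are merged.
#'
#' @param bed_path path to a BED file; at least 6 columns (strand required)
#' @return a data.frame of class `apa_pa_sites` with columns `chrom`, `pos`
#'   (1-based cleavage base), `strand`, `source`
#' @export
load_pa_reference <- function(bed_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 6) {
    stop("PA BED '", bed_path, "' has no strand column (need BED6); records rejected")
  }
  strand <- as.character(bed[[6]])
  if (any(!strand %in% c("+", "-"))) {
    stop("PA BED '", bed_path, "' contains records without a valid strand; rejected")
  }
  # BED is 0-based half-open; the cleavage base is the 3' end of the
  # interval in transcription direction.
  pos <- ifelse(strand == "+", bed[[3]], bed[[2]] + 1L)
  pa <- data.frame(chrom = as.character(bed[[1]]), pos = as.integer(pos),
                   strand = strand, source = as.character(bed[[4]]),
                   stringsAsFactors = FALSE)
  key <- paste(pa$chrom, pa$pos, pa$strand)
  dup <- duplicated(key)
  if (any(dup)) {
    multi <- unique(key[dup])
    pa$source[key %in% multi] <- "merged"
    pa <- pa[!dup, , drop = FALSE]
  }
  pa <- pa[order(pa$chrom, pa$pos, pa$strand), , drop = FALSE]
  rownames(pa) <- NULL
  class(pa) <- c("apa_pa_sites", "data.frame")
  pa
}

#' Write PA sites to BED6
#'
#' Single-base records; inverse of [load_pa_reference()].
#'
#' @param pa an `apa_pa_sites` data.frame
#' @param path output BED path
#' @return `path`, invisibly
#' @export
write_pa_sites <- function(pa, path) {
  pa <- pa[order(pa$chrom, pa$pos, pa$strand), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", pa$chrom, pa$pos - 1L, pa$pos, pa$source, pa$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Fetch genome sequence in transcription orientation
#'
#' @param fasta path to an indexed FASTA (a `.fai` index is created if
#'   absent) or an open [Rsamtools::FaFile]
#' @param chrom chromosome name
#' @param start,end 1-based closed interval; `end = start - 1` yields the
#'   empty string
#' @param strand `"+"` or `"-"`; minus-strand sequence is reverse-complemented
#' @return an uppercase nucleotide string of length `end - start + 1`
#'   (shorter, with a warning, if the interval was clipped at a chromosome
#'   boundary)
#' @export
fetch_seq <- function(fasta, chrom, start, end, strand = "+") {
  fa <- if (inherits(fasta, "FaFile")) fasta else {
    if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
    Rsamtools::FaFile(fasta)
  }
  info <- Rsamtools::seqinfo(fa)
  if (!chrom %in% GenomeInfoDb::seqnames(info)) {
    stop("chromosome '", chrom, "' not found in FASTA")
  }
  if (end < start) return("")
  len <- GenomeInfoDb::seqlengths(info)[[chrom]]
  s <- max(1L, start); e <- min(len, end)
  if (s != start || e != end) {
    warning("interval ", chrom, ":", start, "-", end, " clipped to chromosome bounds")
  }
  if (e < s) return("")
  seq <- Rsamtools::scanFa(fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e)))[[1]]
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  toupper(as.character(seq))
}
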