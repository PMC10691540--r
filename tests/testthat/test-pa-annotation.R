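# SID estimation, PAS motif scan, A-stretch detection and the three-rule
# retention logic.

test_that("SID quantiles match the type-7 empirical quantile oracle", {
  # constant distances
  pk <- data.frame(gene_id = sprintf("g%03d", 1:100), mu = 1000,
                   stringsAsFactors = FALSE)
  # construct models/PA so every gene is a control at distance 80
  models <- structure(lapply(pk$gene_id, function(g)
    toy_model(g, chrom = g, utr_start = 900, utr_end = 1200)), class = "apa_gene_models")
  names(models) <- pk$gene_id
  pa <- data.frame(chrom = pk$gene_id, pos = 1080, strand = "+",
                   source = "x", stringsAsFactors = FALSE)
  s <- estimate_sid(pk, pa, models)
  expect_equal(c(s$lower, s$upper), c(80, 80))
  expect_equal(s$median, 80)

  # graded distances 50,60,...,1040 against the quantile() oracle
  d <- seq(50, 1040, by = 10)
  pa2 <- data.frame(chrom = pk$gene_id, pos = 1000 + d, strand = "+",
                    source = "x", stringsAsFactors = FALSE)
  models2 <- structure(lapply(seq_along(pk$gene_id), function(i)
    toy_model(pk$gene_id[i], chrom = pk$gene_id[i], utr_start = 900,
              utr_end = 1000 + d[i] + 10)), class = "apa_gene_models")
  names(models2) <- pk$gene_id
  s2 <- estimate_sid(pk, pa2, models2)
  expect_equal(c(s2$lower, s2$upper),
               unname(quantile(d, c(0.05, 0.95), type = 7)))
})

test_that("minus-strand control distances are signed in transcription direction", {
  pk <- data.frame(gene_id = sprintf("g%03d", 1:60), mu = 980,
                   stringsAsFactors = FALSE)
  models <- structure(lapply(pk$gene_id, function(g)
    toy_model(g, chrom = g, strand = "-", utr_start = 800, utr_end = 1100)),
    class = "apa_gene_models")
  names(models) <- pk$gene_id
  pa <- data.frame(chrom = pk$gene_id, pos = 900, strand = "-",
                   source = "x", stringsAsFactors = FALSE)
  s <- estimate_sid(pk, pa, models, min_controls = 50)
  # PA at 900 is 80 bp downstream of mode 980 on the minus strand
  expect_equal(c(s$lower, s$upper), c(80, 80))
})

test_that("too few control genes errors and points at the override", {
  pk <- data.frame(gene_id = "g1", mu = 1000)
  models <- structure(list(g1 = toy_model("g1")), class = "apa_gene_models")
  pa <- data.frame(chrom = "chr1", pos = 1080, strand = "+", source = "x")
  expect_error(estimate_sid(pk, pa, models), "sid_override")
})

test_that("PAS scan finds all overlapping hexamer hits and nothing else", {
  expect_equal(scan_pas_motifs("CCAATAAAGG"),
               data.frame(motif = "AATAAA", pos = 3L))
  expect_equal(nrow(scan_pas_motifs("AAAAAA")), 0)  # A6 is not a signal
  expect_equal(nrow(scan_pas_motifs("CCNATAAAGG")), 0)  # N never matches
  expect_error(scan_pas_motifs("ACGTX"), "ACGTN")
  # brute-force sliding-window oracle on random sequence
  set.seed(9)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    oracle <- data.frame(motif = character(0), pos = integer(0))
    for (i in 1:(nchar(s) - 5)) {
      w <- substr(s, i, i + 5)
      if (w %in% PAS_HEXAMERS) oracle <- rbind(oracle,
                                               data.frame(motif = w, pos = i))
    }
    got <- scan_pas_motifs(s)
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("A-stretch detection has an exact 13-base boundary", {
  expect_true(detect_a_stretch(strrep("A", 13))$found)
  expect_false(detect_a_stretch(strrep("A", 12))$found)
  expect_false(detect_a_stretch(paste0(strrep("A", 7), "G", strrep("A", 7)))$found)
  hit <- detect_a_stretch(paste0("CCG", strrep("A", 14), "GG"))
  expect_equal(c(hit$start, hit$end), c(4, 17))
})

test_that("retention truth table holds for all eight flag combinations", {
  flags <- expand.grid(r1 = c(FALSE, TRUE), r2 = c(FALSE, TRUE),
                       r3 = c(FALSE, TRUE))
  status <- retention_status(flags$r1, flags$r2, flags$r3)
  expected <- ifelse(flags$r3, "discarded_internal_priming",
                     ifelse(flags$r1 | flags$r2, "retained",
                            "discarded_no_evidence"))
  expect_equal(status, expected)
  expect_equal(status == "retained", (flags$r1 | flags$r2) & !flags$r3)
})

# A controlled two-peak gene on a hand-built genome exercises the window
# arithmetic of all three rules.
test_that("annotate_peaks applies the rules in the right windows on both strands", {
  base <- strsplit(paste(rep("CGTG", 2000), collapse = ""), "")[[1]]
  # plus-strand peak at 1000, SID (40, 90): known PA at 1060 in SID;
  # second peak at 2000 with AATAAA at txn offset +45-20 window; third at
  # 3000 with an A-stretch inside the SID.
  base[2040:2045] <- strsplit("AATAAA", "")[[1]]   # rule 2 for peak 2000
  base[3050:3062] <- "A"                            # rule 3 for peak 3000
  fa <- write_toy_fasta(list(chr1 = paste(base, collapse = "")))
  sid <- sid_override(40, 90, 65)
  pa <- data.frame(chrom = "chr1", pos = 1060, strand = "+", source = "x",
                   stringsAsFactors = FALSE)
  peaks <- data.frame(gene_id = c("gA", "gB", "gC"),
                      peak_id = c("gA:P1", "gB:P1", "gC:P1"), chrom = "chr1",
                      strand = "+", mu = c(1000, 2000, 3000), sigma = 30,
                      weight = 1, stringsAsFactors = FALSE)
  ann <- annotate_peaks(peaks, sid, pa, fa)
  expect_equal(ann$rule1, c(TRUE, FALSE, FALSE))
  expect_equal(ann$rule2[2], TRUE)
  expect_equal(ann$rule3, c(FALSE, FALSE, TRUE))
  expect_equal(ann$status, c("retained", "retained", "discarded_internal_priming"))
  expect_equal(ann$pa_pos[1], 1060)
  expect_equal(ann$pa_source[1:2], c("known", "de_novo"))
  expect_equal(ann$pa_pos[2], 2065)    # mu + median(SID)

  # mirrored minus-strand peak: PA 60 bp downstream (decreasing coords)
  pam <- data.frame(chrom = "chr1", pos = 4940, strand = "-", source = "x",
                    stringsAsFactors = FALSE)
  pkm <- data.frame(gene_id = "gM", peak_id = "gM:P1", chrom = "chr1",
                    strand = "-", mu = 5000, sigma = 30, weight = 1,
                    stringsAsFactors = FALSE)
  annm <- annotate_peaks(pkm, sid, pam, fa)
  expect_true(annm$rule1)
  expect_equal(annm$status, "retained")
  expect_equal(annm$pa_pos, 4940)
})

test_that("a known PA co-occurring with an A-stretch is discarded as internal priming", {
  base <- rep("C", 3000)
  base[1050:1064] <- "A"
  fa <- write_toy_fasta(list(chr1 = paste(base, collapse = "")))
  pa <- data.frame(chrom = "chr1", pos = 1060, strand = "+", source = "x",
                   stringsAsFactors = FALSE)
  peaks <- data.frame(gene_id = "gA", peak_id = "gA:P1", chrom = "chr1",
                      strand = "+", mu = 1000, sigma = 30, weight = 1,
                      stringsAsFactors = FALSE)
  ann <- annotate_peaks(peaks, sid_override(40, 90, 65), pa, fa)
  expect_true(ann$rule1 && ann$rule3)
  expect_equal(ann$status, "discarded_internal_priming")
})

test_that("simulated internal-priming peaks are all discarded and no clean PA is lost to rule 3", {
  fx <- ref_pipeline()
  ip_genes <- fx$sim$truth$genes$gene_id[fx$sim$truth$genes$ip]
  discarded <- fx$ann[fx$ann$status == "discarded_internal_priming", ]
  expect_setequal(unique(discarded$gene_id), ip_genes)
  # rule 3 never fires on peaks at true (clean) PA modes
  truth <- fx$sim$truth$pa
  for (i in seq_len(nrow(fx$ann))) {
    near_true <- any(truth$gene_id == fx$ann$gene_id[i] &
                       abs(truth$mode - fx$ann$mu[i]) < 50)
    if (near_true) expect_false(fx$ann$rule3[i])
  }
})

test_that("de novo PAs land within half the SID width of the planted site", {
  fx <- ref_pipeline()
  truth <- fx$sim$truth$pa
  withheld <- truth[!truth$annotated, ]
  sid_halfwidth <- (90 - 40) / 2
  for (i in seq_len(nrow(withheld))) {
    est <- fx$ann[fx$ann$gene_id == withheld$gene_id[i] &
                    abs(fx$ann$mu - withheld$mode[i]) < 50, ]
    expect_equal(nrow(est), 1)
    expect_equal(est$pa_source, "de_novo")
    expect_true(abs(est$pa_pos - withheld$cleavage[i]) <= sid_halfwidth)
  }
})

test_that("nucleotide context around retained PAs shows the planted A-rich signal structure", {
  fx <- ref_pipeline()
  ret <- fx$ann[fx$ann$status == "retained" & fx$ann$pa_source == "known", ]
  # planted AATAAA occupies txn offsets [-25, -20] from each cleavage site:
  # upstream windows must be A-enriched relative to downstream ones
  up_a <- down_a <- numeric(0)
  for (i in seq_len(min(nrow(ret), 20))) {
    w_up <- if (ret$strand[i] == "+") c(ret$pa_pos[i] - 25, ret$pa_pos[i] - 20) else
      c(ret$pa_pos[i] + 20, ret$pa_pos[i] + 25)
    s_up <- fetch_seq(fx$sim$fasta, ret$chrom[i], w_up[1], w_up[2], ret$strand[i])
    w_dn <- if (ret$strand[i] == "+") c(ret$pa_pos[i] + 20, ret$pa_pos[i] + 25) else
      c(ret$pa_pos[i] - 25, ret$pa_pos[i] - 20)
    s_dn <- fetch_seq(fx$sim$fasta, ret$chrom[i], w_dn[1], w_dn[2], ret$strand[i])
    count_a <- function(s) lengths(regmatches(s, gregexpr("A", s)))
    up_a <- c(up_a, count_a(s_up))
    down_a <- c(down_a, count_a(s_dn))
  }
  expect_gt(mean(up_a), mean(down_a))
})
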