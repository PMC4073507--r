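test_that("planted class codes are recovered exactly and zero queries work", {
  cfg <- small_cfg(seed = 31)
  sim <- simulate_annotation_and_queries(cfg)
  cc <- assign_class_codes(sim$query, sim$reference)
  joined <- dplyr::left_join(sim$truth, cc, by = "transcript_id")
  expect_equal(joined$primary_code, joined$true_code)

  empty <- simulate_annotation_and_queries(
    small_cfg(seed = 1,
              queries_per_code = c("=" = 0, c = 0, j = 0, e = 0, o = 0,
                                   i = 0, x = 0, s = 0, p = 0, u = 0),
              u_split = c(multi_noncoding = 0, multi_coding = 0,
                          single_exon = 0, short = 0)))
  expect_equal(nrow(empty$query), 0)
})

test_that("the same seed reproduces byte-identical bundle files", {
  cfg <- small_cfg(seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_linc_bundle(cfg, dir = d1)
  simulate_linc_bundle(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("infeasible geometry is rejected as a configuration error", {
  expect_error(
    simulate_annotation_and_queries(small_cfg(seed = 1,
                                              chrom_length = 1e4)),
    class = "lincfinder_config_error"
  )
  expect_error(sim_config(), class = "lincfinder_config_error")
})

test_that("every planted coding sequence contains its recorded ORF verbatim", {
  cfg <- small_cfg(seed = 35)
  sim <- simulate_sequences(cfg, simulate_annotation_and_queries(cfg))
  coding <- dplyr::filter(sim$truth, .data$true_biotype == "coding",
                          .data$is_linc_candidate)
  expect_gt(nrow(coding), 0)
  seqs <- setNames(sim$sequences$sequence, sim$sequences$transcript_id)
  for (i in seq_len(nrow(coding))) {
    tr <- coding[i, ]
    orf <- substr(seqs[[tr$transcript_id]], tr$orf_start + 1, tr$orf_end)
    expect_equal(substr(orf, 1, 3), "ATG")
    expect_true(substr(orf, nchar(orf) - 2, nchar(orf)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_equal(nchar(orf) %% 3, 0)
    found <- find_longest_orf(seqs[[tr$transcript_id]])
    expect_gte(found$length_nt, nchar(orf))
  }
})

test_that("zero divergence makes the classifier perform at chance", {
  # the hexamer table is trained on sequences disjoint from the CV data:
  # a table trained on the CV sequences themselves leaks each sequence's
  # own hexamers into its class profile and inflates apparent accuracy
  accs <- vapply(1:3, function(s) {
    cfg <- small_cfg(seed = 200 + s, divergence = 0)
    sim <- simulate_sequences(cfg, simulate_annotation_and_queries(cfg))
    tr_c <- dplyr::filter(sim$training, class == "coding")
    tr_n <- dplyr::filter(sim$training, class == "noncoding")
    half <- seq_len(nrow(tr_c) / 2)
    hex <- train_hexamer_table(tr_c$sequence[half], tr_n$sequence[half])
    fc <- compute_coding_features(
      tibble::tibble(transcript_id = tr_c$set_id[-half],
                     sequence = tr_c$sequence[-half]), hex)
    fn <- compute_coding_features(
      tibble::tibble(transcript_id = tr_n$set_id[-half],
                     sequence = tr_n$sequence[-half]), hex)
    m <- train_coding_model(fc, fn, scheme = "standard", seed = s)
    mean((m$cv_metrics$sensitivity + m$cv_metrics$specificity) / 2)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("alignment regimes separate conservation scores (AUC >= 0.9)", {
  cfg <- small_cfg(seed = 37)
  sim <- simulate_alignments(
    cfg, simulate_sequences(cfg, simulate_annotation_and_queries(cfg)))
  cal <- sim$calibration
  s_cod <- score_alignments(cal$coding, cal$coding_sequences)$score
  s_non <- score_alignments(cal$noncoding, cal$noncoding_sequences)$score
  auc <- mean(outer(s_cod, s_non, ">")) +
    0.5 * mean(outer(s_cod, s_non, "=="))
  expect_gte(auc, 0.9)
  expect_gt(mean(s_cod), 0)
  expect_lt(mean(s_non), 0)
})

test_that("planted expression pairs are exactly co-monotone", {
  cfg <- small_cfg(seed = 39)
  sim <- simulate_counts(cfg, simulate_annotation_and_queries(cfg))
  expect_equal(nrow(sim$planted_pairs), 3)
  samples <- sim$mapped_totals$sample_id
  for (i in seq_len(nrow(sim$planted_pairs))) {
    x <- as.numeric(sim$counts[
      sim$counts$gene_id == sim$planted_pairs$linc_id[i], samples])
    y <- as.numeric(sim$counts[
      sim$counts$gene_id == sim$planted_pairs$coding_id[i], samples])
    expect_equal(cor(x, y, method = "spearman"), 1)
  }
})

test_that("lincRNA group carries the planted CV inflation across seeds", {
  ok <- vapply(1:8, function(s) {
    cfg <- small_cfg(seed = 300 + s)
    sim <- simulate_counts(cfg, simulate_annotation_and_queries(cfg))
    expr <- normalize_counts(sim$counts, sim$mapped_totals)
    cv <- dplyr::left_join(coefficient_of_variation(expr),
                           sim$gene_groups, by = "gene_id")
    mean(cv$cv_pct[cv$group == "linc"], na.rm = TRUE) >
      mean(cv$cv_pct[cv$group == "coding"], na.rm = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("SNP and QTL simulation honours rates and bookkeeping", {
  cfg <- small_cfg(seed = 41, snp_rate_per_kb = 0)
  sim0 <- simulate_snps_and_qtls(cfg)
  expect_equal(nrow(sim0$snps), 0)

  cfg2 <- small_cfg(seed = 42, n_qtl_meat = 7, n_qtl_other = 4)
  sim <- simulate_snps_and_qtls(cfg2)
  expect_equal(sum(sim$qtls$trait_group == "meat_muscle"), 7)
  expect_equal(sum(sim$qtls$trait_group == "other"), 4)
  expect_true(all(sim$qtls$end > sim$qtls$start))

  # homogeneous Poisson rate: total count within 4 SD of expectation
  rate_cfg <- small_cfg(seed = 43, snp_rate_per_kb = 2)
  n <- nrow(simulate_snps_and_qtls(rate_cfg)$snps)
  lambda <- 2 * 2 * 2e6 / 1000
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))
})

test_that("bundle files round-trip through the package readers", {
  cfg <- small_cfg(seed = 45)
  dir <- withr::local_tempdir()
  sim <- simulate_linc_bundle(cfg, dir = dir)

  q <- read_transcripts_gtf(file.path(dir, "queries.gtf"))
  expect_equal(dplyr::arrange(q, transcript_id, start)$start,
               dplyr::arrange(sim$query, transcript_id, start)$start)
  fa <- read_sequences_fasta(file.path(dir, "candidates.fa"))
  expect_equal(dplyr::arrange(fa, transcript_id),
               dplyr::arrange(sim$sequences, transcript_id))
  maf <- read_maf(file.path(dir, "alignments.maf"))
  expect_setequal(names(maf), names(sim$alignments))
  expect_equal(maf[[1]]$seq, sim$alignments[[names(maf)[1]]]$seq)
  cts <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_equal(cts, sim$counts)
  snps <- read_snp_bed(file.path(dir, "snps.bed"))
  expect_equal(snps$pos, sim$snps$pos)
  qtls <- read_qtl_tsv(file.path(dir, "qtls.tsv"))
  expect_equal(qtls$start, sim$qtls$start)
})
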