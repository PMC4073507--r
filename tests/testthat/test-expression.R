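toy_expr <- function(counts_mat, totals) {
  ids <- sprintf("g%02d", seq_len(nrow(counts_mat)))
  counts <- tibble::as_tibble(counts_mat,
                              .name_repair = ~ names(totals))
  counts <- dplyr::mutate(counts, gene_id = ids, .before = 1)
  normalize_counts(counts,
                   tibble::tibble(sample_id = names(totals),
                                  mapped_total = unname(totals)))
}

test_that("normalization divides by mapped totals and round-trips", {
  expr <- toy_expr(matrix(c(10, 0), nrow = 1), c(s1 = 1000, s2 = 500))
  expect_equal(expr$normalized, c(0.01, 0))
  set.seed(91)
  m <- matrix(rpois(60, 50), nrow = 10)
  totals <- setNames(sample(1e5:2e5, 6), paste0("s", 1:6))
  expr <- toy_expr(m, totals)
  back <- expr$normalized * expr$mapped_total
  expect_equal(back, expr$count)
  expect_error(toy_expr(m, setNames(rep(0, 6), paste0("s", 1:6))),
               class = "lincfinder_input_error")
})

test_that("detection summary counts samples above threshold with tallies", {
  m <- rbind(rep(5, 4), c(0, 0, 0, 0), c(1, 0, 2, 0))
  expr <- toy_expr(m, setNames(rep(1000, 4), paste0("s", 1:4)))
  det <- detection_summary(expr, below_k = 3)
  expect_equal(det$n_detected[match(c("g01", "g02", "g03"), det$gene_id)],
               c(4, 0, 2))
  expect_equal(attr(det, "n_all_samples"), 1)
  expect_equal(attr(det, "n_below_k"), 2)
  # monotone non-increasing in min_count
  det5 <- detection_summary(expr, min_count = 5)
  expect_true(all(det5$n_detected <= det$n_detected))
})

test_that("coefficient of variation matches direct formula and flags zero means", {
  expr <- toy_expr(rbind(c(1, 3), c(4, 4), c(0, 0)),
                   c(s1 = 1, s2 = 1))
  cv <- coefficient_of_variation(expr)
  expect_equal(cv$cv_pct[cv$gene_id == "g01"], 100 * sqrt(2) / 2)
  expect_equal(cv$cv_pct[cv$gene_id == "g02"], 0)
  expect_false(cv$cv_defined[cv$gene_id == "g03"])
  # scale invariance: doubling a row leaves its CV unchanged
  expr2 <- toy_expr(rbind(c(2, 6)), c(s1 = 1, s2 = 1))
  cv2 <- coefficient_of_variation(expr2)
  expect_equal(cv2$cv_pct, cv$cv_pct[cv$gene_id == "g01"])
})

test_that("group comparison reproduces the pooled t-test and conventions", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # textbook 2+2 case, hand-computed pooled t
  a <- c(1, 2); b <- c(4, 6)
  got <- compare_groups(a, b)
  sp <- sqrt((var(a) + var(b)) / 2)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 2 + 1 / 2))
  expect_equal(got$statistic, t_hand)
  expect_equal(got$mean_b, 5)
  expect_equal(got$sd_b, sd(b))

  # power at a planted 3-SD shift
  set.seed(92)
  hits <- vapply(1:50, function(i) {
    compare_groups(rnorm(100), rnorm(100, 3))$p_value < 1e-3
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  expect_error(compare_groups(1, c(1, 2)), class = "lincfinder_input_error")
})

test_that("SNP windows are strand-aware and truncated at chromosome bounds", {
  loci <- tibble::tibble(locus_id = c("plus", "minus"),
                         chrom = "chr1", strand = c("+", "-"),
                         span_start = c(50000, 50000),
                         span_end = c(52000, 52000))
  # 10 SNPs uniformly inside the plus-strand upstream window
  snps <- tibble::tibble(chrom = "chr1",
                         pos = seq(40000, 49999, length.out = 10))
  d <- snp_density(loci, snps)
  expect_equal(d$upstream_density[d$locus_id == "plus"], 1.0)
  expect_equal(d$upstream_kb[d$locus_id == "plus"], 10)
  # minus-strand locus looks upstream on the higher-coordinate side
  expect_equal(d$upstream_n[d$locus_id == "minus"], 0)
  snps_hi <- tibble::tibble(chrom = "chr1", pos = seq(52000, 61999, by = 500))
  d2 <- snp_density(loci, snps_hi)
  expect_equal(d2$upstream_n[d2$locus_id == "minus"], 20)

  # truncation at zero
  near0 <- tibble::tibble(locus_id = "edge", chrom = "chr1", strand = "+",
                          span_start = 3000, span_end = 4000)
  d3 <- snp_density(near0, snps)
  expect_equal(d3$upstream_kb, 3)
})

test_that("SNP counts equal a brute-force point-in-interval scan", {
  set.seed(93)
  loci <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    strand = sample(c("+", "-"), 30, replace = TRUE),
    span_start = sample(20000:400000, 30)
  ) |> dplyr::mutate(span_end = span_start + sample(1000:5000, 30))
  snps <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 2000,
                                        replace = TRUE),
                         pos = sample(0:420000, 2000, replace = TRUE))
  d <- snp_density(loci, snps)
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    up <- if (l$strand == "+") c(l$span_start - 10000, l$span_start)
          else c(l$span_end, l$span_end + 10000)
    dn <- if (l$strand == "+") c(l$span_end, l$span_end + 1000)
          else c(l$span_start - 1000, l$span_start)
    cnt <- function(w) sum(snps$chrom == l$chrom & snps$pos >= w[1] &
                             snps$pos < w[2])
    expect_equal(d$upstream_n[i], cnt(up))
    expect_equal(d$downstream_n[i], cnt(dn))
  }
  # counts are conserved: no window double-counts beyond the SNP total
  expect_lte(sum(d$upstream_n), nrow(snps))
})

test_that("mapping summary reproduces the printed per-sample arithmetic", {
  tsv <- system.file("extdata", "bovine_lt_mapping_counts.tsv",
                     package = "lincfinder")
  counts <- readr::read_tsv(tsv, show_col_types = FALSE)
  ms <- mapping_summary(counts)
  expect_equal(ms$pct_mapped[ms$sample_id == "LIM2"], 75.54)
  expect_equal(ms$pct_uniquely_mapped[ms$sample_id == "LIM2"], 71.38)
  expect_equal(ms$gigabases[ms$sample_id == "LIM1"], 8.64)
  expect_equal(attr(ms, "total_pairs"), 300941530)
  expect_equal(attr(ms, "total_gigabases"), 60.19)

  all_mapped <- tibble::tibble(sample_id = "x", n_reads = 1000,
                               n_mapped = 1000, n_uniquely_mapped = 1000,
                               n_uniquely_mapped_pairs = 500)
  expect_equal(mapping_summary(all_mapped)$pct_mapped, 100)
  expect_error(mapping_summary(dplyr::mutate(all_mapped, n_reads = 0)),
               class = "lincfinder_input_error")
})
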