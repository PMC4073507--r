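test_that("monotone profiles give rho of +/-1 and constants are flagged", {
  up <- spearman_pair(1:9, c(2, 4, 6, 8, 10, 12, 14, 16, 18))
  expect_equal(up$rho, 1)
  down <- spearman_pair(1:9, 9:1)
  expect_equal(down$rho, -1)
  flat <- spearman_pair(rep(1, 9), 1:9)
  expect_true(flat$undefined_rho)
  expect_true(is.na(flat$rho))
  expect_error(spearman_pair(1:3, 1:4), class = "lincfinder_input_error")
})

test_that("exact permutation p agrees with the reference implementation", {
  set.seed(111)
  for (n in c(5, 7)) {
    for (i in 1:20) {
      x <- sample(100, n)  # no ties
      y <- sample(100, n)
      got <- spearman_pair(x, y, p_method = "exact")
      want <- suppressWarnings(cor.test(x, y, method = "spearman",
                                        exact = TRUE))
      expect_equal(got$rho, unname(want$estimate), tolerance = 1e-12)
      expect_equal(got$p_value, want$p.value, tolerance = 1e-12,
                   info = paste("n", n, "rep", i))
    }
  }
})

test_that("exact p handles ties by enumerating over the tied ranks", {
  x <- c(1, 1, 2, 3, 4)
  y <- c(2, 2, 3, 4, 9)
  got <- spearman_pair(x, y, p_method = "exact")
  expect_equal(got$rho, 1)  # identical tie structure, same order
  # brute force over all 120 permutations of y
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perms(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  pm <- perms(seq_along(y))
  rhos <- apply(pm, 1, function(idx) cor(rank(x), rank(y[idx])))
  expect_equal(got$p_value, mean(abs(rhos) >= abs(got$rho) - 1e-12))
})

test_that("asymptotic p matches the t approximation used by cor.test", {
  set.seed(112)
  x <- rnorm(15); y <- rnorm(15)
  got <- spearman_pair(x, y, p_method = "asymptotic")
  rho <- cor(x, y, method = "spearman")
  tstat <- rho * sqrt(13 / (1 - rho^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 13))
})

test_that("Bonferroni threshold reproduces the screen-level arithmetic", {
  expect_equal(signif(bonferroni_threshold(418, 10775), 3), 1.11e-8)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_equal(bonferroni_threshold(10, 10), 5e-4)
})

test_that("no pair can clear a genome-scale Bonferroni bar under exact p", {
  # minimum attainable two-sided exact p at n = 9 is 2/9!
  p_min <- spearman_pair(1:9, 1:9, p_method = "exact")$p_value
  expect_equal(p_min, 2 / factorial(9))
  expect_gt(p_min, bonferroni_threshold(418, 10775))
})

screen_fixture <- function(seed, n_linc = 20, n_coding = 50, n_planted = 5) {
  withr::with_seed(seed, {
    lm <- matrix(rnbinom(n_linc * 9, mu = 50, size = 3), nrow = n_linc)
    cm <- matrix(rnbinom(n_coding * 9, mu = 200, size = 8), nrow = n_coding)
    for (k in seq_len(n_planted)) {
      while (sd(lm[k, ]) == 0) lm[k, ] <- rnbinom(9, mu = 50, size = 3)
      cm[k, ] <- lm[k, ] * 2L + 5L
    }
  })
  s <- paste0("s", 1:9)
  list(
    linc = dplyr::mutate(tibble::as_tibble(lm, .name_repair = ~s),
                         gene_id = sprintf("L%02d", 1:n_linc), .before = 1),
    coding = dplyr::mutate(tibble::as_tibble(cm, .name_repair = ~s),
                           gene_id = sprintf("C%02d", 1:n_coding),
                           .before = 1),
    planted = tibble::tibble(linc_id = sprintf("L%02d", 1:n_planted),
                             coding_id = sprintf("C%02d", 1:n_planted))
  )
}

test_that("planted monotone-linked pairs dominate the Bonferroni hits", {
  # every planted pair must pass with rho exactly 1 in every seed; the
  # asymptotic approximation additionally admits rare chance pairs with
  # |rho| just below 1 (expected well under one per 1000-pair screen)
  n_spurious <- 0
  for (seed in 1:10) {
    fx <- screen_fixture(seed)
    s <- all_pairs_screen(fx$linc, fx$coding)
    sig <- dplyr::filter(tibble::as_tibble(s), passes_bonferroni)
    found <- paste(sig$linc_id, sig$coding_id)
    want <- paste(fx$planted$linc_id, fx$planted$coding_id)
    expect_true(all(want %in% found), info = paste("seed", seed))
    planted_rows <- dplyr::filter(sig, paste(linc_id, coding_id) %in% want)
    expect_equal(planted_rows$rho, rep(1, 5))
    expect_equal(planted_rows$p_value, rep(0, 5))
    spur <- dplyr::filter(sig, !(paste(linc_id, coding_id) %in% want))
    expect_true(all(abs(spur$rho) < 1))
    n_spurious <- n_spurious + nrow(spur)
  }
  expect_lte(n_spurious / 10, 1)
})

test_that("a duplicated profile is flagged significant with rho 1", {
  fx <- screen_fixture(3, n_planted = 0)
  fx$coding[1, -1] <- fx$linc[1, -1]
  s <- all_pairs_screen(fx$linc, fx$coding)
  row <- dplyr::filter(tibble::as_tibble(s), linc_id == "L01",
                       coding_id == "C01")
  expect_equal(row$rho, 1)
  expect_equal(row$p_value, 0)
  expect_true(row$passes_bonferroni)
})

test_that("distance and cis annotation follow the 2-Mb gap definition", {
  fx <- screen_fixture(4, n_linc = 2, n_coding = 2, n_planted = 0)
  pos <- tibble::tibble(
    gene_id = c("L01", "L02", "C01", "C02"),
    chrom = c("chr1", "chr2", "chr1", "chr1"),
    start = c(1e6, 1e6, 2.5e6, 8e6),
    end = c(1.1e6, 1.1e6, 2.6e6, 8.1e6)
  )
  s <- tibble::as_tibble(all_pairs_screen(fx$linc, fx$coding,
                                          loci_positions = pos))
  r <- function(l, c) dplyr::filter(s, linc_id == l, coding_id == c)
  expect_equal(r("L01", "C01")$distance_bp, 1.4e6)
  expect_true(r("L01", "C01")$is_cis)
  expect_equal(r("L01", "C02")$distance_bp, 6.9e6)
  expect_false(r("L01", "C02")$is_cis)
  expect_true(is.na(r("L02", "C01")$distance_bp))
  expect_false(r("L02", "C01")$is_cis)
})

test_that("screen is invariant under a joint sample permutation", {
  fx <- screen_fixture(5)
  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  shuffle <- function(m) {
    dplyr::bind_cols(m[, 1], m[, 1 + perm, drop = FALSE])
  }
  s1 <- tibble::as_tibble(all_pairs_screen(fx$linc, fx$coding))
  s2 <- tibble::as_tibble(all_pairs_screen(shuffle(fx$linc),
                                           shuffle(fx$coding)))
  expect_equal(s1$rho, s2$rho)
  expect_equal(s1$p_value, s2$p_value)
})

test_that("significant-pair count is monotone in alpha", {
  fx <- screen_fixture(6)
  n_sig <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a) {
    generics::glance(all_pairs_screen(fx$linc, fx$coding,
                                      alpha = a))$n_significant
  }, numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("screen summary counts cis and anti-correlated subsets", {
  fx <- screen_fixture(7)
  s <- all_pairs_screen(fx$linc, fx$coding)
  gl <- generics::glance(s)
  tab <- tibble::as_tibble(s)
  expect_equal(gl$n_significant, sum(tab$passes_bonferroni))
  expect_equal(gl$n_anticorrelated,
               sum(tab$passes_bonferroni & tab$rho < 0))
  expect_equal(gl$n_uncorrected, sum(tab$passes_uncorrected))
  expect_equal(gl$bonferroni_threshold, 0.05 / (20 * 50))
})
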