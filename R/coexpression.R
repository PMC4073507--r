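# all permutations of 1..n as an n! x n integer matrix, cached per n
all_permutations <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(the[[key]])) return(the[[key]])
  if (n > 9) abort("permutation enumeration limited to n <= 9",
                   class = "lincfinder_input_error")
  p <- matrix(1L, 1, 1)
  for (k in 2:max(n, 2)) {
    if (n == 1) break
    rows <- nrow(p)
    out <- matrix(0L, rows * k, k)
    for (pos in seq_len(k)) {
      block <- seq_len(rows) + (pos - 1) * rows
      if (pos > 1) out[block, seq_len(pos - 1)] <- p[, seq_len(pos - 1)]
      out[block, pos] <- k
      if (pos < k) out[block, seq(pos + 1, k)] <- p[, seq(pos, k - 1)]
    }
    p <- out
  }
  the[[key]] <- p
  p
}

#' Spearman rank correlation with exact or asymptotic p-value
#'
#' Computes Spearman's rho with average ranks for ties. The two-sided
#' p-value is either exact — the fraction of all `n!` permutations of one
#' profile whose |rho| reaches the observed |rho|, enumerated exhaustively
#' (supported for n <= 9) — or asymptotic, via the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on n-2 degrees of freedom. The
#' default (`"auto"`) uses the exact enumeration for n <= 9 and the
#' approximation above that. A constant profile has undefined rho and is
#' flagged rather than propagating NaN.
#'
#' @param x,y numeric profiles of equal length >= 3.
#' @param p_method `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @return a one-row tibble: `rho`, `p_value`, `p_method`, `undefined_rho`.
#' @examples
#' spearman_pair(1:9, c(2, 4, 6, 8, 10, 12, 14, 16, 18))
#' @export
spearman_pair <- function(x, y, p_method = c("auto", "exact", "asymptotic")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n || n < 3) {
    abort("profiles must have equal length >= 3",
          class = "lincfinder_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_,
                  p_method = "none", undefined_rho = TRUE))
  }
  if (p_method == "auto") p_method <- if (n <= 9) "exact" else "asymptotic"
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (p_method == "exact") {
    p <- exact_spearman_p(rx, ry, rho)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 0))
    p <- if (!is.finite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p_value = p, p_method = p_method, undefined_rho = FALSE)
}

# exhaustive two-sided permutation p for given rank vectors
exact_spearman_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  P <- all_permutations(n)
  ryp <- matrix(ry[P], nrow(P), n)
  s <- as.vector(ryp %*% rx)
  denom <- (n - 1) * sd(rx) * sd(ry)
  rho_perm <- (s - n * mean(rx) * mean(ry)) / denom
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

#' Bonferroni-corrected per-test threshold for the co-expression screen
#'
#' @param n_linc,n_coding numbers of lincRNA and protein-coding genes
#'   screened (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test p-value threshold `alpha / (n_linc * n_coding)`.
#' @examples
#' bonferroni_threshold(418, 10775)  # ~1.11e-8
#' @export
bonferroni_threshold <- function(n_linc, n_coding, alpha = 0.05) {
  stopifnot(n_linc >= 1, n_coding >= 1, alpha > 0, alpha < 1)
  alpha / (n_linc * n_coding)
}

#' All-pairs lincRNA / protein-coding co-expression screen
#'
#' Tests every (lincRNA, protein-coding) pair of expression profiles with
#' Spearman's rank correlation, applies the Bonferroni threshold
#' `alpha / (n_linc * n_coding)`, and annotates each pair with its genomic
#' distance (gap between locus spans, 0 when overlapping, `NA` across
#' chromosomes) and cis status (same chromosome, distance strictly below
#' `cis_window_bp`). Pairs passing the UNcorrected level `alpha` are also
#' flagged, reproducing the screen's secondary, uncorrected analysis.
#'
#' The default p-value method is the asymptotic t approximation: with nine
#' samples the smallest attainable exact-permutation p is 2/9! (about
#' 5.5e-6), so no pair can clear a genome-scale Bonferroni bar under exact
#' enumeration — only the asymptotic approximation, which collapses to 0 at
#' |rho| = 1, can. Exact p-values are available with `p_method = "exact"`;
#' the method is recorded per pair.
#'
#' @param linc_matrix,coding_matrix tibbles with `gene_id` plus one column
#'   per sample, sharing the same sample columns in the same order.
#' @param loci_positions optional tibble `gene_id`, `chrom`, `start`, `end`
#'   giving gene spans for the distance annotation.
#' @param alpha family-wise error rate (default 0.05).
#' @param cis_window_bp cis window (default 2e6, i.e. 2 Mb).
#' @param p_method `"asymptotic"` (default) or `"exact"`.
#' @param fdr also compute Benjamini-Hochberg adjusted p-values (off by
#'   default; Bonferroni remains the headline correction).
#' @return a tibble of class `coexpr_screen`, one row per pair: `linc_id`,
#'   `coding_id`, `rho`, `p_value`, `p_method`, `distance_bp`, `is_cis`,
#'   `passes_bonferroni`, `passes_uncorrected` (and `p_fdr` when
#'   `fdr = TRUE`), with the per-test threshold and summary counts as
#'   attributes (see [glance.coexpr_screen()]).
#' @export
all_pairs_screen <- function(linc_matrix, coding_matrix,
                             loci_positions = NULL, alpha = 0.05,
                             cis_window_bp = 2e6,
                             p_method = c("asymptotic", "exact"),
                             fdr = FALSE) {
  p_method <- match.arg(p_method)
  samples <- setdiff(names(linc_matrix), "gene_id")
  if (!identical(samples, setdiff(names(coding_matrix), "gene_id"))) {
    abort("matrices must share the same sample columns in the same order",
          class = "lincfinder_input_error")
  }
  n <- length(samples)
  lm <- as.matrix(linc_matrix[, samples])
  cm <- as.matrix(coding_matrix[, samples])
  rownames(lm) <- linc_matrix$gene_id
  rownames(cm) <- coding_matrix$gene_id
  sd_l <- apply(lm, 1, sd)
  sd_c <- apply(cm, 1, sd)
  rho <- suppressWarnings(cor(t(lm), t(cm), method = "spearman"))
  pairs <- tidyr::expand_grid(linc_id = linc_matrix$gene_id,
                              coding_id = coding_matrix$gene_id)
  pairs$rho <- rho[cbind(pairs$linc_id, pairs$coding_id)]
  pairs$undefined_rho <- sd_l[pairs$linc_id] == 0 | sd_c[pairs$coding_id] == 0
  pairs$rho[pairs$undefined_rho] <- NA_real_
  if (p_method == "asymptotic") {
    tstat <- pairs$rho * sqrt((n - 2) / pmax(1 - pairs$rho^2, 0))
    pairs$p_value <- ifelse(is.finite(tstat),
                            2 * pt(-abs(tstat), df = n - 2),
                            ifelse(is.na(tstat), NA_real_, 0))
  } else {
    pairs$p_value <- purrr::map2_dbl(pairs$linc_id, pairs$coding_id,
      function(li, ci) {
        if (sd_l[li] == 0 || sd_c[ci] == 0) return(NA_real_)
        rx <- rank(lm[li, ]); ry <- rank(cm[ci, ])
        exact_spearman_p(rx, ry, cor(rx, ry))
      })
  }
  pairs$p_method <- ifelse(pairs$undefined_rho, "none", p_method)
  pairs <- distance_annotation(pairs, loci_positions, cis_window_bp)
  thr <- bonferroni_threshold(nrow(linc_matrix), nrow(coding_matrix), alpha)
  pairs$passes_bonferroni <- !is.na(pairs$p_value) & pairs$p_value < thr
  pairs$passes_uncorrected <- !is.na(pairs$p_value) & pairs$p_value <= alpha
  if (fdr) pairs$p_fdr <- stats::p.adjust(pairs$p_value, method = "BH")
  pairs <- select(pairs, -"undefined_rho")
  sig <- filter(pairs, .data$passes_bonferroni)
  unc <- filter(pairs, .data$passes_uncorrected)
  structure(
    pairs,
    class = c("coexpr_screen", class(pairs)),
    threshold = thr, alpha = alpha, n_samples = n,
    summary = tibble(
      n_pairs = nrow(pairs),
      n_significant = nrow(sig),
      n_cis = sum(sig$is_cis, na.rm = TRUE),
      n_anticorrelated = sum(sig$rho < 0, na.rm = TRUE),
      n_uncorrected = nrow(unc),
      n_cis_uncorrected = sum(unc$is_cis, na.rm = TRUE),
      n_anticorrelated_uncorrected = sum(unc$rho < 0, na.rm = TRUE)
    )
  )
}

distance_annotation <- function(pairs, loci_positions, cis_window_bp) {
  if (is.null(loci_positions)) {
    pairs$distance_bp <- NA_real_
    pairs$is_cis <- NA
    return(pairs)
  }
  pos <- select(loci_positions, "gene_id", "chrom", "start", "end")
  pairs <- pairs %>%
    left_join(rename(pos, linc_chrom = "chrom", linc_start = "start",
                     linc_end = "end"),
              by = c(linc_id = "gene_id")) %>%
    left_join(rename(pos, coding_chrom = "chrom", coding_start = "start",
                     coding_end = "end"),
              by = c(coding_id = "gene_id")) %>%
    mutate(
      distance_bp = ifelse(
        .data$linc_chrom == .data$coding_chrom,
        pmax(pmax(.data$linc_start, .data$coding_start) -
               pmin(.data$linc_end, .data$coding_end), 0),
        NA_real_
      ),
      is_cis = !is.na(.data$distance_bp) &
        .data$distance_bp < cis_window_bp
    ) %>%
    select(-"linc_chrom", -"linc_start", -"linc_end",
           -"coding_chrom", -"coding_start", -"coding_end")
  pairs
}

#' Summarise a co-expression screen
#'
#' @param x a `coexpr_screen` from [all_pairs_screen()].
#' @param ... unused.
#' @return a one-row tibble of screen-level counts: total pairs, pairs
#'   passing Bonferroni, cis and anti-correlated subsets, the uncorrected
#'   analogues, and the per-test threshold.
#' @method glance coexpr_screen
#' @export
glance.coexpr_screen <- function(x, ...) {
  mutate(attr(x, "summary"),
         bonferroni_threshold = attr(x, "threshold"),
         alpha = attr(x, "alpha"))
}

#' Plot the rho distribution of a co-expression screen
#'
#' @param screen a `coexpr_screen`.
#' @return a ggplot object.
#' @export
plot_coexpression_rho <- function(screen) {
  df <- as_tibble(screen)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho,
                                   fill = .data$passes_bonferroni)) +
    ggplot2::geom_histogram(bins = 41, alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = "Bonferroni") +
    ggplot2::labs(x = "Spearman rho", y = "pairs",
                  title = "All-pairs co-expression screen") +
    ggplot2::theme_minimal()
}
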