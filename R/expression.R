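#' Normalize read counts by per-sample mapped-read totals
#'
#' Expression is quantified as the per-read fraction: the number of reads
#' assigned to a gene divided by the total number of mapped reads in that
#' sample (values are tiny, on the order of 1e-5, by design — this is the
#' stated unit, not RPKM).
#'
#' @param counts tibble with a `gene_id` column and one integer column per
#'   sample.
#' @param mapped_totals tibble with columns `sample_id` and `mapped_total`
#'   (positive), covering every sample column of `counts`.
#' @return a long tibble with columns `gene_id`, `sample_id`, `count`,
#'   `mapped_total`, `normalized`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' totals <- tibble::tibble(sample_id = "s1", mapped_total = 1000)
#' normalize_counts(counts, totals)
#' @export
normalize_counts <- function(counts, mapped_totals) {
  stopifnot("gene_id" %in% names(counts),
            all(c("sample_id", "mapped_total") %in% names(mapped_totals)))
  samples <- setdiff(names(counts), "gene_id")
  if (!setequal(samples, mapped_totals$sample_id)) {
    abort("sample columns and mapped_totals$sample_id must agree",
          class = "lincfinder_input_error")
  }
  if (any(mapped_totals$mapped_total <= 0)) {
    abort("mapped totals must be positive",
          class = "lincfinder_input_error")
  }
  counts %>%
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample_id",
                        values_to = "count") %>%
    left_join(mapped_totals, by = "sample_id") %>%
    mutate(normalized = .data$count / .data$mapped_total) %>%
    select("gene_id", "sample_id", "count", "mapped_total", "normalized")
}

#' Per-gene detection across samples
#'
#' Counts, for each gene, the number of samples in which it is detected
#' (raw count at or above `min_count`), and tallies how many genes are
#' detected in all samples and in fewer than `below_k` samples.
#'
#' @param expr long expression tibble from [normalize_counts()].
#' @param min_count detection threshold on the raw count (default 1).
#' @param below_k tally genes detected in fewer than this many samples
#'   (default 5).
#' @return a tibble `gene_id`, `n_detected` with attributes
#'   `n_all_samples`, `n_below_k` and `n_samples`.
#' @export
detection_summary <- function(expr, min_count = 1, below_k = 5) {
  n_samples <- dplyr::n_distinct(expr$sample_id)
  out <- expr %>%
    group_by(.data$gene_id) %>%
    summarise(n_detected = sum(.data$count >= min_count), .groups = "drop")
  attr(out, "n_samples") <- n_samples
  attr(out, "n_all_samples") <- sum(out$n_detected == n_samples)
  attr(out, "n_below_k") <- sum(out$n_detected < below_k)
  out
}

#' Per-gene coefficient of variation of normalized expression
#'
#' CV (%) = 100 x sample standard deviation / mean of the normalized values
#' across samples (n-1 denominator). Genes with zero mean are flagged
#' (`cv_defined = FALSE`) rather than dropped.
#'
#' @param expr long expression tibble from [normalize_counts()].
#' @return a tibble `gene_id`, `mean_normalized`, `cv_pct`, `cv_defined`.
#' @export
coefficient_of_variation <- function(expr) {
  expr %>%
    group_by(.data$gene_id) %>%
    summarise(
      mean_normalized = mean(.data$normalized),
      cv_pct = ifelse(mean(.data$normalized) > 0,
                      100 * sd(.data$normalized) / mean(.data$normalized),
                      NA_real_),
      .groups = "drop"
    ) %>%
    mutate(cv_defined = !is.na(.data$cv_pct))
}

#' Two-sample comparison of gene-level statistics
#'
#' Two-sided two-sample Student's t-test (pooled variance by default, Welch
#' by flag) between two groups of per-gene values, reporting group means and
#' standard deviations in `mean +/- sd` style. When both groups are constant
#' and identical the statistic is 0 and p = 1 by convention.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch variant (default `FALSE`).
#' @return a one-row tibble: `statistic`, `p_value`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values",
          class = "lincfinder_input_error")
  }
  base <- tibble(
    mean_a = mean(values_a), sd_a = sd(values_a), n_a = length(values_a),
    mean_b = mean(values_b), sd_b = sd(values_b), n_b = length(values_b)
  )
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(mutate(base, statistic = 0, p_value = 1, .before = 1))
  }
  tt <- t.test(values_a, values_b, var.equal = !welch)
  mutate(base, statistic = unname(tt$statistic), p_value = tt$p.value,
         .before = 1)
}

#' SNP density in regulatory windows around loci
#'
#' Places a strand-aware upstream window (5' of the transcription start
#' site, default 10 kb) and downstream window (3' of the transcript end,
#' default 1 kb) around each locus and reports SNP density in SNPs/kb.
#' Windows are truncated at position 0 and, when `chrom_lengths` is given,
#' at the chromosome end; densities use the truncated width.
#'
#' @param loci tibble with columns `locus_id`, `chrom`, `strand`,
#'   `span_start`, `span_end` (e.g. from [cluster_loci()]).
#' @param snps tibble with columns `chrom` and `pos` (0-based positions).
#' @param upstream_bp,downstream_bp window sizes (defaults 10000 and 1000).
#' @param chrom_lengths optional tibble `chrom`, `length`.
#' @return a tibble per locus: `locus_id`, `upstream_n`, `upstream_kb`,
#'   `upstream_density`, `downstream_n`, `downstream_kb`,
#'   `downstream_density`.
#' @export
snp_density <- function(loci, snps, upstream_bp = 10000, downstream_bp = 1000,
                        chrom_lengths = NULL) {
  stopifnot(all(c("locus_id", "chrom", "strand", "span_start", "span_end")
                %in% names(loci)))
  clen <- function(chrom) {
    if (is.null(chrom_lengths)) return(Inf)
    len <- chrom_lengths$length[chrom_lengths$chrom == chrom]
    if (length(len) == 0) Inf else len
  }
  purrr::map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    if (l$strand == "-") {
      up <- c(l$span_end, l$span_end + upstream_bp)
      dn <- c(l$span_start - downstream_bp, l$span_start)
    } else {
      up <- c(l$span_start - upstream_bp, l$span_start)
      dn <- c(l$span_end, l$span_end + downstream_bp)
    }
    lim <- clen(l$chrom)
    clip <- function(w) c(max(w[1], 0), min(w[2], lim))
    up <- clip(up); dn <- clip(dn)
    count_in <- function(w) {
      sum(snps$chrom == l$chrom & snps$pos >= w[1] & snps$pos < w[2])
    }
    tibble(
      locus_id = l$locus_id,
      upstream_n = count_in(up),
      upstream_kb = max(up[2] - up[1], 0) / 1000,
      downstream_n = count_in(dn),
      downstream_kb = max(dn[2] - dn[1], 0) / 1000
    ) %>%
      mutate(
        upstream_density = ifelse(.data$upstream_kb > 0,
                                  .data$upstream_n / .data$upstream_kb,
                                  NA_real_),
        downstream_density = ifelse(.data$downstream_kb > 0,
                                    .data$downstream_n / .data$downstream_kb,
                                    NA_real_)
      )
  }) %>% bind_rows()
}

# round half away from zero, matching printed-table rendering
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read-mapping summary arithmetic
#'
#' Derives the per-sample percentages and base totals of a sequencing
#' mapping summary: percent mapped and percent uniquely mapped reads (both
#' rounded half-up to 2 decimals), gigabases sequenced
#' (`n_reads x read_length / 1e9`, 2 decimals), percent of uniquely mapped
#' reads that are properly paired, and the totals across samples (read
#' pairs = total reads / 2).
#'
#' @param per_sample_counts tibble with columns `sample_id`, `n_reads`,
#'   `n_mapped`, `n_uniquely_mapped`, `n_uniquely_mapped_pairs`.
#' @param read_length_bp read length in bp (default 100).
#' @return a tibble with the input columns plus `pct_mapped`,
#'   `pct_uniquely_mapped`, `pct_uniquely_mapped_paired`, `gigabases`;
#'   attributes `total_pairs` and `total_gigabases` carry the across-sample
#'   totals.
#' @export
mapping_summary <- function(per_sample_counts, read_length_bp = 100) {
  need <- c("sample_id", "n_reads", "n_mapped", "n_uniquely_mapped",
            "n_uniquely_mapped_pairs")
  stopifnot(all(need %in% names(per_sample_counts)))
  x <- per_sample_counts
  if (any(x$n_reads <= 0)) {
    abort("n_reads must be positive", class = "lincfinder_input_error")
  }
  if (any(x$n_uniquely_mapped > x$n_mapped) || any(x$n_mapped > x$n_reads)) {
    abort("need n_uniquely_mapped <= n_mapped <= n_reads",
          class = "lincfinder_input_error")
  }
  out <- x %>% mutate(
    pct_mapped = round_half_up(100 * .data$n_mapped / .data$n_reads),
    pct_uniquely_mapped =
      round_half_up(100 * .data$n_uniquely_mapped / .data$n_reads),
    pct_uniquely_mapped_paired =
      round_half_up(100 * 2 * .data$n_uniquely_mapped_pairs /
                      .data$n_uniquely_mapped),
    gigabases = round_half_up(.data$n_reads * read_length_bp / 1e9)
  )
  attr(out, "total_pairs") <- sum(x$n_reads) / 2
  attr(out, "total_gigabases") <-
    round_half_up(sum(x$n_reads) * read_length_bp / 1e9)
  out
}

#' Plot coefficient-of-variation distributions per gene group
#'
#' Violin/box comparison of per-gene CV between gene groups (e.g. lincRNA
#' versus protein-coding).
#'
#' @param cv_by_group tibble with columns `group` and `cv_pct`.
#' @return a ggplot object.
#' @export
plot_cv_comparison <- function(cv_by_group) {
  ggplot2::ggplot(cv_by_group,
                  ggplot2::aes(x = .data$group, y = .data$cv_pct,
                               fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "coefficient of variation (%)",
                  title = "Inter-individual expression variability") +
    ggplot2::theme_minimal()
}
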