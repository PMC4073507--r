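#' Overlap lincRNA loci with QTL intervals
#'
#' An overlap is at least 1 bp of intersection between a locus span and a
#' QTL interval (half-open coordinates: end-to-start touching is no
#' overlap). QTL strand is ignored; overlapping or nested QTLs are counted
#' as distinct regions.
#'
#' @param loci tibble with `locus_id`, `chrom`, `span_start`, `span_end`
#'   (e.g. from [cluster_loci()]).
#' @param qtls tibble with `qtl_id`, `chrom`, `start`, `end`, `trait_name`,
#'   `trait_group` (groups `"meat_muscle"` / `"other"`).
#' @return a tibble of overlap events (`locus_id`, `qtl_id`, `trait_name`,
#'   `trait_group`), from which both directions of the mapping follow:
#'   attributes `per_locus` (locus_id, n_qtls) and `per_qtl` (qtl_id,
#'   n_loci) tabulate them, including zero-count entries.
#' @export
overlap_qtl <- function(loci, qtls) {
  stopifnot(all(c("locus_id", "chrom", "span_start", "span_end")
                %in% names(loci)),
            all(c("qtl_id", "chrom", "start", "end", "trait_name",
                  "trait_group") %in% names(qtls)))
  events <- if (nrow(loci) == 0 || nrow(qtls) == 0) {
    tibble(locus_id = character(), qtl_id = character(),
           trait_name = character(), trait_group = character())
  } else {
    lgr <- GenomicRanges::GRanges(loci$chrom,
      IRanges::IRanges(loci$span_start + 1L, loci$span_end))
    qgr <- GenomicRanges::GRanges(qtls$chrom,
      IRanges::IRanges(qtls$start + 1L, qtls$end))
    hits <- GenomicRanges::findOverlaps(lgr, qgr, minoverlap = 1L)
    tibble(
      locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
      qtl_id = qtls$qtl_id[S4Vectors::subjectHits(hits)],
      trait_name = qtls$trait_name[S4Vectors::subjectHits(hits)],
      trait_group = qtls$trait_group[S4Vectors::subjectHits(hits)]
    ) %>% arrange(.data$locus_id, .data$qtl_id)
  }
  per_locus <- tibble(locus_id = loci$locus_id) %>%
    left_join(dplyr::count(events, .data$locus_id, name = "n_qtls"),
              by = "locus_id") %>%
    mutate(n_qtls = tidyr::replace_na(.data$n_qtls, 0L))
  per_qtl <- tibble(qtl_id = qtls$qtl_id) %>%
    left_join(dplyr::count(events, .data$qtl_id, name = "n_loci"),
              by = "qtl_id") %>%
    mutate(n_loci = tidyr::replace_na(.data$n_loci, 0L))
  structure(events, per_locus = per_locus, per_qtl = per_qtl)
}

#' Chi-squared enrichment of locus-QTL overlaps in a trait group
#'
#' Counts locus-QTL overlap events per trait group (meat/muscle-related
#' versus other) and tests the observed split against an expectation with a
#' 1-df chi-squared goodness-of-fit test. Two expectation models are
#' offered: `"span_proportional"` (default) — expected counts proportional
#' to the total base-pair span of each group's QTLs, which accounts for the
#' genomic footprint of each group — and `"count_proportional"` — expected
#' proportional to the number of QTLs per group.
#'
#' @param overlaps overlap events from [overlap_qtl()].
#' @param qtls the QTL tibble given to [overlap_qtl()]; both groups must be
#'   represented.
#' @param expectation `"span_proportional"` or `"count_proportional"`.
#' @return an object of class `qtl_enrichment`: one-row tibble with
#'   `observed_meat_muscle`, `observed_other`, `expected_meat_muscle`,
#'   `expected_other`, `statistic`, `df`, `p_value`, `expectation`.
#' @export
chi_square_enrichment <- function(overlaps, qtls,
                                  expectation = c("span_proportional",
                                                  "count_proportional")) {
  expectation <- match.arg(expectation)
  groups <- c("meat_muscle", "other")
  if (!all(groups %in% qtls$trait_group)) {
    abort("need at least one QTL in each trait group",
          class = "lincfinder_input_error")
  }
  observed <- vapply(groups,
                     function(g) sum(overlaps$trait_group == g), numeric(1))
  weight <- switch(expectation,
    span_proportional = vapply(groups, function(g) {
      sub <- qtls[qtls$trait_group == g, ]
      sum(sub$end - sub$start)
    }, numeric(1)),
    count_proportional = vapply(groups,
      function(g) sum(qtls$trait_group == g), numeric(1))
  )
  expected <- sum(observed) * weight / sum(weight)
  if (any(expected <= 0) || sum(observed) == 0) {
    abort("expected count of zero in a group; test not valid",
          class = "lincfinder_test_error")
  }
  stat <- sum((observed - expected)^2 / expected)
  out <- tibble(
    observed_meat_muscle = observed[["meat_muscle"]],
    observed_other = observed[["other"]],
    expected_meat_muscle = expected[["meat_muscle"]],
    expected_other = expected[["other"]],
    statistic = stat,
    df = 1L,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    expectation = expectation
  )
  class(out) <- c("qtl_enrichment", class(out))
  out
}

#' @method tidy qtl_enrichment
#' @export
tidy.qtl_enrichment <- function(x, ...) as_tibble(unclass(x))

#' Default keyword map from trait names to trait groups
#'
#' A starting point for assigning QTL trait names to the meat/muscle group:
#' trait names containing any of the keywords (case-insensitive) map to
#' `"meat_muscle"`, all others to `"other"`. The map is never applied
#' silently — pass the result to your QTL table yourself.
#'
#' @param trait_names character vector of trait names.
#' @param keywords keywords marking meat-quality / muscle-related traits.
#' @return character vector of groups, same length as `trait_names`.
#' @export
assign_trait_groups <- function(trait_names,
                                keywords = c("tenderness", "marbling",
                                             "meat", "muscle", "carcass",
                                             "shear", "ribeye")) {
  pattern <- paste(keywords, collapse = "|")
  ifelse(grepl(pattern, trait_names, ignore.case = TRUE),
         "meat_muscle", "other")
}
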