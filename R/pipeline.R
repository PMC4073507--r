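#' Run the lincRNA discovery pipeline end to end
#'
#' Orchestrates the stages in order: class-code classification, candidate
#' filtering, coding-potential cascade, expression characterisation,
#' co-expression screen and QTL enrichment, logging input/output counts per
#' stage into a reproducible report. Any characterisation stage whose
#' inputs are absent from the bundle is skipped and recorded as such.
#'
#' The conservation stage supports the two threshold readings: the
#' `"negative"` rule (default) retains transcripts with a score strictly
#' below 0, and `"calibrated"` sets the threshold empirically on the
#' bundled control alignments so that `retain_noncoding_frac` of the known
#' non-coding controls are retained.
#'
#' @param bundle a simulation bundle from [simulate_linc_bundle()], or any
#'   list with the same elements read from files (`reference`, `query`,
#'   `sequences`, `training`, `alignments`, `calibration`, `counts`,
#'   `mapped_totals`, `gene_groups`, `snps`, `qtls`).
#' @param min_length,min_exons candidate filter parameters (defaults 200
#'   and 2).
#' @param conservation_rule `"negative"` (default), `"calibrated"` or
#'   `"off"`.
#' @param retain_noncoding_frac calibration target when
#'   `conservation_rule = "calibrated"` (default 0.73).
#' @param classifier `"on"` (default) or `"off"`; the model is trained on
#'   the bundled training sets with [train_coding_model()].
#' @param folds,cv_scheme classifier cross-validation parameters.
#' @param motif_db motif database for the domain filter (default
#'   [synthetic_motif_db()]); `NULL` disables the stage.
#' @param alpha,cis_window_bp co-expression screen parameters (defaults
#'   0.05 and 2 Mb).
#' @param upstream_bp,downstream_bp SNP-density windows (defaults 10 kb
#'   and 1 kb).
#' @param expectation QTL-enrichment expectation model.
#' @param seed integer seed for the model training split.
#' @return an object of class `linc_report`: a list with `counts` (named
#'   stage counts), `params` (parameter echo), `seed`, and the stage
#'   results (`class_codes`, `candidates`, `cascade`, `model`, `loci`,
#'   `expression`, `coexpression`, `enrichment`, `snp_density`).
#' @export
run_pipeline <- function(bundle,
                         min_length = 200L, min_exons = 2L,
                         conservation_rule = c("negative", "calibrated",
                                               "off"),
                         retain_noncoding_frac = 0.73,
                         classifier = c("on", "off"),
                         folds = 10, cv_scheme = "inverse",
                         motif_db = synthetic_motif_db(),
                         alpha = 0.05, cis_window_bp = 2e6,
                         upstream_bp = 10000, downstream_bp = 1000,
                         expectation = "span_proportional",
                         seed = 1L) {
  conservation_rule <- match.arg(conservation_rule)
  classifier <- match.arg(classifier)
  for (field in c("reference", "query")) {
    if (is.null(bundle[[field]])) {
      abort(paste0("pipeline config/bundle is missing '", field, "'"),
            class = "lincfinder_config_error")
    }
  }
  counts <- list()
  report <- list()

  # stage 1: classify
  cc <- assign_class_codes(bundle$query, bundle$reference)
  counts$n_query <- nrow(transcript_summary(bundle$query))
  counts$n_u <- sum(cc$primary_code == "u")
  report$class_codes <- cc

  # stage 2: candidate filter
  cand_tx <- filter_linc_candidates(bundle$query, cc,
                                    min_length = min_length,
                                    min_exons = min_exons)
  cand_ids <- unique(cand_tx$transcript_id)
  counts$n_candidates <- length(cand_ids)
  counts$n_candidate_loci <- nrow(cluster_loci(cand_tx))
  report$candidates <- cand_tx

  # stage 3: coding-potential cascade
  model <- NULL
  hex <- NULL
  cons_scores <- NULL
  cons_threshold <- NULL
  if (length(cand_ids) > 0 && !is.null(bundle$sequences)) {
    cand_seqs <- filter(bundle$sequences,
                        .data$transcript_id %in% cand_ids)
    if (classifier == "on" && !is.null(bundle$training)) {
      tr_c <- filter(bundle$training, .data$class == "coding")
      tr_n <- filter(bundle$training, .data$class == "noncoding")
      hex <- train_hexamer_table(tr_c$sequence, tr_n$sequence)
      f_c <- compute_coding_features(
        tibble(transcript_id = tr_c$set_id, sequence = tr_c$sequence), hex)
      f_n <- compute_coding_features(
        tibble(transcript_id = tr_n$set_id, sequence = tr_n$sequence), hex)
      model <- train_coding_model(f_c, f_n, folds = folds,
                                  scheme = cv_scheme, seed = seed)
      counts$classifier_cutoff <- model$cutoff
    }
    if (conservation_rule != "off" && !is.null(bundle$alignments)) {
      cons_scores <- score_alignments(bundle$alignments, cand_seqs)
      cons_threshold <- if (conservation_rule == "negative") {
        0
      } else {
        cal <- bundle$calibration
        calibrate_conservation_threshold(
          score_alignments(cal$noncoding, cal$noncoding_sequences)$score,
          score_alignments(cal$coding, cal$coding_sequences)$score,
          retain_noncoding_frac = retain_noncoding_frac
        )$threshold
      }
      counts$conservation_threshold <- cons_threshold
    }
    cascade <- coding_cascade(
      cand_seqs, model = model, hexamer_table = hex,
      conservation_scores = cons_scores,
      conservation_threshold = cons_threshold,
      motif_db = motif_db
    )
    report$model <- model
    report$cascade <- cascade
    retained_ids <- cascade$retained
  } else {
    retained_ids <- cand_ids
  }
  counts$n_retained <- length(retained_ids)
  retained_tx <- filter(bundle$query, .data$transcript_id %in% retained_ids)
  loci <- cluster_loci(retained_tx)
  counts$n_linc_loci <- nrow(loci)
  report$loci <- loci
  report$retained <- retained_ids

  # stage 4: expression characterisation
  if (!is.null(bundle$counts) && !is.null(bundle$mapped_totals)) {
    expr <- normalize_counts(bundle$counts, bundle$mapped_totals)
    det <- detection_summary(expr)
    cv <- coefficient_of_variation(expr)
    counts$n_genes_quantified <- nrow(det)
    counts$n_detected_all_samples <- attr(det, "n_all_samples")
    if (!is.null(bundle$gene_groups)) {
      cvg <- left_join(cv, bundle$gene_groups, by = "gene_id") %>%
        filter(.data$cv_defined)
      if (dplyr::n_distinct(cvg$group) == 2) {
        report$cv_comparison <- compare_groups(
          cvg$cv_pct[cvg$group == "linc"],
          cvg$cv_pct[cvg$group == "coding"]
        )
      }
    }
    report$expression <- list(normalized = expr, detection = det, cv = cv)
  }
  if (!is.null(bundle$snps) && nrow(loci) > 0) {
    report$snp_density <- snp_density(loci, bundle$snps,
                                      upstream_bp = upstream_bp,
                                      downstream_bp = downstream_bp)
  }

  # stage 5: co-expression screen
  if (!is.null(bundle$counts) && !is.null(bundle$gene_groups)) {
    expr_n <- normalize_counts(bundle$counts, bundle$mapped_totals) %>%
      select("gene_id", "sample_id", "normalized") %>%
      tidyr::pivot_wider(names_from = "sample_id",
                         values_from = "normalized")
    groups <- bundle$gene_groups
    linc_m <- filter(expr_n, .data$gene_id %in%
                       groups$gene_id[groups$group == "linc"])
    coding_m <- filter(expr_n, .data$gene_id %in%
                         groups$gene_id[groups$group == "coding"])
    if (nrow(linc_m) > 0 && nrow(coding_m) > 0) {
      screen <- all_pairs_screen(linc_m, coding_m,
                                 loci_positions = gene_positions(bundle),
                                 alpha = alpha,
                                 cis_window_bp = cis_window_bp)
      counts$n_coexpr_pairs <- nrow(screen)
      counts$n_coexpr_significant <- glance(screen)$n_significant
      report$coexpression <- screen
    }
  }

  # stage 6: QTL enrichment
  if (!is.null(bundle$qtls) && nrow(loci) > 0) {
    ov <- overlap_qtl(loci, bundle$qtls)
    counts$n_qtl_overlaps <- nrow(ov)
    report$qtl_overlaps <- ov
    if (all(c("meat_muscle", "other") %in% bundle$qtls$trait_group) &&
        nrow(ov) > 0) {
      report$enrichment <- chi_square_enrichment(ov, bundle$qtls,
                                                 expectation = expectation)
      counts$qtl_chi_squared <- report$enrichment$statistic
    }
  }

  report$counts <- counts
  report$params <- list(
    min_length = min_length, min_exons = min_exons,
    conservation_rule = conservation_rule,
    retain_noncoding_frac = retain_noncoding_frac,
    classifier = classifier, folds = folds, cv_scheme = cv_scheme,
    alpha = alpha, cis_window_bp = cis_window_bp,
    upstream_bp = upstream_bp, downstream_bp = downstream_bp,
    expectation = expectation
  )
  report$seed <- seed
  class(report) <- "linc_report"
  report
}

# genomic spans per expression gene id: lincRNA candidates map to their
# transcript span; coding expression genes have no planted position
gene_positions <- function(bundle) {
  smry <- transcript_summary(bundle$query)
  pos <- smry %>%
    select(gene_id = "transcript_id", "chrom", start = "tx_start",
           end = "tx_end")
  if (!is.null(bundle$gene_groups)) {
    coding_ids <- bundle$gene_groups$gene_id[
      bundle$gene_groups$group == "coding"]
    missing <- setdiff(coding_ids, pos$gene_id)
    if (length(missing) > 0) {
      pos <- bind_rows(pos, tibble(gene_id = missing,
                                   chrom = "chrUnplaced",
                                   start = NA_integer_,
                                   end = NA_integer_))
    }
  }
  pos
}

#' @export
print.linc_report <- function(x, ...) {
  cat("lincRNA pipeline report (seed", x$seed, ")\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %s\n", nm,
                format(x$counts[[nm]], digits = 6)))
  }
  invisible(x)
}

#' @method glance linc_report
#' @export
glance.linc_report <- function(x, ...) {
  as_tibble(x$counts)
}
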