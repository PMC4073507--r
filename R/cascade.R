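#' Run the coding-potential filter cascade
#'
#' Applies up to three independent coding-potential filters to candidate
#' transcripts and intersects them. A candidate is retained as a putative
#' lincRNA when it passes every enabled stage:
#'
#' 1. conservation: codon-conservation score strictly below
#'    `conservation_threshold`;
#' 2. classifier: coding probability from the logistic model strictly below
#'    the model's cutoff;
#' 3. domain: no known protein motif in any of the three translated frames.
#'
#' A stage is disabled by leaving its input `NULL`; with all stages disabled
#' the input is returned unchanged. Because the stages are independent
#' predicates the final retained set does not depend on their order; the
#' audit reports the count surviving each stage alone and the running
#' intersection.
#'
#' @param candidates tibble with columns `transcript_id` and `sequence`.
#' @param model a [train_coding_model()] fit, or `NULL`.
#' @param hexamer_table hexamer table used to compute classifier features
#'   (required when `model` is given).
#' @param conservation_scores tibble with columns `transcript_id` and
#'   `score`, e.g. from [codon_conservation_score()] applied per transcript,
#'   or `NULL`.
#' @param conservation_threshold numeric threshold (required when
#'   `conservation_scores` is given); see
#'   [calibrate_conservation_threshold()].
#' @param motif_db a [pwm_set()] or scanner function, or `NULL`.
#' @param n_frames frames scanned for classifier features.
#' @return an object of class `linc_cascade`: list with `retained`
#'   (character vector of transcript ids), `detail` (per-candidate tibble
#'   with per-stage pass flags) and `audit` (tibble of stage counts).
#' @export
coding_cascade <- function(candidates, model = NULL, hexamer_table = NULL,
                           conservation_scores = NULL,
                           conservation_threshold = NULL,
                           motif_db = NULL, n_frames = 3) {
  stopifnot(all(c("transcript_id", "sequence") %in% names(candidates)))
  detail <- tibble(transcript_id = candidates$transcript_id)
  n0 <- nrow(candidates)

  if (!is.null(conservation_scores)) {
    if (is.null(conservation_threshold)) {
      abort("conservation_threshold required when conservation_scores given",
            class = "lincfinder_input_error")
    }
    cs <- select(conservation_scores, "transcript_id", "score")
    detail <- detail %>%
      left_join(cs, by = "transcript_id") %>%
      mutate(pass_conservation = !is.na(.data$score) &
               .data$score < conservation_threshold) %>%
      rename(conservation_score = "score")
  } else {
    detail$pass_conservation <- TRUE
  }

  if (!is.null(model)) {
    if (is.null(hexamer_table)) {
      abort("hexamer_table required when a model is given",
            class = "lincfinder_input_error")
    }
    feats <- compute_coding_features(candidates, hexamer_table,
                                     n_frames = n_frames)
    pred <- predict(model, feats)
    detail <- detail %>%
      left_join(select(pred, "transcript_id", "coding_prob"),
                by = "transcript_id") %>%
      mutate(pass_classifier = .data$coding_prob < model$cutoff)
  } else {
    detail$pass_classifier <- TRUE
  }

  if (!is.null(motif_db)) {
    detail$pass_domain <- vapply(candidates$sequence, function(sq) {
      peps <- translate_three_frames(sq)
      !domain_filter(peps, motif_db)$has_known_motif
    }, logical(1), USE.NAMES = FALSE)
  } else {
    detail$pass_domain <- TRUE
  }

  detail$retained <- detail$pass_conservation & detail$pass_classifier &
    detail$pass_domain
  audit <- tibble(
    stage = c("input", "conservation", "classifier",
              "conservation+classifier", "domain", "retained"),
    n = c(n0,
          sum(detail$pass_conservation),
          sum(detail$pass_classifier),
          sum(detail$pass_conservation & detail$pass_classifier),
          sum(detail$pass_domain),
          sum(detail$retained))
  )
  structure(
    list(retained = detail$transcript_id[detail$retained],
         detail = detail, audit = audit),
    class = "linc_cascade"
  )
}

#' @export
print.linc_cascade <- function(x, ...) {
  cat("Coding-potential cascade:", x$audit$n[1], "candidates ->",
      length(x$retained), "retained\n")
  print(x$audit)
  invisible(x)
}

#' Tidy methods for cascade results
#'
#' @param x a `linc_cascade`.
#' @param ... unused.
#' @return `tidy()`: the per-candidate detail tibble. `glance()`: one row of
#'   stage counts.
#' @method tidy linc_cascade
#' @export
tidy.linc_cascade <- function(x, ...) x$detail

#' @rdname tidy.linc_cascade
#' @method glance linc_cascade
#' @export
glance.linc_cascade <- function(x, ...) {
  tidyr::pivot_wider(x$audit, names_from = "stage", values_from = "n",
                     names_prefix = "n_")
}

#' Plot cascade audit counts
#'
#' Bar chart of the number of candidates surviving each cascade stage.
#'
#' @param cascade a `linc_cascade`.
#' @return a ggplot object.
#' @export
plot_cascade_audit <- function(cascade) {
  audit <- mutate(cascade$audit,
                  stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(audit, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Coding-potential cascade audit") +
    ggplot2::theme_minimal()
}
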