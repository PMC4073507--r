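#' Sensitivity and specificity with the non-coding-positive convention
#'
#' Positives are non-coding sequences: TP = non-coding predicted non-coding,
#' FP = coding predicted non-coding, TN = coding predicted coding,
#' FN = non-coding predicted coding. Sensitivity = TP/(TP+FN),
#' Specificity = TN/(TN+FP).
#'
#' @param counts a data frame (or one-row tibble) with columns `TP`, `FP`,
#'   `TN`, `FN`, all non-negative.
#' @return a one-row tibble with columns `sensitivity` and `specificity`.
#' @examples
#' sensitivity_specificity(data.frame(TP = 90, FN = 10, TN = 80, FP = 20))
#' @export
sensitivity_specificity <- function(counts) {
  need <- c("TP", "FP", "TN", "FN")
  stopifnot(all(need %in% names(counts)))
  tp <- counts$TP[1]; fp <- counts$FP[1]; tn <- counts$TN[1]; fn <- counts$FN[1]
  if (any(c(tp, fp, tn, fn) < 0)) {
    abort("confusion counts must be non-negative",
          class = "lincfinder_input_error")
  }
  if (tp + fn == 0 || tn + fp == 0) {
    abort("zero denominator: need TP+FN > 0 and TN+FP > 0",
          class = "lincfinder_rate_error")
  }
  tibble(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Select a probability cutoff from score distributions
#'
#' Given coding-probability scores for known non-coding and known coding
#' sequences, picks the cutoff over all candidate thresholds (midpoints of
#' adjacent sorted unique scores) that maximises balanced accuracy
#' `(sensitivity + specificity) / 2`, where sequences scoring below the
#' cutoff are called non-coding. Ties go to the smallest cutoff. With
#' `criterion = "sens_spec_crossing"` the cutoff minimising
#' `|sensitivity - specificity|` is returned instead.
#'
#' @param scores_noncoding,scores_coding non-empty numeric vectors of scores
#'   in (0, 1).
#' @param criterion `"max_sens_plus_spec"` (default) or
#'   `"sens_spec_crossing"`.
#' @return a one-row tibble: `cutoff`, `sensitivity`, `specificity`.
#' @export
select_cutoff <- function(scores_noncoding, scores_coding,
                          criterion = c("max_sens_plus_spec",
                                        "sens_spec_crossing")) {
  criterion <- match.arg(criterion)
  if (length(scores_noncoding) == 0 || length(scores_coding) == 0) {
    abort("both score sets must be non-empty",
          class = "lincfinder_input_error")
  }
  all_scores <- sort(unique(c(scores_noncoding, scores_coding)))
  cands <- if (length(all_scores) > 1) {
    (all_scores[-1] + all_scores[-length(all_scores)]) / 2
  } else {
    all_scores
  }
  sens <- vapply(cands, function(c) mean(scores_noncoding < c), numeric(1))
  spec <- vapply(cands, function(c) mean(scores_coding >= c), numeric(1))
  obj <- switch(criterion,
    max_sens_plus_spec = (sens + spec) / 2,
    sens_spec_crossing = -abs(sens - spec)
  )
  best <- which(obj == max(obj))[1]  # candidates sorted: first = smallest
  tibble(cutoff = cands[best], sensitivity = sens[best],
         specificity = spec[best])
}

#' Train the logistic coding-potential classifier with cross-validation
#'
#' Fits a logistic regression of coding status on the four coding features
#' (`orf_length_nt`, `orf_coverage`, `fickett`, `hexamer_bias`; no feature
#' scaling) and estimates prediction accuracy by repeated data splitting.
#' The fitted probability is a coding probability; a transcript is called
#' non-coding when its probability falls below the selected cutoff.
#'
#' Two cross-validation schemes are available. The default `"inverse"` scheme
#' splits the pooled training data into `folds` parts and, in each
#' repetition, trains on ONE part and predicts the remaining parts — the
#' historically used design for this classifier, which trains on a tenth of
#' the data each round. `"standard"` is conventional k-fold CV (train on
#' k-1 parts, predict the held-out part). Per repetition the cutoff
#' maximising balanced accuracy on that repetition's predictions is applied
#' and sensitivity/specificity recorded (non-coding = positive). The final
#' model is refit on all data and the final cutoff selected on the pooled
#' held-out predictions.
#'
#' @param coding_features,noncoding_features feature tibbles from
#'   [compute_coding_features()] for the two training sets.
#' @param folds number of parts (default 10, >= 2).
#' @param scheme `"inverse"` (default) or `"standard"`.
#' @param seed integer seed; results are deterministic given the seed.
#' @return an object of class `coding_model`: a list with `fit` (the glm),
#'   `weights`, `cutoff`, `cv_metrics` (tibble with one row per repetition:
#'   `repetition`, `sensitivity`, `specificity`, `cutoff`), `scheme`,
#'   `training_seed`.
#' @export
train_coding_model <- function(coding_features, noncoding_features,
                               folds = 10, scheme = c("inverse", "standard"),
                               seed = 1L) {
  scheme <- match.arg(scheme)
  if (nrow(coding_features) == 0 || nrow(noncoding_features) == 0) {
    abort("both feature sets must be non-empty; cannot train on one class",
          class = "lincfinder_training_error")
  }
  if (folds < 2) abort("folds must be >= 2", class = "lincfinder_input_error")
  feats <- c("orf_length_nt", "orf_coverage", "fickett", "hexamer_bias")
  dat <- bind_rows(
    mutate(coding_features[, feats], is_coding = 1),
    mutate(noncoding_features[, feats], is_coding = 0)
  )
  withr::with_seed(seed, {
    part <- sample(rep_len(seq_len(folds), nrow(dat)))
  })
  fit_part <- function(train_idx) {
    suppressWarnings(glm(is_coding ~ orf_length_nt + orf_coverage + fickett +
                           hexamer_bias, data = dat[train_idx, ],
                         family = binomial()))
  }
  cv <- purrr::map(seq_len(folds), function(r) {
    if (scheme == "inverse") {
      train_idx <- which(part == r)
      test_idx <- which(part != r)
    } else {
      train_idx <- which(part != r)
      test_idx <- which(part == r)
    }
    if (length(unique(dat$is_coding[train_idx])) < 2) {
      abort("a training part contains a single class; increase its size",
            class = "lincfinder_training_error")
    }
    fit <- fit_part(train_idx)
    # cutoff chosen on the training part only; metrics on the held-out part
    p_train <- suppressWarnings(as.numeric(
      predict(fit, type = "response")))
    lab_train <- dat$is_coding[train_idx]
    cut <- select_cutoff(p_train[lab_train == 0], p_train[lab_train == 1])
    p <- suppressWarnings(as.numeric(
      predict(fit, newdata = dat[test_idx, ], type = "response")))
    lab <- dat$is_coding[test_idx]
    rates <- sensitivity_specificity(data.frame(
      TP = sum(p < cut$cutoff & lab == 0),
      FP = sum(p < cut$cutoff & lab == 1),
      TN = sum(p >= cut$cutoff & lab == 1),
      FN = sum(p >= cut$cutoff & lab == 0)
    ))
    tibble(repetition = r, sensitivity = rates$sensitivity,
           specificity = rates$specificity, cutoff = cut$cutoff,
           heldout = list(tibble(p = p, is_coding = lab)))
  }) %>% bind_rows()
  pooled <- bind_rows(cv$heldout)
  final_cut <- select_cutoff(pooled$p[pooled$is_coding == 0],
                             pooled$p[pooled$is_coding == 1])
  fit <- fit_part(seq_len(nrow(dat)))
  structure(
    list(
      fit = fit,
      weights = stats::coef(fit),
      cutoff = final_cut$cutoff,
      cv_metrics = select(cv, -"heldout"),
      scheme = scheme,
      training_seed = as.integer(seed)
    ),
    class = "coding_model"
  )
}

#' Predict coding probabilities from a trained coding model
#'
#' @param object a `coding_model`.
#' @param features a feature tibble from [compute_coding_features()].
#' @param ... unused.
#' @return `features` with added columns `coding_prob` and
#'   `predicted_noncoding` (`coding_prob < cutoff`).
#' @export
predict.coding_model <- function(object, features, ...) {
  # separable training data can leave the glm rank-deficient; predictions
  # are still well defined for the filter decision
  p <- suppressWarnings(as.numeric(
    predict(object$fit, newdata = features, type = "response")))
  mutate(features, coding_prob = p,
         predicted_noncoding = p < object$cutoff)
}

#' @export
print.coding_model <- function(x, ...) {
  cat("Logistic coding-potential model\n")
  cat("  scheme:", x$scheme, " folds:", nrow(x$cv_metrics),
      " seed:", x$training_seed, "\n")
  cat(sprintf("  cutoff: %.4f (call non-coding when coding probability < cutoff)\n",
              x$cutoff))
  cat(sprintf("  CV sensitivity %.3f, specificity %.3f (means over repetitions; non-coding = positive)\n",
              mean(x$cv_metrics$sensitivity), mean(x$cv_metrics$specificity)))
  invisible(x)
}

#' Tidy a coding model
#'
#' @param x a `coding_model`.
#' @param ... unused.
#' @return `tidy()`: one row per model term with its weight. `glance()`: a
#'   one-row summary with cutoff and mean CV metrics.
#' @method tidy coding_model
#' @export
tidy.coding_model <- function(x, ...) {
  tibble(term = names(x$weights), estimate = unname(x$weights))
}

#' @rdname tidy.coding_model
#' @method glance coding_model
#' @export
glance.coding_model <- function(x, ...) {
  tibble(
    cutoff = x$cutoff,
    mean_cv_sensitivity = mean(x$cv_metrics$sensitivity),
    mean_cv_specificity = mean(x$cv_metrics$specificity),
    folds = nrow(x$cv_metrics),
    scheme = x$scheme,
    training_seed = x$training_seed
  )
}
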