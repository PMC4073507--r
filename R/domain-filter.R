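AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build, read and write position-weight-matrix motif sets
#'
#' The built-in protein-motif scanner uses a set of amino-acid position
#' weight matrices (log-odds scores, 20 residues by motif width) with a
#' per-motif score threshold. `pwm_set()` builds one from matrices;
#' `read_motif_tsv()`/`write_motif_tsv()` round-trip the set through a plain
#' TSV (columns `motif_id`, `threshold`, `position`, then one column per
#' residue).
#'
#' @param matrices named list of numeric matrices with rownames covering the
#'   20 standard residues.
#' @param thresholds named numeric vector of per-motif score thresholds.
#' @param motif_db a `pwm_set`.
#' @param path file path.
#' @return a `pwm_set` object (named list with `matrix` and `threshold` per
#'   motif).
#' @export
pwm_set <- function(matrices, thresholds) {
  stopifnot(length(matrices) > 0 || length(thresholds) == 0,
            setequal(names(matrices), names(thresholds)))
  out <- purrr::map(names(matrices), function(id) {
    m <- matrices[[id]]
    stopifnot(all(AA_ALPHABET %in% rownames(m)))
    list(matrix = m[AA_ALPHABET, , drop = FALSE],
         threshold = unname(thresholds[[id]]))
  })
  names(out) <- names(matrices)
  structure(out, class = "pwm_set")
}

#' @rdname pwm_set
#' @export
write_motif_tsv <- function(motif_db, path) {
  rows <- purrr::map(names(motif_db), function(id) {
    m <- motif_db[[id]]$matrix
    df <- as_tibble(t(m))
    df$motif_id <- id
    df$threshold <- motif_db[[id]]$threshold
    df$position <- seq_len(ncol(m))
    select(df, "motif_id", "threshold", "position", dplyr::all_of(AA_ALPHABET))
  })
  readr::write_tsv(bind_rows(rows), path)
  invisible(path)
}

#' @rdname pwm_set
#' @export
read_motif_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(df) == 0) return(pwm_set(list(), numeric()))
  ids <- unique(df$motif_id)
  mats <- purrr::map(ids, function(id) {
    sub <- arrange(filter(df, .data$motif_id == id), .data$position)
    t(as.matrix(sub[, AA_ALPHABET]))
  })
  names(mats) <- ids
  thr <- vapply(ids, function(id) df$threshold[df$motif_id == id][1],
                numeric(1))
  names(thr) <- ids
  pwm_set(mats, thr)
}

# best PWM score over all offsets of one peptide; residues outside the
# 20-letter alphabet (X, *) score the column minimum
scan_pwm <- function(peptide, pwm) {
  w <- ncol(pwm)
  n <- nchar(peptide)
  if (n < w) return(tibble(offset = integer(), score = numeric()))
  aa <- strsplit(toupper(peptide), "")[[1]]
  row_idx <- match(aa, AA_ALPHABET)
  col_min <- apply(pwm, 2, min)
  scores <- vapply(seq_len(n - w + 1), function(o) {
    idx <- row_idx[o:(o + w - 1)]
    vals <- pwm[cbind(idx, seq_len(w))]
    vals[is.na(idx)] <- col_min[is.na(idx)]
    sum(vals)
  }, numeric(1))
  tibble(offset = seq_len(n - w + 1) - 1L, score = scores)
}

#' Protein-domain filter on translated frames
#'
#' Scans each frame's peptide against a motif database and reports whether
#' any motif scores at or above its threshold. The database is either a
#' built-in [pwm_set()] (used by the package's tests and default pipeline)
#' or an external-scanner handle: a function taking the peptide vector and
#' returning a tibble of hits with columns `motif_id`, `frame`, `score` —
#' the hook through which an HMM-profile scanner can be plugged in.
#'
#' @param peptides character vector of peptides, e.g. from
#'   [translate_three_frames()].
#' @param motif_db a `pwm_set`, or a function as described above. An empty
#'   `pwm_set` never produces a hit.
#' @return a list with `has_known_motif` (logical) and `hits` (tibble with
#'   columns `motif_id`, `frame`, `offset`, `score`).
#' @export
domain_filter <- function(peptides, motif_db) {
  empty_hits <- tibble(motif_id = character(), frame = integer(),
                       offset = integer(), score = numeric())
  if (is.function(motif_db)) {
    hits <- as_tibble(motif_db(peptides))
    return(list(has_known_motif = nrow(hits) > 0, hits = hits))
  }
  if (!inherits(motif_db, "pwm_set")) {
    abort("motif_db must be a pwm_set or a scanner function",
          class = "lincfinder_resource_error")
  }
  hits <- purrr::map(seq_along(peptides), function(f) {
    purrr::map(names(motif_db), function(id) {
      sc <- scan_pwm(peptides[f], motif_db[[id]]$matrix)
      sc <- filter(sc, .data$score >= motif_db[[id]]$threshold)
      if (nrow(sc) == 0) return(NULL)
      mutate(sc, motif_id = id, frame = f - 1L,
             .before = 1)
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (nrow(hits) == 0) hits <- empty_hits
  list(has_known_motif = nrow(hits) > 0, hits = hits)
}

#' A small synthetic amino-acid motif set
#'
#' Three synthetic position weight matrices built in code (not derived from
#' any curated motif database), each strongly favouring one fixed residue
#' word; thresholds are set so random peptides essentially never hit. Used
#' as the default built-in database for tests and examples.
#'
#' @param seed integer seed for the background noise in the matrices.
#' @return a `pwm_set` of three motifs.
#' @export
synthetic_motif_db <- function(seed = 421L) {
  words <- c(zinc_knuckle_like = "CHHCWK", helix_cap_like = "DDLLKKW",
             walker_a_like = "GKSGSGKT")
  withr::with_seed(seed, {
    mats <- purrr::map(words, function(w) {
      aa <- strsplit(w, "")[[1]]
      m <- matrix(rnorm(20 * length(aa), mean = -2, sd = 0.3),
                  nrow = 20, dimnames = list(AA_ALPHABET, NULL))
      for (j in seq_along(aa)) m[aa[j], j] <- 3
      m
    })
  })
  thr <- vapply(words, function(w) 2.5 * nchar(w), numeric(1))
  pwm_set(mats, thr)
}
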