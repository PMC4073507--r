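#' Codon-conservation score from a multi-species alignment
#'
#' A deliberately simple surrogate for phylogenetic codon-model scoring of
#' protein-coding constraint: within the reference ORF, every substituted
#' codon in each non-reference species is classified as synonymous or
#' non-synonymous under the standard genetic code, and the score is
#' `sum over species of log((syn + 1) / (nonsyn + 1))`. Positive scores
#' indicate coding-like (synonymous-biased) constraint; the score is monotone
#' increasing in the synonymous count. An alignment with no substitutions
#' scores 0.
#'
#' Alignment columns where the reference row has a gap are treated as
#' insertions and skipped; a reference gap run inside the ORF whose total
#' length is not a multiple of 3 breaks the reading frame and raises an
#' error. Species codons containing gaps or ambiguous bases are skipped.
#'
#' @param alignment a tibble with columns `species` and `seq` (equal-length
#'   gapped rows, gap character `-`); the FIRST row is the reference species
#'   carrying the ORF.
#' @param orf a one-row tibble from [find_longest_orf()] with `found = TRUE`,
#'   giving 0-based half-open offsets on the ungapped reference row
#'   (`rev_comp` ORFs are not supported for alignment scoring).
#' @return a one-row tibble: `score` (summed over species) and `per_species`
#'   (list-column tibble with `species`, `syn`, `nonsyn`, `score`).
#' @export
codon_conservation_score <- function(alignment, orf) {
  stopifnot(all(c("species", "seq") %in% names(alignment)),
            nrow(alignment) >= 1)
  if (!isTRUE(orf$found)) {
    abort("ORF not found; nothing to score",
          class = "lincfinder_input_error")
  }
  if (isTRUE(orf$rev_comp)) {
    abort("reverse-complement ORFs are not supported for alignment scoring",
          class = "lincfinder_input_error")
  }
  rows <- toupper(alignment$seq)
  if (length(unique(nchar(rows))) != 1) {
    abort("alignment rows must have equal length",
          class = "lincfinder_alignment_error")
  }
  ref <- strsplit(rows[1], "")[[1]]
  nongap <- which(ref != "-")
  if (orf$end > length(nongap)) {
    abort("reference row does not cover the ORF",
          class = "lincfinder_alignment_error")
  }
  orf_cols <- nongap[(orf$start + 1):orf$end]  # alignment columns of ORF nt
  # reference gaps strictly inside the ORF must preserve frame
  inner <- seq(min(orf_cols), max(orf_cols))
  n_gap <- sum(ref[inner] == "-")
  if (n_gap %% 3 != 0) {
    abort("frame-breaking gap in the reference ORF",
          class = "lincfinder_alignment_error")
  }
  codon_cols <- split(orf_cols, rep(seq_len(length(orf_cols) / 3), each = 3))
  code <- Biostrings::GENETIC_CODE
  per <- purrr::map(seq_len(nrow(alignment))[-1], function(i) {
    sp <- strsplit(rows[i], "")[[1]]
    syn <- 0L; nonsyn <- 0L
    for (cols in codon_cols) {
      rc <- paste(ref[cols], collapse = "")
      sc <- paste(sp[cols], collapse = "")
      if (grepl("[^ACGT]", sc) || grepl("[^ACGT]", rc)) next
      if (sc == rc) next
      if (identical(code[[rc]], code[[sc]])) syn <- syn + 1L
      else nonsyn <- nonsyn + 1L
    }
    tibble(species = alignment$species[i], syn = syn, nonsyn = nonsyn,
           score = log((syn + 1) / (nonsyn + 1)))
  }) %>% bind_rows()
  if (nrow(per) == 0) {
    per <- tibble(species = character(), syn = integer(),
                  nonsyn = integer(), score = numeric())
  }
  tibble(score = sum(per$score), per_species = list(per))
}

#' Calibrate the conservation-score threshold empirically
#'
#' Transcripts are retained as non-coding when their conservation score falls
#' BELOW the threshold (coding-like scores are high). The threshold is set
#' from a control set of known non-coding scores as the smallest candidate
#' value retaining at least `retain_noncoding_frac` of them — i.e. the
#' threshold that removes as many coding transcripts as possible while
#' honouring the required non-coding retention. The achieved coding-removal
#' fraction is reported from a coding control set.
#'
#' @param scores_known_noncoding,scores_coding_controls non-empty numeric
#'   score vectors.
#' @param retain_noncoding_frac required retained fraction of the non-coding
#'   controls, in (0, 1] (default 0.73).
#' @return a one-row tibble: `threshold`, `noncoding_retained_frac`,
#'   `coding_removed_frac`.
#' @export
calibrate_conservation_threshold <- function(scores_known_noncoding,
                                             scores_coding_controls,
                                             retain_noncoding_frac = 0.73) {
  if (length(scores_known_noncoding) == 0 ||
      length(scores_coding_controls) == 0) {
    abort("both score sets must be non-empty",
          class = "lincfinder_input_error")
  }
  if (retain_noncoding_frac <= 0 || retain_noncoding_frac > 1) {
    abort("retain_noncoding_frac must be in (0, 1]",
          class = "lincfinder_input_error")
  }
  nc <- scores_known_noncoding
  cands <- c(sort(unique(nc)), max(nc) + 1)
  retained <- vapply(cands, function(t) mean(nc < t), numeric(1))
  thr <- cands[match(TRUE, retained >= retain_noncoding_frac)]
  tibble(
    threshold = thr,
    noncoding_retained_frac = mean(nc < thr),
    coding_removed_frac = mean(scores_coding_controls >= thr)
  )
}

#' Write and read multi-species alignments as MAF
#'
#' Minimal MAF (multiple alignment format) I/O for transcript-anchored
#' alignment blocks: one `a` line per block followed by `s` lines named
#' `species.transcript_id`. `read_maf()` returns a named list of alignment
#' tibbles (columns `species`, `seq`), keyed by the reference row's
#' transcript id; `write_maf()` accepts such a list.
#'
#' @param alignments named list of alignment tibbles.
#' @param path file path.
#' @return `read_maf()`: named list of tibbles. `write_maf()`: `path`,
#'   invisibly.
#' @export
write_maf <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (tx in names(alignments)) {
    aln <- alignments[[tx]]
    writeLines("", con)
    writeLines("a score=0.000000", con)
    width <- max(nchar(paste0(aln$species, ".", tx)))
    for (i in seq_len(nrow(aln))) {
      seq <- aln$seq[i]
      src <- formatC(paste0(aln$species[i], ".", tx), width = width,
                     flag = "-")
      len <- nchar(gsub("-", "", seq))
      writeLines(sprintf("s %s 0 %d + %d %s", src, len, len, seq), con)
    }
  }
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  flush_block <- function(cur, out) {
    if (is.null(cur) || nrow(cur) == 0) return(out)
    out[[cur$tx[1]]] <- tibble(species = cur$species, seq = cur$seq)
    out
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      out <- flush_block(cur, out)
      cur <- tibble(species = character(), tx = character(),
                    seq = character())
    } else if (startsWith(ln, "s")) {
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      src <- strsplit(parts[2], ".", fixed = TRUE)[[1]]
      cur <- bind_rows(cur, tibble(
        species = src[1],
        tx = paste(src[-1], collapse = "."),
        seq = parts[7]
      ))
    }
  }
  flush_block(cur, out)
}
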