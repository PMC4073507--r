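#' Find the longest open reading frame in a transcript sequence
#'
#' Scans the three forward reading frames (optionally also the three reverse-
#' complement frames, for transcripts assembled from non-directional
#' libraries) for the longest complete ORF: an `ATG` followed by in-frame
#' codons up to and including a stop codon (`TAA`, `TAG`, `TGA`). Ties are
#' broken by smaller start offset, then smaller frame; forward frames are
#' scanned before reverse frames.
#'
#' @param sequence a single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive), length >= 3.
#' @param n_frames 3 (forward frames only, default) or 6 (both strands).
#' @return a one-row tibble: `found`, `start`, `end` (0-based half-open
#'   offsets within the scanned strand's sequence, stop codon included),
#'   `frame` (0, 1 or 2), `length_nt`, `rev_comp` (`TRUE` when the ORF lies
#'   on the reverse complement). When no complete ORF exists, `found = FALSE`
#'   and `length_nt = 0`.
#' @examples
#' find_longest_orf("ATGAAATAG")
#' @export
find_longest_orf <- function(sequence, n_frames = 3) {
  check_nt(sequence)
  if (!n_frames %in% c(3, 6)) {
    abort("n_frames must be 3 or 6", class = "lincfinder_input_error")
  }
  seqs <- toupper(sequence)
  strands <- list(list(seq = seqs, rc = FALSE))
  if (n_frames == 6) {
    strands <- c(strands, list(list(seq = revcomp(seqs), rc = TRUE)))
  }
  best <- NULL
  for (st in strands) {
    for (frame in 0:2) {
      orf <- longest_orf_in_frame(st$seq, frame)
      if (is.null(orf)) next
      better <- is.null(best) ||
        orf$length > best$length ||
        (orf$length == best$length && !st$rc && best$rc) ||
        (orf$length == best$length && st$rc == best$rc &&
           orf$start < best$start) ||
        (orf$length == best$length && st$rc == best$rc &&
           orf$start == best$start && frame < best$frame)
      if (better) {
        best <- list(start = orf$start, end = orf$end, frame = frame,
                     length = orf$length, rc = st$rc)
      }
    }
  }
  if (is.null(best)) {
    return(tibble(found = FALSE, start = NA_integer_, end = NA_integer_,
                  frame = NA_integer_, length_nt = 0L, rev_comp = FALSE))
  }
  tibble(found = TRUE, start = best$start, end = best$end,
         frame = best$frame, length_nt = best$length, rev_comp = best$rc)
}

# longest complete ATG..stop ORF in one frame of an uppercase sequence;
# returns NULL or list(start, end, length) with 0-based half-open offsets
longest_orf_in_frame <- function(seq, frame) {
  n <- nchar(seq)
  starts <- seq.int(frame + 1, n, by = 3)
  starts <- starts[starts + 2 <= n]
  if (length(starts) == 0) return(NULL)
  codons <- substring(seq, starts, starts + 2)
  is_start <- codons == "ATG"
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  best <- NULL
  open <- NA_integer_  # codon index of earliest ATG since last stop
  for (k in seq_along(codons)) {
    if (is.na(open) && is_start[k]) open <- k
    if (is_stop[k] && !is.na(open)) {
      len <- (k - open + 1L) * 3L
      if (is.null(best) || len > best$length) {
        best <- list(start = starts[open] - 1L,
                     end = starts[k] + 2L,
                     length = len)
      }
      open <- NA_integer_
    }
  }
  best
}

check_nt <- function(sequence) {
  if (length(sequence) != 1 || !is.character(sequence)) {
    abort("sequence must be a single string", class = "lincfinder_input_error")
  }
  if (grepl("[^ACGTNacgtn]", sequence)) {
    abort("sequence contains characters outside A/C/G/T/N",
          class = "lincfinder_input_error")
  }
  invisible(sequence)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Fickett TESTCODE lookup tables: probability that a sequence with the given
# position/content parameter is coding, binned from the highest threshold
# down, plus the per-base weights.
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_POSITION_BREAKS <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
FICKETT_CONTENT_BREAKS <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                            0.17, 0)

#' Fickett (TESTCODE) coding-potential score
#'
#' Computes the classical position/composition statistic: for each base the
#' positional asymmetry across the three codon positions
#' (`max(count) / (min(count) + 1)`) and the overall base content are mapped
#' through the published lookup tables to coding probabilities, which are
#' combined with the published weights. Higher scores indicate coding-like
#' periodicity and composition. The score is case-insensitive and is not, in
#' general, invariant under reverse complementation.
#'
#' @param sequence a single nucleotide string, length >= 6.
#' @return a single numeric score.
#' @export
fickett_score <- function(sequence) {
  check_nt(sequence)
  if (nchar(sequence) < 6) {
    abort("sequence must be at least 6 nt for a Fickett score",
          class = "lincfinder_input_error")
  }
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  pos <- (seq_along(chars) - 1) %% 3
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- vapply(0:2, function(p) sum(chars == b & pos == p), numeric(1))
    pos_value <- max(counts) / (min(counts) + 1)
    content <- sum(chars == b) / length(chars)
    pi <- match(TRUE, pos_value >= FICKETT_POSITION_BREAKS)
    ci <- match(TRUE, content >= FICKETT_CONTENT_BREAKS)
    score <- score +
      FICKETT_POSITION_PROB[[b]][pi] * FICKETT_POSITION_WEIGHT[[b]] +
      FICKETT_CONTENT_PROB[[b]][ci] * FICKETT_CONTENT_WEIGHT[[b]]
  }
  score
}

all_hexamers <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b6 = bases, b5 = bases, b4 = bases, b3 = bases,
                   b2 = bases, b1 = bases, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)
}

#' Hexamer-usage log-ratio table and per-sequence bias
#'
#' `train_hexamer_table()` counts overlapping hexamers (step 1) in a coding
#' and a non-coding training set and returns, for each of the 4096 hexamers,
#' `log(f_coding / f_noncoding)` where each frequency carries a pseudocount:
#' `f = (count + pseudocount) / (total + pseudocount * 4096)`.
#' `hexamer_bias()` scores a sequence as the mean table entry over its
#' hexamers; positive values indicate coding-like composition.
#'
#' @param coding_seqs,noncoding_seqs non-empty character vectors of nucleotide
#'   sequences.
#' @param pseudocount pseudocount added per hexamer (default 1).
#' @param sequence a single nucleotide string.
#' @param table a hexamer table from `train_hexamer_table()`.
#' @return `train_hexamer_table()`: a named numeric vector of length 4096.
#'   `hexamer_bias()`: a single numeric value (0 for sequences shorter than
#'   6 nt or without any unambiguous hexamer).
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0 || length(noncoding_seqs) == 0) {
    abort("both training sets must be non-empty",
          class = "lincfinder_input_error")
  }
  hx <- all_hexamers()
  count6 <- function(seqs) {
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(toupper(seqs)), width = 6, step = 1
    )
    colSums(m)[hx]
  }
  cc <- count6(coding_seqs)
  nc <- count6(noncoding_seqs)
  fc <- (cc + pseudocount) / (sum(cc) + pseudocount * length(hx))
  fn <- (nc + pseudocount) / (sum(nc) + pseudocount * length(hx))
  out <- log(fc / fn)
  names(out) <- hx
  out
}

#' @rdname train_hexamer_table
#' @export
hexamer_bias <- function(sequence, table) {
  check_nt(sequence)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 6) return(0)
  kmers <- substring(s, 1:(n - 5), 6:n)
  vals <- table[kmers]
  vals <- vals[!is.na(vals)]  # hexamers containing N are skipped
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Translate a transcript in the three forward frames
#'
#' Standard-genetic-code translation of frames 0, 1 and 2; stop codons are
#' rendered as `*`, ambiguous codons as `X`, and trailing partial codons are
#' dropped (frames with fewer than 3 remaining nucleotides yield an empty
#' peptide).
#'
#' @param sequence a single nucleotide string, length >= 3.
#' @return a character vector of three peptides, named `frame0`..`frame2`.
#' @examples
#' translate_three_frames("ATGGCC")
#' @export
translate_three_frames <- function(sequence) {
  check_nt(sequence)
  s <- toupper(sequence)
  n <- nchar(s)
  peps <- vapply(0:2, function(frame) {
    len <- ((n - frame) %/% 3) * 3
    if (len < 3) return("")
    sub <- substr(s, frame + 1, frame + len)
    as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "solve",
      no.init.codon = TRUE
    ))
  }, character(1))
  names(peps) <- paste0("frame", 0:2)
  peps
}

#' Compute the coding-feature vector for transcript sequences
#'
#' For each sequence, the longest-ORF length and coverage (ORF length over
#' transcript length), the Fickett score and the hexamer-usage bias — the
#' feature set of the logistic coding-potential classifier.
#'
#' @param sequences a tibble with columns `transcript_id` and `sequence`.
#' @param hexamer_table table from [train_hexamer_table()].
#' @param n_frames passed to [find_longest_orf()].
#' @return a tibble with columns `transcript_id`, `orf_length_nt`,
#'   `orf_coverage`, `fickett`, `hexamer_bias`.
#' @export
compute_coding_features <- function(sequences, hexamer_table, n_frames = 3) {
  stopifnot(all(c("transcript_id", "sequence") %in% names(sequences)))
  purrr::map2(sequences$transcript_id, sequences$sequence, function(id, sq) {
    orf <- find_longest_orf(sq, n_frames = n_frames)
    tibble(
      transcript_id = id,
      orf_length_nt = orf$length_nt,
      orf_coverage = orf$length_nt / nchar(sq),
      fickett = fickett_score(sq),
      hexamer_bias = hexamer_bias(sq, hexamer_table)
    )
  }) %>% bind_rows()
}
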