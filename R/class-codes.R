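#' Classify assembled transcripts against a reference annotation
#'
#' Assigns Cuffcompare-style class codes describing each query transcript's
#' relationship to a reference annotation. The codes, in precedence order,
#' are:
#'
#' * `=` complete match of the intron chain of a reference transcript
#'   (single-exon queries match single-exon references they overlap);
#' * `c` contained in a reference transcript: every query exon lies within a
#'   reference exon and the query introns form a consecutive run of the
#'   reference intron chain;
#' * `j` potentially novel isoform: at least one shared intron boundary
#'   (splice junction) without a full intron-chain match;
#' * `e` single-exon query overlapping a reference exon and at least 10 bp of
#'   a reference intron (possible pre-mRNA fragment);
#' * `o` generic same-strand exonic overlap not matching any of the above;
#' * `i` single-exon query falling entirely within a reference intron;
#' * `x` exonic overlap with a reference transcript on the opposite strand;
#' * `s` a query intron overlaps a reference intron on the opposite strand;
#' * `p` possible polymerase run-on fragment: no overlap, same strand, within
#'   2 kb of a reference transcript span;
#' * `u` unknown intergenic transcript (none of the above).
#'
#' All codes a query earns against any reference transcript are retained in
#' `codes`; `primary_code` is the highest-precedence one. Queries earning more
#' than one code are flagged `multi_classified` (the tracking-file `.`
#' category). Strands are compatible when equal or when either is `"."`;
#' opposite-strand codes require two known, unequal strands.
#'
#' @param query,reference exon-level transcript tibbles
#'   (see [validate_transcripts()]). `reference` may have zero rows.
#' @param run_on_bp maximum gap (bp) to a reference span for code `p`
#'   (default 2000).
#' @return a tibble with one row per query transcript: `transcript_id`,
#'   `codes` (comma-separated), `primary_code`, `matched_reference_id`
#'   (`NA` for codes `u` and `p`), `multi_classified`.
#' @examples
#' ref <- tibble::tibble(transcript_id = "r1", gene_id = "rg1", chrom = "chr1",
#'                       start = c(0, 500), end = c(100, 600), strand = "+")
#' qry <- tibble::tibble(transcript_id = "q1", gene_id = "qg1", chrom = "chr1",
#'                       start = c(10, 500), end = c(100, 580), strand = "+")
#' assign_class_codes(qry, ref)
#' @export
assign_class_codes <- function(query, reference, run_on_bp = 2000L) {
  qs <- transcript_summary(query)
  rs <- transcript_summary(reference)
  if (nrow(qs) == 0) {
    return(tibble(transcript_id = character(), codes = character(),
                  primary_code = character(),
                  matched_reference_id = character(),
                  multi_classified = logical()))
  }
  rs <- arrange(rs, .data$transcript_id)
  ref_by_chrom <- split(seq_len(nrow(rs)), rs$chrom)

  res <- purrr::map(seq_len(nrow(qs)), function(i) {
    q <- qs[i, ]
    codes <- character()
    match_id <- rep(NA_character_, 10)
    names(match_id) <- CLASS_CODE_ORDER
    idx <- ref_by_chrom[[q$chrom]]
    for (j in idx) {
      r <- rs[j, ]
      got <- codes_vs_reference(q, r, run_on_bp)
      for (cd in got) {
        codes <- union(codes, cd)
        if (is.na(match_id[[cd]])) match_id[[cd]] <- r$transcript_id
      }
    }
    if (length(codes) == 0) codes <- "u"
    primary <- CLASS_CODE_ORDER[match(TRUE, CLASS_CODE_ORDER %in% codes)]
    n_codes <- length(codes)
    tibble(
      transcript_id = q$transcript_id,
      codes = paste(CLASS_CODE_ORDER[CLASS_CODE_ORDER %in% codes],
                    collapse = ","),
      primary_code = primary,
      matched_reference_id = if (primary %in% c("u", "p")) NA_character_
                             else match_id[[primary]],
      multi_classified = n_codes > 1
    )
  })
  bind_rows(res)
}

CLASS_CODE_ORDER <- c("=", "c", "j", "e", "o", "i", "x", "s", "p", "u")

strands_compatible <- function(a, b) a == b || a == "." || b == "."
strands_opposite <- function(a, b) a %in% c("+", "-") && b %in% c("+", "-") && a != b

# all class codes one query earns against one reference transcript;
# q and r are single rows of transcript_summary()
codes_vs_reference <- function(q, r, run_on_bp) {
  qes <- q$exon_starts[[1]]; qee <- q$exon_ends[[1]]
  res_ <- r$exon_starts[[1]]; ree <- r$exon_ends[[1]]
  qis <- q$intron_starts[[1]]; qie <- q$intron_ends[[1]]
  ris <- r$intron_starts[[1]]; rie <- r$intron_ends[[1]]
  compat <- strands_compatible(q$strand, r$strand)
  opp <- strands_opposite(q$strand, r$strand)
  exon_ov <- exonic_overlap_bp(qes, qee, res_, ree)
  out <- character()

  if (compat && exon_ov >= 1 &&
      length(qis) == length(ris) &&
      all(qis == ris) && all(qie == rie)) {
    out <- c(out, "=")
  }
  if (compat && !("=" %in% out) && contained_in_reference(qes, qee, qis, qie,
                                                          res_, ree, ris, rie)) {
    out <- c(out, "c")
  }
  if (compat && length(qis) > 0 && !("=" %in% out) &&
      (length(intersect(qis, ris)) > 0 || length(intersect(qie, rie)) > 0)) {
    out <- c(out, "j")
  }
  if (compat && q$n_exons == 1 && exon_ov >= 1 && length(ris) > 0) {
    intron_ov <- pmin(qee[1], rie) - pmax(qes[1], ris)
    if (any(intron_ov >= 10)) out <- c(out, "e")
  }
  # generic exonic overlap only when no more specific same-strand code matched
  if (compat && exon_ov >= 1 && !any(c("=", "c", "j", "e") %in% out)) {
    out <- c(out, "o")
  }
  if (compat && q$n_exons == 1 && length(ris) > 0 &&
      any(qes[1] >= ris & qee[1] <= rie)) {
    out <- c(out, "i")
  }
  if (opp && exon_ov >= 1) out <- c(out, "x")
  if (opp && length(qis) > 0 && length(ris) > 0) {
    ov <- 0L
    for (k in seq_along(qis)) {
      ov <- ov + sum(pmax(pmin(qie[k], rie) - pmax(qis[k], ris), 0L))
    }
    if (ov >= 1) out <- c(out, "s")
  }
  span_gap <- max(q$tx_start, r$tx_start) - min(q$tx_end, r$tx_end)
  if (compat && exon_ov == 0 && span_gap >= 0 && span_gap <= run_on_bp) {
    out <- c(out, "p")
  }
  out
}

# query exon chain contained in the reference: every query exon inside a
# reference exon and query introns a consecutive run of the reference chain
contained_in_reference <- function(qes, qee, qis, qie, res_, ree, ris, rie) {
  for (i in seq_along(qes)) {
    if (!any(qes[i] >= res_ & qee[i] <= ree)) return(FALSE)
  }
  if (length(qis) == 0) return(TRUE)
  if (length(ris) < length(qis)) return(FALSE)
  first <- which(ris == qis[1] & rie == qie[1])
  if (length(first) != 1) return(FALSE)
  if (first + length(qis) - 1 > length(ris)) return(FALSE)
  run <- seq(first, first + length(qis) - 1)
  all(ris[run] == qis) && all(rie[run] == qie)
}

#' Filter intergenic transcripts to lincRNA candidates
#'
#' Keeps the classified transcripts whose primary class code is `u` (unknown
#' intergenic), with at least `min_exons` exons and a spliced length strictly
#' greater than `min_length` nucleotides. Input order is preserved and the
#' operation is idempotent.
#'
#' @param transcripts exon-level transcript tibble.
#' @param class_codes result of [assign_class_codes()] for the same
#'   transcripts.
#' @param min_length minimum spliced length in nt, exclusive (default 200).
#' @param min_exons minimum exon count, inclusive (default 2).
#' @return the exon-level tibble restricted to surviving transcripts.
#' @export
filter_linc_candidates <- function(transcripts, class_codes,
                                   min_length = 200L, min_exons = 2L) {
  smry <- transcript_summary(transcripts)
  keep <- smry %>%
    left_join(select(class_codes, "transcript_id", "primary_code"),
              by = "transcript_id") %>%
    filter(.data$primary_code == "u",
           .data$n_exons >= min_exons,
           .data$spliced_length > min_length) %>%
    pull("transcript_id")
  filter(transcripts, .data$transcript_id %in% keep)
}

#' Cluster transcripts into loci by exonic overlap
#'
#' Transcripts sharing at least 1 bp of exonic overlap on the same chromosome
#' and strand are transitively merged into a locus (connected components of
#' the pairwise exonic-overlap graph). Locus ids are `XLOC_`-style and
#' deterministic given the input: loci are numbered by chromosome, strand and
#' span start.
#'
#' @param transcripts exon-level transcript tibble.
#' @return a tibble with one row per locus: `locus_id`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `n_transcripts` and the list-column
#'   `transcript_ids`.
#' @export
cluster_loci <- function(transcripts) {
  smry <- transcript_summary(transcripts)
  if (nrow(smry) == 0) {
    return(tibble(locus_id = character(), chrom = character(),
                  strand = character(), span_start = integer(),
                  span_end = integer(), n_transcripts = integer(),
                  transcript_ids = list()))
  }
  smry <- arrange(smry, .data$chrom, .data$strand, .data$tx_start,
                  .data$transcript_id)
  n <- nrow(smry)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  groups <- split(seq_len(n), paste(smry$chrom, smry$strand))
  for (idx in groups) {
    if (length(idx) < 2) next
    # exon-level overlap within the chrom/strand group
    ex <- smry[idx, ] %>%
      select("transcript_id", "exon_starts", "exon_ends") %>%
      mutate(row = idx) %>%
      tidyr::unnest(c("exon_starts", "exon_ends"))
    ir <- IRanges::IRanges(start = ex$exon_starts + 1L, end = ex$exon_ends)
    hits <- IRanges::findOverlaps(ir, minoverlap = 1L,
                                  drop.self = TRUE, drop.redundant = TRUE)
    a <- ex$row[S4Vectors::queryHits(hits)]
    b <- ex$row[S4Vectors::subjectHits(hits)]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  smry$component <- comp
  loci <- smry %>%
    group_by(.data$component) %>%
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      span_start = min(.data$tx_start), span_end = max(.data$tx_end),
      n_transcripts = dplyr::n(),
      transcript_ids = list(sort(.data$transcript_id)),
      .groups = "drop"
    ) %>%
    arrange(.data$chrom, .data$strand, .data$span_start, .data$span_end) %>%
    mutate(locus_id = sprintf("XLOC_%06d", row_number())) %>%
    select("locus_id", "chrom", "strand", "span_start", "span_end",
           "n_transcripts", "transcript_ids")
  loci
}

#' Write class-code assignments as TSV
#'
#' Mirrors Cuffcompare tracking semantics: one row per query transcript with
#' its full code set, primary code and matched reference transcript.
#'
#' @param class_codes result of [assign_class_codes()].
#' @param path output file path.
#' @export
write_class_codes_tsv <- function(class_codes, path) {
  readr::write_tsv(class_codes, path)
  invisible(path)
}
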