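#' Exon-level transcript tables
#'
#' Throughout lincfinder a set of transcript models is a tidy tibble with one
#' row per exon and columns `transcript_id`, `gene_id`, `chrom`, `start`,
#' `end`, `strand`. Coordinates are 0-based, half-open (`start` inclusive,
#' `end` exclusive); strand is one of `"+"`, `"-"`, `"."`. Within a transcript
#' exons must be sorted by `start`, pairwise disjoint and on a single
#' chromosome and strand.
#'
#' `validate_transcripts()` checks these invariants and returns its input
#' invisibly; `transcript_summary()` collapses the exon table to one row per
#' transcript with its span, exon count, spliced length and intron chain.
#'
#' @param transcripts exon-level transcript tibble as described above.
#' @return `transcript_summary()` returns a tibble with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `n_exons`, `spliced_length`, and list-columns `exon_starts`,
#'   `exon_ends`, `intron_starts`, `intron_ends`.
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = c(100, 300), end = c(200, 400), strand = "+"
#' )
#' transcript_summary(tx)
#' @export
validate_transcripts <- function(transcripts) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(transcripts))
  if (length(missing) > 0) {
    abort(paste0("transcript table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lincfinder_structure_error")
  }
  if (nrow(transcripts) == 0) return(invisible(transcripts))
  if (any(!transcripts$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'",
          class = "lincfinder_structure_error")
  }
  if (any(transcripts$start < 0) || any(transcripts$end <= transcripts$start)) {
    abort("exon coordinates must satisfy 0 <= start < end",
          class = "lincfinder_structure_error")
  }
  bad <- transcripts %>%
    group_by(.data$transcript_id) %>%
    summarise(
      one_place = dplyr::n_distinct(.data$chrom) == 1 &&
        dplyr::n_distinct(.data$strand) == 1,
      sorted_disjoint = all(diff(order(.data$start)) > 0) &&
        all(.data$start[order(.data$start)][-1] >=
              .data$end[order(.data$start)][-dplyr::n()]),
      .groups = "drop"
    ) %>%
    filter(!.data$one_place | !.data$sorted_disjoint)
  if (nrow(bad) > 0) {
    abort(paste0("malformed exon structure for transcript(s): ",
                 paste(head(bad$transcript_id, 5), collapse = ", ")),
          class = "lincfinder_structure_error")
  }
  invisible(transcripts)
}

#' @rdname validate_transcripts
#' @export
transcript_summary <- function(transcripts) {
  validate_transcripts(transcripts)
  if (nrow(transcripts) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      tx_start = integer(), tx_end = integer(),
      n_exons = integer(), spliced_length = integer(),
      exon_starts = list(), exon_ends = list(),
      intron_starts = list(), intron_ends = list()
    ))
  }
  transcripts %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      n_exons = dplyr::n(),
      spliced_length = sum(.data$end - .data$start),
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      # introns are the gaps between consecutive exons
      intron_starts = list(if (dplyr::n() > 1) .data$end[-dplyr::n()] else integer()),
      intron_ends = list(if (dplyr::n() > 1) .data$start[-1] else integer()),
      .groups = "drop"
    )
}

# total exonic overlap (bp) between two exon chains given as start/end vectors
exonic_overlap_bp <- function(s1, e1, s2, e2) {
  if (length(s1) == 0 || length(s2) == 0) return(0L)
  total <- 0L
  for (i in seq_along(s1)) {
    ov <- pmin(e1[i], e2) - pmax(s1[i], s2)
    total <- total + sum(pmax(ov, 0L))
  }
  as.integer(total)
}

#' Read and write transcript models as GTF
#'
#' Thin wrappers around [rtracklayer::import()] / [rtracklayer::export()] that
#' convert between GTF's 1-based inclusive coordinates and the package's
#' 0-based half-open exon tables. Only `exon` features are read; `gene_id` and
#' `transcript_id` attributes are mandatory.
#'
#' @param path file path of a GTF file.
#' @param transcripts exon-level transcript tibble (see
#'   [validate_transcripts()]).
#' @return `read_transcripts_gtf()` returns an exon-level tibble;
#'   `write_transcripts_gtf()` returns `path` invisibly.
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  if (is.null(gr$transcript_id) || is.null(gr$gene_id) ||
      anyNA(gr$transcript_id) || anyNA(gr$gene_id)) {
    abort("GTF exons must carry gene_id and transcript_id attributes",
          class = "lincfinder_structure_error")
  }
  out <- tibble(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    mutate(strand = ifelse(.data$strand == "*", ".", .data$strand)) %>%
    arrange(.data$transcript_id, .data$start)
  validate_transcripts(out)
  out
}

#' @rdname read_transcripts_gtf
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  validate_transcripts(transcripts)
  tx <- arrange(transcripts, .data$transcript_id, .data$start)
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = ifelse(tx$strand == ".", "*", tx$strand)
  )
  gr$type <- "exon"
  gr$source <- "lincfinder"
  gr$gene_id <- tx$gene_id
  gr$transcript_id <- tx$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
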