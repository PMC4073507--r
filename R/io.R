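#' Read pipeline input tables
#'
#' Plain-text readers for the remaining pipeline inputs: an HTSeq-count
#' style counts TSV (`gene_id` column plus one column per sample), a
#' mapped-totals TSV (`sample_id`, `mapped_total`), a 3-column SNP BED
#' (chrom, 0-based start, end), a QTL TSV (`qtl_id`, `chrom`, `start`,
#' `end`, `trait_name`, `trait_group`) and a transcript FASTA.
#'
#' @param path file path.
#' @return a tibble (`read_sequences_fasta()` returns columns
#'   `transcript_id`, `sequence`).
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_counts_tsv
#' @export
read_mapped_totals_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c",
                                          mapped_total = "d"))
}

#' @rdname read_counts_tsv
#' @export
read_snp_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "pos", "end"),
                        show_col_types = FALSE,
                        col_types = readr::cols(chrom = "c", pos = "i",
                                                end = "i"))
  select(df, "chrom", "pos")
}

#' @rdname read_counts_tsv
#' @export
read_qtl_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_counts_tsv
#' @export
read_sequences_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(transcript_id = names(ss),
         sequence = unname(as.character(ss)))
}
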