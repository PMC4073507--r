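make_tx <- function(id, chrom, strand, starts, ends, gene = paste0(id, "g")) {
  tibble::tibble(transcript_id = id, gene_id = gene, chrom = chrom,
                 start = starts, end = ends, strand = strand)
}

ref2ex <- make_tx("r1", "chr1", "+", c(100, 600, 1200), c(300, 800, 1500))

test_that("legend predicates classify canonical cases", {
  # identical intron chain with altered terminal exons -> "="
  q <- make_tx("q", "chr1", "+", c(150, 600, 1200), c(300, 800, 1400))
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "=")
  expect_equal(assign_class_codes(q, ref2ex)$matched_reference_id, "r1")

  # chromosome absent from the reference -> "u", no match
  q <- make_tx("q", "chr9", "+", c(100, 600), c(300, 800))
  res <- assign_class_codes(q, ref2ex)
  expect_equal(res$primary_code, "u")
  expect_true(is.na(res$matched_reference_id))

  # single exon inside a reference exon -> contained
  q <- make_tx("q", "chr1", "+", 620, 780)
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "c")

  # shared junction without full chain match -> novel isoform
  q <- make_tx("q", "chr1", "+", c(100, 600), c(300, 900))
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "j")

  # single exon spilling >= 10 bp into an intron -> pre-mRNA fragment
  q <- make_tx("q", "chr1", "+", 250, 350)
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "e")

  # single exon entirely inside an intron, same strand -> "i"
  q <- make_tx("q", "chr1", "+", 400, 500)
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "i")

  # exonic overlap on the opposite strand -> "x"
  q <- make_tx("q", "chr1", "-", 620, 780)
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "x")

  # near the reference but disjoint, same strand -> run-on fragment
  q <- make_tx("q", "chr1", "+", 1600, 1900)
  res <- assign_class_codes(q, ref2ex)
  expect_equal(res$primary_code, "p")
  expect_true(is.na(res$matched_reference_id))

  # more than 2 kb away -> "u"
  q <- make_tx("q", "chr1", "+", 4000, 4300)
  expect_equal(assign_class_codes(q, ref2ex)$primary_code, "u")
})

test_that("every query gets exactly one primary code from its code set", {
  set.seed(11)
  sets <- random_transcript_set(20, 60)
  res <- assign_class_codes(sets$query, sets$reference)
  expect_equal(nrow(res), 60)
  expect_true(all(nchar(res$primary_code) == 1))
  for (i in seq_len(nrow(res))) {
    expect_true(res$primary_code[i] %in%
                  strsplit(res$codes[i], ",")[[1]])
  }
  expect_equal(res$multi_classified,
               lengths(strsplit(res$codes, ",")) > 1)
})

test_that("class codes match the brute-force legend-predicate oracle", {
  set.seed(42)
  sets <- random_transcript_set(50, 200)
  got <- assign_class_codes(sets$query, sets$reference)
  want <- oracle_class_codes(as.data.frame(sets$query),
                             as.data.frame(sets$reference))
  got <- got[match(want$transcript_id, got$transcript_id), ]
  expect_equal(got$primary_code, want$primary_code)
  sort_codes <- function(x) {
    vapply(strsplit(x, ","), function(v) paste(sort(v), collapse = ","), "")
  }
  expect_equal(sort_codes(got$codes), want$codes)
})

test_that("classification is invariant under coordinate translation", {
  set.seed(5)
  sets <- random_transcript_set(15, 40)
  base <- assign_class_codes(sets$query, sets$reference)
  shift <- function(tx, by) dplyr::mutate(tx, start = start + by,
                                          end = end + by)
  shifted <- assign_class_codes(shift(sets$query, 7919),
                                shift(sets$reference, 7919))
  expect_equal(base$primary_code, shifted$primary_code)
  expect_equal(base$codes, shifted$codes)
})

test_that("candidate filter keeps multi-exon intergenic transcripts > 200 nt", {
  txs <- dplyr::bind_rows(
    make_tx("single500", "chr1", "+", 5000, 5500),
    make_tx("short2ex", "chr1", "+", c(7000, 7200), c(7075, 7275)),
    make_tx("good", "chr1", "+", c(9000, 9500), c(9150, 9600)),
    make_tx("exactly200", "chr1", "+", c(11000, 11500), c(11100, 11600))
  )
  cc <- assign_class_codes(txs, ref2ex[0, ])
  expect_true(all(cc$primary_code == "u"))
  kept <- filter_linc_candidates(txs, cc)
  expect_equal(unique(kept$transcript_id), "good")
  # strict inequality on length: a 200-nt spliced transcript is excluded
  expect_false("exactly200" %in% kept$transcript_id)
  # subset of input and idempotent
  kept2 <- filter_linc_candidates(kept, cc)
  expect_equal(kept, kept2)
})

test_that("candidate filter equals direct attribute-table evaluation", {
  set.seed(99)
  sets <- random_transcript_set(10, 30)
  cc <- assign_class_codes(sets$query, sets$reference)
  kept <- unique(filter_linc_candidates(sets$query, cc)$transcript_id)
  attrs <- transcript_summary(sets$query)
  want <- attrs$transcript_id[
    cc$primary_code[match(attrs$transcript_id, cc$transcript_id)] == "u" &
      attrs$n_exons >= 2 & attrs$spliced_length > 200]
  expect_setequal(kept, want)
})

test_that("loci merge by exonic overlap and separate by strand", {
  a <- make_tx("a", "chr1", "+", c(100, 500), c(200, 600))
  b <- make_tx("b", "chr1", "+", c(150, 800), c(250, 900))
  c_ <- make_tx("c", "chr1", "-", c(100, 500), c(200, 600))
  loci <- cluster_loci(dplyr::bind_rows(a, b, c_))
  expect_equal(nrow(loci), 2)
  plus <- loci[loci$strand == "+", ]
  expect_equal(plus$n_transcripts, 2)
  expect_equal(plus$span_start, 100)
  expect_equal(plus$span_end, 900)
})

test_that("locus partition equals graph components computed independently", {
  skip_if_not_installed("igraph")
  set.seed(77)
  sets <- random_transcript_set(40, 100)
  txs <- sets$query
  loci <- cluster_loci(txs)
  smry <- transcript_summary(txs)
  n <- nrow(smry)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (smry$chrom[i] != smry$chrom[j] ||
        smry$strand[i] != smry$strand[j]) next
    ov <- 0
    for (a in seq_along(smry$exon_starts[[i]])) {
      ov <- ov + sum(pmax(0, pmin(smry$exon_ends[[i]][a],
                                  smry$exon_ends[[j]]) -
                            pmax(smry$exon_starts[[i]][a],
                                 smry$exon_starts[[j]])))
    }
    adj[i, j] <- adj[j, i] <- ov >= 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  oracle_partition <- unname(split(smry$transcript_id, comp))
  got_partition <- loci$transcript_ids
  canon <- function(p) sort(vapply(p, function(v)
    paste(sort(v), collapse = "|"), ""))
  expect_equal(canon(got_partition), canon(oracle_partition))
})

test_that("transcript tables round-trip through GTF", {
  set.seed(3)
  sets <- random_transcript_set(10, 0)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(sets$reference, path)
  back <- read_transcripts_gtf(path)
  orig <- dplyr::arrange(sets$reference, transcript_id, start)
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$strand, orig$strand)
  expect_equal(back$transcript_id, orig$transcript_id)
  expect_equal(back$gene_id, orig$gene_id)
})

test_that("malformed exon structures are rejected", {
  bad <- tibble::tibble(transcript_id = "t", gene_id = "g", chrom = "chr1",
                        start = c(100, 150), end = c(200, 250),
                        strand = "+")
  expect_error(validate_transcripts(bad), class = "lincfinder_structure_error")
  bad2 <- make_tx("t", "chr1", "+", 100, 100)
  expect_error(validate_transcripts(bad2),
               class = "lincfinder_structure_error")
})
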