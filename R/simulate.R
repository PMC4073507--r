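#' Simulation configuration for the synthetic pipeline inputs
#'
#' Builds the configuration driving every synthetic generator. Defaults are
#' chosen to emulate the study design the pipeline targets: nine samples,
#' reference genes with multi-exon structure, query transcripts planted in
#' every class-code category, coding/non-coding sequence classes separated
#' in hexamer composition and ORF structure, synonymous-biased versus
#' neutral cross-species substitutions, negative-binomial counts with lower
#' means and inflated dispersion for the lincRNA group, planted perfectly
#' co-monotone lincRNA/coding pairs, homogeneous-Poisson SNPs and
#' trait-grouped QTL intervals. One seed drives all sub-simulators through
#' fixed independent substreams, so adding a later stage never perturbs an
#' earlier one.
#'
#' @param seed integer seed (mandatory).
#' @param n_chromosomes,chrom_length genome geometry (default 2 x 5 Mb).
#' @param n_reference_genes reference transcripts, one per gene
#'   (default 300).
#' @param queries_per_code named integer vector of query transcripts to
#'   plant per class code; `u` is split internally into multi-exon
#'   non-coding candidates, multi-exon coding impostors, single-exon and
#'   short transcripts via `u_split`.
#' @param u_split named vector with entries `multi_noncoding`,
#'   `multi_coding`, `single_exon`, `short` summing to
#'   `queries_per_code["u"]`.
#' @param divergence separability of the coding and non-coding sequence
#'   generators in `[0, 1]`: 0 makes the two classes identically distributed
#'   (no planted ORF, no codon bias); 1 plants long ORFs with strongly
#'   biased codon usage (default 1).
#' @param orf_coverage_target fraction of a coding transcript covered by
#'   the planted ORF at divergence 1 (default 0.7).
#' @param n_train_coding,n_train_noncoding classifier training-set sizes
#'   (default 300 each, a desk-scale version of the 10,000 + 10,000 design).
#' @param train_length_range length range (nt) of training sequences.
#' @param species alignment species; the first is the reference.
#' @param sub_rate per-codon substitution probability per non-reference
#'   species (default 0.3).
#' @param syn_bias probability that a coding-regime substitution is
#'   synonymous (default 0.9); the non-coding regime substitutes uniformly.
#' @param n_calibration_controls conservation-calibration control-set size
#'   per class (default 100).
#' @param n_samples expression samples (default 9).
#' @param n_coding_expr_genes protein-coding genes carried into the count
#'   matrix (default 150).
#' @param linc_mu,linc_size,coding_mu,coding_size negative-binomial mean and
#'   size (inverse-dispersion) per gene group; the lincRNA defaults
#'   (mu 40, size 2) give visibly higher dispersion than the coding
#'   defaults (mu 200, size 8).
#' @param mapped_total_range per-sample mapped-read totals drawn uniformly
#'   from this range. The default band is deliberately narrow (+/- 10%):
#'   because every gene in a sample is divided by the same total, strong
#'   library-size variation induces rank correlation between unrelated
#'   genes, which would confound the planted co-expression truth.
#' @param n_planted_pairs perfectly co-monotone lincRNA/coding pairs to
#'   plant (default 5).
#' @param snp_rate_per_kb homogeneous SNP rate (default 1).
#' @param n_qtl_meat,n_qtl_other QTLs per trait group (default 15 each).
#' @param qtl_width_range QTL width range in bp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 2,
                       chrom_length = 5e6,
                       n_reference_genes = 300,
                       queries_per_code = c("=" = 60, c = 20, j = 80,
                                            e = 20, o = 30, i = 25, x = 20,
                                            s = 10, p = 15, u = 120),
                       u_split = c(multi_noncoding = 50, multi_coding = 50,
                                   single_exon = 10, short = 10),
                       divergence = 1,
                       orf_coverage_target = 0.7,
                       n_train_coding = 300,
                       n_train_noncoding = 300,
                       train_length_range = c(400, 1500),
                       species = c("cow", "human", "mouse", "rat", "dog"),
                       sub_rate = 0.3,
                       syn_bias = 0.9,
                       n_calibration_controls = 100,
                       n_samples = 9,
                       n_coding_expr_genes = 150,
                       linc_mu = 40, linc_size = 2,
                       coding_mu = 200, coding_size = 8,
                       mapped_total_range = c(9e5, 1.1e6),
                       n_planted_pairs = 5,
                       snp_rate_per_kb = 1,
                       n_qtl_meat = 15, n_qtl_other = 15,
                       qtl_width_range = c(1e5, 4e5)) {
  if (missing(seed)) abort("seed is mandatory",
                           class = "lincfinder_config_error")
  if (sum(u_split) != queries_per_code[["u"]]) {
    abort("u_split must sum to queries_per_code['u']",
          class = "lincfinder_config_error")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# fixed substream seeds per stage, below 2^31
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 977 + k * 100003) %% 2147483629)
}

SLOT_PITCH <- 25000

# slot table: one candidate gene region + one intergenic region per slot
slot_table <- function(cfg) {
  per_chrom <- floor(cfg$chrom_length / SLOT_PITCH)
  if (per_chrom < 1) {
    abort("chromosome too short for the slot layout",
          class = "lincfinder_config_error")
  }
  tidyr::expand_grid(chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
                     slot = seq_len(per_chrom)) %>%
    mutate(slot_start = (.data$slot - 1) * SLOT_PITCH)
}

#' Simulate a reference annotation and class-code-planted queries
#'
#' Places one multi-exon reference transcript per gene in regularly spaced
#' genomic slots, then constructs query transcripts that satisfy each
#' requested class-code predicate by construction (e.g. an `=` query copies
#' a reference intron chain with altered terminal exons; an `i` query is a
#' single exon dropped inside a reference intron; `u` queries sit in
#' intergenic regions more than 2 kb from any reference span). The `u`
#' queries include multi-exon non-coding candidates, multi-exon
#' coding-impostor candidates, single-exon and short (< 200 nt spliced)
#' transcripts, so the candidate filter and the coding cascade both have
#' planted positives and negatives.
#'
#' @param cfg a [sim_config()].
#' @return a list with `reference` and `query` exon-level transcript
#'   tibbles and `truth`, a tibble with one row per query: `transcript_id`,
#'   `true_code`, `partner_reference_id`, `u_kind` (`NA` for non-`u`
#'   queries), `true_biotype` (`coding` / `noncoding` / `unknown`),
#'   `is_linc_candidate` (u, multi-exon, spliced length > 200).
#' @export
simulate_annotation_and_queries <- function(cfg) {
  slots <- slot_table(cfg)
  n_paired <- sum(cfg$queries_per_code[names(cfg$queries_per_code) != "u"])
  n_u <- cfg$queries_per_code[["u"]]
  if (cfg$n_reference_genes > nrow(slots) || n_u > nrow(slots) ||
      n_paired > cfg$n_reference_genes) {
    abort(paste("infeasible geometry: need more/longer chromosomes or",
                "fewer genes/queries"),
          class = "lincfinder_config_error")
  }
  withr::with_seed(substream(cfg$seed, 1), {
    ref <- purrr::map(seq_len(cfg$n_reference_genes), function(g) {
      slot <- slots[g, ]
      n_ex <- sample(4:6, 1)
      ex_len <- sample(100:300, n_ex, replace = TRUE)
      in_len <- sample(500:900, n_ex - 1, replace = TRUE)
      starts <- slot$slot_start + 2500 +
        cumsum(c(0, ex_len[-n_ex] + in_len))
      tibble(
        transcript_id = sprintf("REF_T%04d", g),
        gene_id = sprintf("REF_G%04d", g),
        chrom = slot$chrom,
        start = starts, end = starts + ex_len,
        strand = if (g %% 2 == 0) "+" else "-"
      )
    }) %>% bind_rows()
    ref_smry <- transcript_summary(ref)

    code_ids <- rep(names(cfg$queries_per_code), cfg$queries_per_code)
    paired_codes <- code_ids[code_ids != "u"]
    qlist <- list()
    truth <- list()
    qn <- 0
    for (k in seq_along(paired_codes)) {
      code <- paired_codes[k]
      r <- ref_smry[k, ]  # one reference partner per paired query
      qn <- qn + 1
      id <- sprintf("QRY_T%04d", qn)
      ex <- build_query_exons(code, r)
      qlist[[qn]] <- tibble(
        transcript_id = id, gene_id = sprintf("QRY_G%04d", qn),
        chrom = r$chrom, start = ex$start, end = ex$end,
        strand = ex$strand
      )
      truth[[qn]] <- tibble(
        transcript_id = id, true_code = code,
        partner_reference_id = r$transcript_id,
        u_kind = NA_character_, true_biotype = "unknown",
        is_linc_candidate = FALSE
      )
    }

    u_kinds <- rep(names(cfg$u_split), cfg$u_split)
    u_kinds <- sample(u_kinds)  # shuffle kinds over slots
    for (k in seq_along(u_kinds)) {
      kind <- u_kinds[k]
      slot <- slots[k, ]
      qn <- qn + 1
      id <- sprintf("QRY_T%04d", qn)
      base <- slot$slot_start + 16000
      strand <- sample(c("+", "-"), 1)
      if (kind == "single_exon") {
        st <- base + sample(0:1000, 1)
        ex <- tibble(start = st, end = st + sample(300:600, 1))
      } else if (kind == "short") {
        st <- base + sample(0:1000, 1)
        ex <- tibble(start = c(st, st + 80 + 200),
                     end = c(st + 80, st + 80 + 200 + 80))
      } else {
        n_ex <- sample(2:4, 1)
        ex_len <- sample(150:300, n_ex, replace = TRUE)
        in_len <- sample(200:800, max(n_ex - 1, 1), replace = TRUE)
        st <- base + sample(0:500, 1) +
          cumsum(c(0, ex_len[-n_ex] + in_len[seq_len(n_ex - 1)]))
        ex <- tibble(start = st, end = st + ex_len)
      }
      qlist[[qn]] <- tibble(
        transcript_id = id, gene_id = sprintf("QRY_G%04d", qn),
        chrom = slot$chrom, start = ex$start, end = ex$end, strand = strand
      )
      spliced <- sum(ex$end - ex$start)
      truth[[qn]] <- tibble(
        transcript_id = id, true_code = "u",
        partner_reference_id = NA_character_,
        u_kind = kind,
        true_biotype = dplyr::case_when(
          kind == "multi_coding" ~ "coding",
          kind == "multi_noncoding" ~ "noncoding",
          TRUE ~ "noncoding"
        ),
        is_linc_candidate = kind %in% c("multi_noncoding", "multi_coding") &&
          nrow(ex) >= 2 && spliced > 200
      )
    }
    query <- bind_rows(qlist)
    truth <- bind_rows(truth)
  })
  list(reference = ref, query = query, truth = truth)
}

# exon construction per class code against one reference summary row r
build_query_exons <- function(code, r) {
  es <- r$exon_starts[[1]]; ee <- r$exon_ends[[1]]
  k <- length(es)
  same <- r$strand
  opp <- if (r$strand == "+") "-" else "+"
  switch(code,
    "=" = list(start = c(es[1] - 50, es[-1]),
               end = c(ee[-k], ee[k] + 50), strand = same),
    "c" = list(start = c(es[2] + 10, es[3:(k - 1)]),
               end = c(ee[2:(k - 2)], ee[k - 1] - 10), strand = same),
    "j" = list(start = c(es[-k], es[k] + 30),
               end = ee, strand = same),
    "e" = list(start = es[2] + 10, end = ee[2] + 50, strand = same),
    "o" = list(start = c(r$tx_start - 300, ee[1] + 100),
               end = c(es[1] + 50, ee[1] + 300), strand = same),
    "i" = list(start = ee[2] + 100, end = ee[2] + 300, strand = same),
    "x" = list(start = es[2] + 10, end = ee[2] - 10, strand = opp),
    "s" = list(start = c(ee[1] + 50, ee[2] + 50),
               end = c(ee[1] + 200, ee[2] + 200), strand = opp),
    "p" = {
      gap <- sample(200:1500, 1)
      st <- r$tx_end + gap
      list(start = c(st, st + 400), end = c(st + 150, st + 700),
           strand = same)
    },
    abort(paste("no construction for code", code),
          class = "lincfinder_config_error")
  )
}

CODONS <- {
  b <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

# codon sampling weights: divergence tilts usage toward G/C-ending codons
coding_codon_weights <- function(divergence) {
  gc3 <- substr(SENSE_CODONS, 3, 3) %in% c("G", "C")
  w <- exp(divergence * ifelse(gc3, 1.2, -1.2))
  w / sum(w)
}

random_nt <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# one coding sequence of total length len with a planted ORF; returns
# list(seq, orf_start, orf_end, frame)
make_coding_seq <- function(len, cfg) {
  if (cfg$divergence == 0) {
    return(list(seq = random_nt(len), orf_start = NA_integer_,
                orf_end = NA_integer_, frame = NA_integer_))
  }
  cover <- cfg$orf_coverage_target * cfg$divergence
  n_codon <- max(floor(len * cover / 3) - 2, 10)
  orf_len <- 3 * (n_codon + 2)  # ATG + codons + stop
  utr5 <- max(floor((len - orf_len) / 2), 0)
  utr3 <- max(len - orf_len - utr5, 0)
  body <- sample(SENSE_CODONS, n_codon, replace = TRUE,
                 prob = coding_codon_weights(cfg$divergence))
  orf <- paste0("ATG", paste(body, collapse = ""),
                sample(STOP_CODONS, 1))
  seq <- paste0(if (utr5 > 0) random_nt(utr5) else "",
                orf,
                if (utr3 > 0) random_nt(utr3) else "")
  list(seq = seq, orf_start = utr5, orf_end = utr5 + orf_len,
       frame = utr5 %% 3)
}

#' Simulate transcript and training sequences
#'
#' Emits sequences for every lincRNA candidate query (coding impostors carry
#' a planted in-frame ORF with divergence-tilted codon usage; non-coding
#' candidates are composition-random) and for the classifier training sets.
#' At `divergence = 0` both classes are drawn from the same null generator,
#' so any classifier should perform at chance; at the default
#' `divergence = 1` the classes are well separated.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_annotation_and_queries()].
#' @return `sim` extended with `sequences` (tibble `transcript_id`,
#'   `sequence`), `training` (tibble `set_id`, `class`, `sequence`) and
#'   `truth` gaining `orf_start`, `orf_end`, `orf_frame` for planted ORFs.
#' @export
simulate_sequences <- function(cfg, sim) {
  lens <- transcript_summary(sim$query) %>%
    select("transcript_id", "spliced_length")
  cand <- sim$truth %>%
    filter(.data$is_linc_candidate) %>%
    left_join(lens, by = "transcript_id")
  withr::with_seed(substream(cfg$seed, 2), {
    seqs <- purrr::map(seq_len(nrow(cand)), function(i) {
      len <- max(cand$spliced_length[i], 60)
      if (cand$true_biotype[i] == "coding") {
        cs <- make_coding_seq(len, cfg)
        tibble(transcript_id = cand$transcript_id[i], sequence = cs$seq,
               orf_start = cs$orf_start, orf_end = cs$orf_end,
               orf_frame = cs$frame)
      } else {
        tibble(transcript_id = cand$transcript_id[i],
               sequence = random_nt(len),
               orf_start = NA_integer_, orf_end = NA_integer_,
               orf_frame = NA_integer_)
      }
    }) %>% bind_rows()
    train_len <- function() sample(cfg$train_length_range[1]:
                                     cfg$train_length_range[2], 1)
    training <- bind_rows(
      purrr::map(seq_len(cfg$n_train_coding), function(i) {
        cs <- make_coding_seq(train_len(), cfg)
        tibble(set_id = sprintf("TRAIN_C%04d", i), class = "coding",
               sequence = cs$seq)
      }),
      purrr::map(seq_len(cfg$n_train_noncoding), function(i) {
        tibble(set_id = sprintf("TRAIN_N%04d", i), class = "noncoding",
               sequence = random_nt(train_len()))
      })
    )
  })
  sim$sequences <- select(seqs, "transcript_id", "sequence")
  sim$truth <- left_join(sim$truth,
                         select(seqs, "transcript_id", "orf_start",
                                "orf_end", "orf_frame"),
                         by = "transcript_id")
  sim$training <- training
  sim
}

# substitute one sequence under the coding (synonymous-biased, within the
# ORF) or neutral regime; returns the mutated sequence
mutate_sequence <- function(seq, regime, orf, cfg) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (regime == "coding" && !is.na(orf[1])) {
    # ORF region codon-wise, flanks neutral
    orf_pos <- seq(orf[1] + 1, orf[2])
    codon_starts <- orf_pos[seq(1, length(orf_pos) - 2, by = 3)]
    for (cs in codon_starts) {
      if (runif(1) < cfg$sub_rate) {
        codon <- paste(chars[cs:(cs + 2)], collapse = "")
        new <- substitute_codon(codon, synonymous = runif(1) < cfg$syn_bias)
        chars[cs:(cs + 2)] <- strsplit(new, "")[[1]]
      }
    }
    flank <- setdiff(seq_len(n), orf_pos)
    hit <- flank[runif(length(flank)) < cfg$sub_rate / 3]
    if (length(hit) > 0) {
      chars[hit] <- vapply(chars[hit], random_other_base, character(1))
    }
  } else {
    hit <- which(runif(n) < cfg$sub_rate / 3)
    if (length(hit) > 0) {
      chars[hit] <- vapply(chars[hit], random_other_base, character(1))
    }
  }
  paste(chars, collapse = "")
}

random_other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)

substitute_codon <- function(codon, synonymous) {
  code <- Biostrings::GENETIC_CODE
  if (synonymous) {
    syn <- SENSE_CODONS[code[SENSE_CODONS] == code[[codon]]]
    syn <- setdiff(syn, codon)
    if (length(syn) == 0) return(codon)  # e.g. ATG, TGG have no synonym
    sample(syn, 1)
  } else {
    sample(setdiff(SENSE_CODONS, codon), 1)
  }
}

#' Simulate multi-species alignments
#'
#' Builds a gap-free alignment per candidate transcript and per
#' conservation-calibration control: the reference row is the transcript
#' sequence; each other species carries substitutions under the coding
#' regime (synonymous-biased within the planted/longest ORF, neutral in the
#' flanks) or the neutral regime (uniform), according to the transcript's
#' true biotype.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_sequences()].
#' @return `sim` extended with `alignments` (named list of alignment
#'   tibbles for candidates) and `calibration` (list with `noncoding` and
#'   `coding` named alignment lists plus matching sequence tibbles).
#' @export
simulate_alignments <- function(cfg, sim) {
  make_aln <- function(seq, regime, orf) {
    rows <- c(seq, unname(vapply(cfg$species[-1], function(sp) {
      mutate_sequence(seq, regime, orf, cfg)
    }, character(1))))
    tibble(species = cfg$species, seq = rows)
  }
  withr::with_seed(substream(cfg$seed, 3), {
    cand <- filter(sim$truth, .data$is_linc_candidate)
    seqs <- setNames(sim$sequences$sequence, sim$sequences$transcript_id)
    alignments <- purrr::map(seq_len(nrow(cand)), function(i) {
      tr <- cand[i, ]
      orf <- if (tr$true_biotype == "coding" && !is.na(tr$orf_start)) {
        c(tr$orf_start, tr$orf_end)
      } else {
        o <- find_longest_orf(seqs[[tr$transcript_id]])
        if (o$found) c(o$start, o$end) else c(NA_integer_, NA_integer_)
      }
      regime <- if (tr$true_biotype == "coding") "coding" else "neutral"
      make_aln(seqs[[tr$transcript_id]], regime, orf)
    })
    names(alignments) <- cand$transcript_id
    ncal <- cfg$n_calibration_controls
    tr_c <- filter(sim$training, .data$class == "coding") %>%
      head(ncal)
    tr_n <- filter(sim$training, .data$class == "noncoding") %>%
      head(ncal)
    cal_aln <- function(df, regime) {
      out <- purrr::map(seq_len(nrow(df)), function(i) {
        o <- find_longest_orf(df$sequence[i])
        orf <- if (o$found) c(o$start, o$end) else c(NA_integer_, NA_integer_)
        make_aln(df$sequence[i], regime, orf)
      })
      names(out) <- df$set_id
      out
    }
    calibration <- list(
      coding = cal_aln(tr_c, "coding"),
      noncoding = cal_aln(tr_n, "neutral"),
      coding_sequences = tibble(transcript_id = tr_c$set_id,
                                sequence = tr_c$sequence),
      noncoding_sequences = tibble(transcript_id = tr_n$set_id,
                                   sequence = tr_n$sequence)
    )
  })
  sim$alignments <- alignments
  sim$calibration <- calibration
  sim
}

#' Score a set of alignments with the codon-conservation surrogate
#'
#' Convenience wrapper: finds each transcript's longest ORF and applies
#' [codon_conservation_score()]. Transcripts without any complete ORF carry
#' no codon-level evidence of coding constraint and score `-Inf`, so any
#' upper-threshold filter always retains them.
#'
#' @param alignments named list of alignment tibbles (reference row first).
#' @param sequences tibble `transcript_id`, `sequence` covering the
#'   alignment names.
#' @return tibble `transcript_id`, `score`.
#' @export
score_alignments <- function(alignments, sequences) {
  seqs <- setNames(sequences$sequence, sequences$transcript_id)
  purrr::map(names(alignments), function(tx) {
    orf <- find_longest_orf(seqs[[tx]])
    score <- if (orf$found) {
      codon_conservation_score(alignments[[tx]], orf)$score
    } else {
      -Inf
    }
    tibble(transcript_id = tx, score = score)
  }) %>% bind_rows()
}

#' Simulate negative-binomial count matrices
#'
#' Draws per-gene counts over the configured samples: the lincRNA group
#' (the non-coding `u` candidates, one gene each) receives lower means and
#' higher dispersion than the protein-coding group. Planted co-expressed
#' pairs are exactly co-monotone: the coding partner's profile is a strictly
#' increasing transform of its lincRNA's profile, so their Spearman rho
#' is 1 by construction.
#'
#' @param cfg a [sim_config()].
#' @param sim result of [simulate_annotation_and_queries()] (or later
#'   stage).
#' @return `sim` extended with `counts` (tibble `gene_id` + sample
#'   columns), `mapped_totals` (tibble `sample_id`, `mapped_total`),
#'   `gene_groups` (tibble `gene_id`, `group`) and `planted_pairs` (tibble
#'   `linc_id`, `coding_id`).
#' @export
simulate_counts <- function(cfg, sim) {
  linc_ids <- sim$truth %>%
    filter(.data$is_linc_candidate, .data$true_biotype == "noncoding") %>%
    pull("transcript_id")
  coding_ids <- sprintf("CEXPR_G%04d", seq_len(cfg$n_coding_expr_genes))
  if (cfg$n_planted_pairs > min(length(linc_ids), length(coding_ids))) {
    abort("n_planted_pairs exceeds available genes",
          class = "lincfinder_config_error")
  }
  s <- cfg$n_samples
  withr::with_seed(substream(cfg$seed, 4), {
    draw <- function(n, mu, size) {
      matrix(rnbinom(n * s, mu = mu, size = size), nrow = n)
    }
    lm <- draw(length(linc_ids), cfg$linc_mu, cfg$linc_size)
    cm <- draw(length(coding_ids), cfg$coding_mu, cfg$coding_size)
    pair_linc <- sample(seq_along(linc_ids), cfg$n_planted_pairs)
    pair_coding <- sample(seq_along(coding_ids), cfg$n_planted_pairs)
    for (k in seq_len(cfg$n_planted_pairs)) {
      # guarantee a non-constant profile for the planted pair
      while (sd(lm[pair_linc[k], ]) == 0) {
        lm[pair_linc[k], ] <- rnbinom(s, mu = cfg$linc_mu,
                                      size = cfg$linc_size)
      }
      # a pure multiple stays rank-identical even after division by
      # per-sample mapped totals (an additive offset would not)
      cm[pair_coding[k], ] <- lm[pair_linc[k], ] * 5L
    }
    totals <- tibble(
      sample_id = sprintf("S%02d", seq_len(s)),
      mapped_total = round(runif(s, cfg$mapped_total_range[1],
                                 cfg$mapped_total_range[2]))
    )
  })
  counts <- bind_rows(
    as_tibble(lm, .name_repair = ~ totals$sample_id) %>%
      mutate(gene_id = linc_ids, .before = 1),
    as_tibble(cm, .name_repair = ~ totals$sample_id) %>%
      mutate(gene_id = coding_ids, .before = 1)
  )
  sim$counts <- counts
  sim$mapped_totals <- totals
  sim$gene_groups <- bind_rows(
    tibble(gene_id = linc_ids, group = "linc"),
    tibble(gene_id = coding_ids, group = "coding")
  )
  sim$planted_pairs <- tibble(linc_id = linc_ids[pair_linc],
                              coding_id = coding_ids[pair_coding])
  sim
}

#' Simulate SNP positions and QTL intervals
#'
#' SNPs follow a homogeneous Poisson process along each chromosome at the
#' configured rate; QTLs are non-degenerate intervals with widths drawn from
#' the configured range, labelled with trait names from a meat/muscle or an
#' other-trait vocabulary.
#'
#' @param cfg a [sim_config()].
#' @param sim simulation list to extend (may be an empty list).
#' @return `sim` extended with `snps` (tibble `chrom`, `pos`) and `qtls`
#'   (tibble `qtl_id`, `chrom`, `start`, `end`, `trait_name`,
#'   `trait_group`).
#' @export
simulate_snps_and_qtls <- function(cfg, sim = list()) {
  meat_traits <- c("meat tenderness", "marbling score", "shear force",
                   "muscle depth", "carcass weight")
  other_traits <- c("milk yield", "fertility", "coat colour", "stature",
                    "somatic cell score")
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  withr::with_seed(substream(cfg$seed, 5), {
    snps <- purrr::map(chroms, function(ch) {
      n <- rpois(1, cfg$snp_rate_per_kb * cfg$chrom_length / 1000)
      if (n == 0) return(NULL)
      tibble(chrom = ch, pos = sort(sample.int(cfg$chrom_length, n,
                                               replace = TRUE) - 1L))
    }) %>% bind_rows()
    if (nrow(snps) == 0) snps <- tibble(chrom = character(), pos = integer())
    make_qtls <- function(n, group, traits, offset) {
      if (n == 0) return(NULL)
      tibble(
        qtl_id = sprintf("QTL_%04d", offset + seq_len(n)),
        chrom = sample(chroms, n, replace = TRUE),
        width = round(runif(n, cfg$qtl_width_range[1],
                            cfg$qtl_width_range[2]))
      ) %>%
        mutate(
          start = vapply(.data$width, function(w) {
            sample.int(max(cfg$chrom_length - w, 1), 1) - 1L
          }, integer(1)),
          end = .data$start + .data$width,
          trait_name = sample(traits, n, replace = TRUE),
          trait_group = group
        ) %>%
        select(-"width")
    }
    qtls <- bind_rows(
      make_qtls(cfg$n_qtl_meat, "meat_muscle", meat_traits, 0),
      make_qtls(cfg$n_qtl_other, "other", other_traits, cfg$n_qtl_meat)
    )
  })
  sim$snps <- snps
  sim$qtls <- qtls
  sim
}

#' Generate the full synthetic input bundle
#'
#' Runs every sub-simulator in order under one seed and, when `dir` is
#' given, writes all pipeline input files (reference and query GTF,
#' candidate FASTA, training FASTA pair, alignment MAF, counts and
#' mapped-totals TSV, SNP BED, QTL TSV, ground-truth JSON).
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return the full simulation list (invisible file manifest in
#'   `$manifest` when files are written).
#' @export
simulate_linc_bundle <- function(cfg, dir = NULL) {
  sim <- simulate_annotation_and_queries(cfg)
  sim <- simulate_sequences(cfg, sim)
  sim <- simulate_alignments(cfg, sim)
  sim <- simulate_counts(cfg, sim)
  sim <- simulate_snps_and_qtls(cfg, sim)
  if (!is.null(dir)) {
    sim$manifest <- write_bundle(sim, dir)
  }
  sim
}

write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  write_transcripts_gtf(sim$reference, path("reference.gtf"))
  write_transcripts_gtf(sim$query, path("queries.gtf"))
  fa <- Biostrings::DNAStringSet(setNames(sim$sequences$sequence,
                                          sim$sequences$transcript_id))
  Biostrings::writeXStringSet(fa, path("candidates.fa"))
  for (cl in c("coding", "noncoding")) {
    sub <- filter(sim$training, .data$class == cl)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sub$sequence, sub$set_id)),
      path(paste0("training_", cl, ".fa"))
    )
  }
  write_maf(sim$alignments, path("alignments.maf"))
  readr::write_tsv(sim$counts, path("counts.tsv"))
  readr::write_tsv(sim$mapped_totals, path("mapped_totals.tsv"))
  readr::write_tsv(
    mutate(sim$snps, end = .data$pos + 1L),
    path("snps.bed"), col_names = FALSE
  )
  readr::write_tsv(sim$qtls, path("qtls.tsv"))
  jsonlite::write_json(
    list(truth = sim$truth, planted_pairs = sim$planted_pairs,
         gene_groups = sim$gene_groups),
    path("truth.json")
  )
  files <- c("reference.gtf", "queries.gtf", "candidates.fa",
             "training_coding.fa", "training_noncoding.fa",
             "alignments.maf", "counts.tsv", "mapped_totals.tsv",
             "snps.bed", "qtls.tsv", "truth.json")
  file.path(dir, files)
}
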