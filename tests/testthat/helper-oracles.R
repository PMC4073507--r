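# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every predicate from first principles with
# naive loops, sharing no code with the package internals.

random_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# ---- class-code oracle -----------------------------------------------------

# exon tables: data frames with start/end (0-based half-open), plus strand
oracle_codes_one <- function(qex, qstrand, rex, rstrand, run_on_bp = 2000) {
  ov_bp <- function(a, b) {
    tot <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      tot <- tot + max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
    }
    tot
  }
  introns <- function(ex) {
    if (nrow(ex) < 2) return(data.frame(start = numeric(), end = numeric()))
    data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
  }
  qin <- introns(qex); rin <- introns(rex)
  compat <- qstrand == rstrand || qstrand == "." || rstrand == "."
  opposite <- qstrand %in% c("+", "-") && rstrand %in% c("+", "-") &&
    qstrand != rstrand
  exov <- ov_bp(qex, rex)
  codes <- character()

  same_chain <- nrow(qin) == nrow(rin) &&
    (nrow(qin) == 0 || (all(qin$start == rin$start) && all(qin$end == rin$end)))
  if (compat && exov >= 1 && same_chain) codes <- c(codes, "=")

  contained <- {
    each_in <- all(vapply(seq_len(nrow(qex)), function(i) {
      any(qex$start[i] >= rex$start & qex$end[i] <= rex$end)
    }, logical(1)))
    chain_ok <- TRUE
    if (nrow(qin) > 0) {
      hits <- which(rin$start == qin$start[1] & rin$end == qin$end[1])
      if (length(hits) != 1 || hits + nrow(qin) - 1 > nrow(rin)) {
        chain_ok <- FALSE
      } else {
        run <- hits:(hits + nrow(qin) - 1)
        chain_ok <- all(rin$start[run] == qin$start) &&
          all(rin$end[run] == qin$end)
      }
    }
    each_in && chain_ok
  }
  if (compat && !("=" %in% codes) && contained) codes <- c(codes, "c")

  shared_boundary <- nrow(qin) > 0 && nrow(rin) > 0 &&
    (any(qin$start %in% rin$start) || any(qin$end %in% rin$end))
  if (compat && nrow(qin) > 0 && !("=" %in% codes) && shared_boundary) {
    codes <- c(codes, "j")
  }

  if (compat && nrow(qex) == 1 && exov >= 1 && nrow(rin) > 0) {
    deep <- any(vapply(seq_len(nrow(rin)), function(j) {
      min(qex$end[1], rin$end[j]) - max(qex$start[1], rin$start[j]) >= 10
    }, logical(1)))
    if (deep) codes <- c(codes, "e")
  }

  if (compat && exov >= 1 && !any(c("=", "c", "j", "e") %in% codes)) {
    codes <- c(codes, "o")
  }

  if (compat && nrow(qex) == 1 && nrow(rin) > 0 &&
      any(qex$start[1] >= rin$start & qex$end[1] <= rin$end)) {
    codes <- c(codes, "i")
  }

  if (opposite && exov >= 1) codes <- c(codes, "x")

  if (opposite && nrow(qin) > 0 && nrow(rin) > 0 &&
      ov_bp(qin, rin) >= 1) {
    codes <- c(codes, "s")
  }

  qspan <- c(min(qex$start), max(qex$end))
  rspan <- c(min(rex$start), max(rex$end))
  gap <- max(qspan[1], rspan[1]) - min(qspan[2], rspan[2])
  if (compat && exov == 0 && gap >= 0 && gap <= run_on_bp) {
    codes <- c(codes, "p")
  }
  codes
}

oracle_class_codes <- function(query, reference) {
  order_codes <- c("=", "c", "j", "e", "o", "i", "x", "s", "p", "u")
  q_ids <- unique(query$transcript_id)
  out <- lapply(q_ids, function(qid) {
    qex <- query[query$transcript_id == qid, ]
    qex <- qex[order(qex$start), ]
    codes <- character()
    for (rid in unique(reference$transcript_id)) {
      rex <- reference[reference$transcript_id == rid, ]
      rex <- rex[order(rex$start), ]
      if (qex$chrom[1] != rex$chrom[1]) next
      codes <- union(codes,
                     oracle_codes_one(qex, qex$strand[1], rex, rex$strand[1]))
    }
    if (length(codes) == 0) codes <- "u"
    primary <- order_codes[which(order_codes %in% codes)[1]]
    data.frame(transcript_id = qid, primary_code = primary,
               codes = paste(sort(codes), collapse = ","))
  })
  do.call(rbind, out)
}

# random exon-level transcript tables around a shared coordinate space,
# biased so that all class codes actually occur
random_transcript_set <- function(n_ref, n_query) {
  ref <- do.call(rbind, lapply(seq_len(n_ref), function(i) {
    n_ex <- sample(1:4, 1)
    len <- sample(50:200, n_ex, replace = TRUE)
    gap <- if (n_ex > 1) sample(60:400, n_ex - 1, replace = TRUE) else integer()
    anchor <- sample(0:30000, 1)
    starts <- anchor + cumsum(c(0, len[-n_ex] + gap))
    data.frame(transcript_id = sprintf("R%03d", i),
               gene_id = sprintf("RG%03d", i),
               chrom = sample(c("chr1", "chr2"), 1),
               start = starts, end = starts + len,
               strand = sample(c("+", "-"), 1))
  }))
  qry <- do.call(rbind, lapply(seq_len(n_query), function(i) {
    n_ex <- sample(1:3, 1)
    len <- sample(40:250, n_ex, replace = TRUE)
    gap <- if (n_ex > 1) sample(50:500, n_ex - 1, replace = TRUE) else integer()
    # anchor near a random reference most of the time
    r <- ref[ref$transcript_id == sample(unique(ref$transcript_id), 1), ]
    anchor <- if (runif(1) < 0.8) {
      min(r$start) + sample(-2500:2500, 1)
    } else {
      sample(0:35000, 1)
    }
    anchor <- max(anchor, 0)
    starts <- anchor + cumsum(c(0, len[-n_ex] + gap))
    data.frame(transcript_id = sprintf("Q%03d", i),
               gene_id = sprintf("QG%03d", i),
               chrom = if (runif(1) < 0.9) r$chrom[1] else "chr3",
               start = starts, end = starts + len,
               strand = sample(c("+", "-"), 1))
  }))
  list(reference = tibble::as_tibble(ref), query = tibble::as_tibble(qry))
}

# ---- ORF oracle ------------------------------------------------------------

# exhaustive scan over every (start, stop, frame) triple
oracle_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- list(length = 0L, start = NA, frame = NA)
  for (frame in 0:2) {
    starts <- seq(frame + 1, n, by = 3)
    starts <- starts[starts + 2 <= n]
    codons <- substring(seq, starts, starts + 2)
    for (a in seq_along(codons)) {
      if (codons[a] != "ATG") next
      for (b in seq_along(codons)) {
        if (b < a || !(codons[b] %in% stops)) next
        if (any(codons[seq(a, b)][-(b - a + 1)] %in% stops)) next
        len <- (b - a + 1) * 3
        if (len > best$length ||
            (len == best$length && starts[a] - 1 < best$start)) {
          best <- list(length = len, start = starts[a] - 1, frame = frame)
        }
      }
    }
  }
  best
}

# ---- Fickett oracle --------------------------------------------------------

# direct transcription of the published lookup tables, computed base by base
oracle_fickett <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    n1 <- sum(chars[seq(1, length(chars), by = 3)] == b)
    n2 <- sum(chars[seq(2, length(chars), by = 3)] == b)
    n3 <- if (length(chars) >= 3) {
      sum(chars[seq(3, length(chars), by = 3)] == b)
    } else 0
    posval <- max(n1, n2, n3) / (min(n1, n2, n3) + 1)
    conval <- sum(chars == b) / length(chars)
    pbin <- 11 - findInterval(posval, c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7,
                                        1.8, 1.9)) - 1
    cbin <- 11 - findInterval(conval, c(0.17, 0.19, 0.21, 0.23, 0.25, 0.27,
                                        0.29, 0.31, 0.33)) - 1
    total <- total + pos_prob[[b]][pbin] * pos_w[[b]] +
      con_prob[[b]][cbin] * con_w[[b]]
  }
  total
}

# ---- translation oracle ----------------------------------------------------

oracle_translate <- function(seq, frame) {
  seq <- toupper(seq)
  code <- Biostrings::GENETIC_CODE
  out <- character()
  i <- frame + 1
  while (i + 2 <= nchar(seq)) {
    codon <- substr(seq, i, i + 2)
    out <- c(out, if (grepl("[^ACGT]", codon)) "X" else code[[codon]])
    i <- i + 3
  }
  paste(out, collapse = "")
}
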