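# a scaled-down configuration keeping the distributional parameters of the
# defaults but fewer entities, for fast unit tests
small_cfg <- function(seed, ...) {
  base <- list(
    n_chromosomes = 2, chrom_length = 2e6,
    n_reference_genes = 60,
    queries_per_code = c("=" = 8, c = 4, j = 8, e = 4, o = 4, i = 4,
                         x = 4, s = 2, p = 4, u = 40),
    u_split = c(multi_noncoding = 15, multi_coding = 15,
                single_exon = 5, short = 5),
    n_train_coding = 80, n_train_noncoding = 80,
    n_calibration_controls = 20,
    n_coding_expr_genes = 40,
    n_planted_pairs = 3
  )
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, c(list(seed = seed), args))
}

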