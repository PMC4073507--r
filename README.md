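# lincfinder

`lincfinder` identifies and characterises long intergenic non-coding RNAs
(lincRNAs) from assembled RNA-seq transcript models. It is written for
transcriptomics researchers who have a reference annotation, assembled
transcripts, transcript sequences and per-sample read counts — the situation
of a typical bulk RNA-seq survey of a tissue across several individuals
(the motivating design is nine bovine *Longissimus thoraci* muscle samples)
— and want a tested, reproducible alternative to ad-hoc filtering scripts.

## What it computes

**Classification.** Each assembled transcript is compared against the
reference annotation and assigned Cuffcompare-style class codes
(`=`, `c`, `j`, `e`, `o`, `i`, `x`, `s`, `p`, `u`), with the full code set
retained for multi-classified transcripts. Intergenic (`u`) transcripts with
≥ 2 exons and spliced length > 200 nt become lincRNA candidates, and
transcripts are clustered into loci by exonic overlap.

**Coding-potential cascade.** A candidate survives only if it passes three
independent filters:

1. *Conservation* — a codon-level constraint score over a multi-species
   alignment, `Σ_species log((syn + 1)/(nonsyn + 1))` across substituted
   codons of the longest ORF; positive values are coding-like. Retain when
   the score falls below a threshold: 0 by default, or calibrated so a
   chosen fraction (default 73%) of known non-coding controls is retained.
2. *Classifier* — logistic regression on ORF length, ORF coverage, the
   Fickett TESTCODE statistic and hexamer-usage bias
   (log f_coding/f_noncoding averaged over 6-mers), with cross-validated
   cutoff selection maximising (sensitivity + specificity)/2, where
   **non-coding is the positive class**: Sens = TP/(TP+FN),
   Spec = TN/(TN+FP).
3. *Domain filter* — three-frame translation scanned against a
   protein-motif database (built-in PWM scanner; external scanners plug in
   as a function handle).

**Characterisation.** Normalised expression (reads per transcript / total
mapped reads), detection across samples, per-gene coefficient of variation
(100·sd/mean), group comparisons by Student's t-test, strand-aware SNP
density in −10 kb/+1 kb regulatory windows, all-pairs Spearman co-expression
with the Bonferroni threshold α/(n_linc · n_coding) and a 2-Mb *cis*
window, and QTL-overlap enrichment via a 1-df chi-squared test against a
span-proportional expectation.

**Synthetic data.** `simulate_linc_bundle()` generates every pipeline input
(GTF, FASTA, MAF, counts, SNP BED, QTL TSV) with known ground truth under a
single seed, so the whole pipeline is testable offline.

## Worked example

```r
library(lincfinder)

cfg    <- sim_config(seed = 42)          # default study-scale simulation
sim    <- simulate_linc_bundle(cfg)      # all inputs + ground truth
report <- run_pipeline(sim, seed = 42)
report
#> lincRNA pipeline report (seed 42 )
#>   n_query                      400
#>   n_u                          120
#>   n_candidates                 100
#>   n_candidate_loci             100
#>   classifier_cutoff            0.500011
#>   conservation_threshold       0
#>   n_retained                   50
#>   n_linc_loci                  50
#>   n_genes_quantified           200
#>   n_detected_all_samples       200
#>   n_coexpr_pairs               7500
#>   n_coexpr_significant         5
#>   n_qtl_overlaps               56
#>   qtl_chi_squared              9.2802
```

Of 400 simulated queries, 120 are intergenic (`u`); 100 pass the
multi-exon/200-nt filter; the cascade retains exactly the 50 planted
non-coding candidates (the 50 coding impostors are removed), one locus
each. The per-stage audit:

```r
report$cascade$audit
#>   stage                       n
#> 1 input                     100
#> 2 conservation               52
#> 3 classifier                 50
#> 4 conservation+classifier    50
#> 5 domain                    100
#> 6 retained                   50
```

The lincRNA group shows the planted inter-individual expression-variability
inflation (mean CV 69.3% vs 37.6% for coding genes):

```r
report$cv_comparison
#>   statistic  p_value mean_a  sd_a   n_a mean_b  sd_b   n_b
#> 1      14.0 2.04e-31   69.3  19.5    50   37.6  11.4   150
```

and the co-expression screen flags exactly the 5 planted co-monotone
lincRNA/coding pairs at the Bonferroni level (`n_coexpr_significant` above).
`plot_cascade_audit()`, `plot_cv_comparison()` and `plot_coexpression_rho()`
draw the corresponding figures; `tidy()`/`glance()` methods give tabular
access to every fitted object.

A thin command-line wrapper over these functions ships at
`inst/cli/lincpipe.R` (subcommands `simulate`, `classify`,
`codingpotential`, `expression`, `coexpress`, `qtl`, `run-all`).

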