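# top1tam

Tools for analysing the short-deletion mutational signature caused by
topoisomerase 1 (TOP1) cleavage at genome-embedded ribonucleotides — the
process behind the COSMIC indel signature ID4 and its extended form,
ID-TOP1. The package is aimed at researchers studying indel mutagenesis in
ribonucleotide-excision-repair (RNase H2) deficient cells, cancers and the
germline, and at anyone who needs a tested, self-contained implementation
of the analyses involved:

* **Deletion context classification.** 2–5 bp deletions are annotated by
  short tandem repeat (STR) context, single-nucleotide microhomology
  (SNMH), canonical dinucleotide class, and compliance with the **TNT
  motif**: thymidines spaced `d` bases apart, `T·N^(d−1)·T`, flanking or
  containing a `d`-bp deletion. A deletion is TNT-compliant when some
  register of the deletion within its repeat/MH region places the deleted
  bases as `N^(d−1)T` with a T immediately 5′, on either strand.
* **Null models and enrichment.** The genome-wide null (the compliant
  fraction of 100,000 uniformly placed deletions in the mappable genome),
  the matched-repeat bootstrap (1,000 replicates drawn from repeats of
  matching type, unit length and total length), two-sided Fisher tests of
  observed versus expected motif fractions, and Bonferroni/BH correction.
* **Spectrum statistics.** COSMIC ID-83 spectra, wild-type background
  subtraction (negative cells clamped to 0), cosine similarity
  `cos(θ) = Σ A_i B_i / (‖A‖‖B‖)`, an empirical Dirichlet-multinomial null
  for cosine values, complete-linkage clustering on cosine distance with
  bootstrap support, and two-bit sequence logos with the canonical
  orientation (reverse-complement when the deleted dinucleotide contains
  an A, except AT/TA) and right-alignment to the most 3′ T.
* **Fluctuation analysis.** Lea–Coulson method of the median
  (`r₀/m − ln m = 1.24`), per-bp per-generation rates, and nonparametric
  95% CIs from order statistics (for 16 cultures: the 4th and 13th ranked
  counts).
* **Transcription stratification.** Expression-decile and collapsed
  germline expression groups, per-stratum rates `c/(g·n)` with
  gene-resampling bootstrap CIs, highly-expressed tissue-restricted (HETR)
  gene calls (within-tissue median ≥ q90, other-tissue median < 0.1·q90)
  with Fisher odds-ratio matrices, TOP1-activity signal decile relative
  rates, and percentile-based individual filtering.
* **Reporter design.** The synonymous-recoding algorithm that packs a
  coding sequence with 2 bp tandem repeats using a 5-codon sliding window,
  then removes stop codons that a +2 frameshift would expose.
* **Synthetic data.** Seeded generators for genomes with planted
  repeat/MH content, deletion sets with a tunable TNT bias,
  Luria–Delbrück colony counts, expression tables with planted HETR genes,
  and binned activity tracks — each with machine-readable truth labels, so
  every stage of the pipeline is testable without external downloads.

## Worked example

Plant deletions with a known TNT bias on a synthetic genome, classify
them, and test motif enrichment against the genomic null:

```r
library(top1tam)

genome <- generate_genome(20000, seed = 42, gc_fraction = 0.4)
dels   <- plant_deletions(genome, n = 200, tnt_bias = 0.8, seed = 43)
cls    <- classify_deletions(dels, genome)
table(cls$context)
#> other  SNMH   STR
#>    28    88    84
mean(cls$tnt_compliant)
#> [1] 0.85

bg  <- genomic_null(genome, d = 2, n_samples = 20000, seed = 44)
bg$fraction
#> [1] 0.34265
enr <- enrichment_test(nrow(cls), sum(cls$tnt_compliant), bg$fraction)
enr[c("odds_ratio", "p_value")]
#>   odds_ratio      p_value
#> 1   10.68134 9.854438e-26
```

170 of 200 planted deletions sit at TNT motifs against a genomic
background availability of 34%, an enrichment the Fisher test calls at
odds ratio ≈ 10.7 — the qualitative pattern seen at deletion sites in
RNase-H2-deficient tumours.

Estimate a mutation rate from a simulated fluctuation assay:

```r
assay <- simulate_fluctuation(1e-7, n_start = 1000, n_final = 1e7,
                              n_cultures = 16, seed = 45)
fit <- lea_coulson_estimate(assay, target_bp = 1032, copies = 1)
fit
#> <fluctuation_fit> n = 16  median count = 5
#>   m = 2.375  rate/bp/gen = 1.405e-10  95% CI [ 5.264e-11 , 2.116e-10 ]
```

The median of 16 mutant counts is 5, giving `m = 2.375` expected mutations
per culture and a per-bp per-generation rate of `1.4e-10` over the
1,032 bp frameshift-productive target, with the CI built from the 4th- and
13th-ranked cultures. `tidy(fit)` and `glance(fit)` return the estimates
and settings as tibbles; `autoplot()` / `plot_*()` helpers display
spectra, logos, decile curves and stratum rates.

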