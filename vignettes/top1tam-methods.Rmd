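---
title: "Methods: models, parameters and design choices in top1tam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in top1tam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(top1tam)
```

# The mutational process being modelled

Topoisomerase 1 (TOP1) relieves torsional stress by transient single-strand
cleavage. When TOP1 cleaves 3′ of a ribonucleotide embedded in DNA — the
most common aberrant nucleotide in replicating eukaryotic genomes, normally
removed by RNase-H2-initiated ribonucleotide excision repair — the
2′-OH of the ribose can resolve the cleavage complex into a non-ligatable
nick. A second TOP1 cleavage a few bases 5′, followed by strand
realignment, deletes the intervening 2–5 bp. Because realignment requires
a repeated base at the two cleavage sites, and because TOP1 prefers to cut
immediately 3′ of a thymidine, the resulting deletions concentrate at
short tandem repeats (STRs) and single-nucleotide microhomology (SNMH)
sites, within a **TNT motif**: thymidines spaced `d` bases apart
(`T·N^(d−1)·T`) around a `d`-bp deletion. Transcription both requires TOP1
activity and incorporates ribonucleotide-exposing intermediates, so the
deletion rate rises with expression level. This package implements the
computational machinery for detecting and quantifying that signature.

# Deletion classification

A deletion call is held 0-based (`pos` = first deleted base); VCF
conversion (1-based, anchor-base) is confined to the I/O layer.
`normalize_indels()` left-aligns; all equivalent registers of a deletion —
the contiguous set of start positions yielding the same edited sequence —
are enumerated exactly.

* `repeat_copies` is the maximal tandem count of the deleted unit spanning
  the site, *including* the deleted copy (so deleting one unit of a
  doublet gives 2). This matches COSMIC ID-83 repeat-size semantics.
* `mh_length` is the longest homology between the deleted sequence and its
  immediate flanks (deleted suffix vs 5′ flank, deleted prefix vs 3′
  flank; the 3′-anchored value is recorded on ties, consistent with
  right-alignment).
* Context is `STR` when `repeat_copies ≥ 2`, else `SNMH` when
  `mh_length ≥ 1`, else `other`; STR takes precedence so the two tallies
  are disjoint.
* 2 bp deletions at STR/SNMH sites collapse into six canonical
  dinucleotide classes (`AT`, `TA`, `CC/GG`, `CG/GC`, `CT/TC/AG/GA`,
  `AC/CA/GT/TG`). The homopolymer dinucleotides `AA`/`TT` take no class:
  deleting them is a homopolymer contraction, not the loss of a 2 bp
  repeat unit, so they fall outside this taxonomy and are reported `NA`.

## TNT scoring is strand-symmetric

The motif rule — deleted bases `N^(d−1)T` with a T immediately 5′ at some
register (for 2 bp deletions and non-repeat contexts), or the repeat/MH
region containing `T·N^(d−1)·T` (for 3–5 bp deletions in repeats) — is
applied on **both strands**: on the written strand the complementary
reading is an `A·N^(d−1)·A` motif. A deletion is an unoriented
double-stranded event, and sequence-logo construction reverse-complements
A-containing deletions before display, so one-strand scoring would make
the flag depend on which strand the reference happens to record. The
symmetric rule makes classification reverse-complement invariant (a tested
property). A consequence worth noting: a deletion in a `(CA)ₙ` repeat is
compliant, because the same event on the opposite strand is a `(TG)ₙ`
deletion with a canonical T context; only repeats with no T on either
strand (`CC`/`GG`, `CG`/`GC`) are constitutively non-compliant — exactly
the classes never observed among these deletions.

# Null models and enrichment

* **Genomic null.** The compliant fraction of `n` uniformly placed `d`-bp
  deletions in the mappable genome (default `n = 100{,}000`; tests and the
  acceptance script use 20,000 samples on 20 kb genomes, where the sampled
  fraction is within three binomial standard errors of the exhaustive
  enumeration).
* **Matched-repeat bootstrap.** For each observed STR/SNMH deletion, each
  of `B = 1{,}000` replicates draws (uniformly, with replacement) a
  genomic repeat matching the deletion's kind, unit length (the primitive
  period of the deleted unit) and total repeat length, and records motif
  presence; the replicate statistic is the motif fraction and the
  empirical p is `(1 + #{replicates ≥ observed})/(B + 1)`, which cannot be
  zero.
* **Fisher enrichment test.** Observed motif/non-motif counts are compared
  with a pseudo-cohort of equal size carrying the expected fraction. Two
  constructions are provided. `pseudo_cohort = "rounded"` fixes the
  expected column at `round(f·n)`: deterministic and reproducible, but
  conservative under the null, because one-sample data is tested in a
  two-sample frame — null p-values concentrate above uniform.
  `pseudo_cohort = "sampled"` draws the expected column as
  `Binomial(n, f)`, the standard two-independent-binomials setting in
  which Fisher's exact test is approximately calibrated; the calibration
  suite (200 uniform-placement datasets, Kolmogorov–Smirnov at α = 0.01)
  uses this form. The choice is explicit and swappable per call.

# Spectra and their comparison

ID-83 category labels follow the COSMIC layout (1 bp deletions/insertions
by C/T base and homopolymer length; 2, 3, 4, 5+ bp deletions/insertions by
repeat-unit count; microhomology deletions by homology length). A
`frameshift2` subset (36 categories) collects the events that expose a
reporter's +2 reading frame: deletions of length ≡ 2 (mod 3) and
insertions of length ≡ 1 (mod 3) under ID-83 binning. A published
41-category reporter scheme could not be reconstructed from public
descriptions; the subset used here is defined exactly and fixed, which is
what spectrum comparison requires.

Background subtraction is per-category `max(0, ko − mean(wt))`. Cosine
similarity uses the standard formula and is scale-invariant. Its
significance comes from an empirical null: 10,000 pairs of count vectors
drawn from a flat Dirichlet-multinomial at the observed totals
(`rgamma`-normalized Dirichlet, then multinomial), with add-one smoothing.
Under the null the p-value is uniform (tested by KS over 500 repetitions
at 2,000 pairs — scaled down to keep the suite fast; the estimator is the
same at any pair count).

Clustering is complete-linkage on cosine distance (1 − cosine). Bootstrap
support resamples each spectrum's mutations with replacement, reclusters,
and scores a join as supported when its exact leaf set reappears as a
clade; support is reported as a percentage of `B = 1{,}000` replicates
(tests use 100–200).

Sequence logos use the uncorrected two-bit representation: column
information `2 + Σ f·log₂f` with `N` excluded per column; the small-sample
correction is available behind an option but off by default. The logo
window width is a parameter (`flank`, default 10 bp each side); windows
running off the sequence are N-padded and flagged. Orientation and
register follow the canonicalization rules: reverse-complement when the
deleted dinucleotide contains an A (except AT/TA), and right-align the
deleted pair to the most 3′ T of the repeat/MH region, else to the region
limit.

# Fluctuation analysis

The Lea–Coulson method of the median solves `r₀/m − ln m = 1.24` for the
expected mutations per culture `m`, where `r₀` is the median mutant count;
the left side is strictly decreasing in `m`, so the root (found by
`uniroot` on `(10⁻¹², 10⁶]`) is unique. The constant 1.24 is exposed as a
parameter. Per-generation rates divide by the final population (total
divisions ≈ `N_final`, the standard convention); per-bp rates divide
further by the target size (default 1,032 bp, the frameshift-productive
reporter span) and reporter copy number (1 or 2). A median count of zero
reports rate 0 with a below-detection flag rather than failing.

The 95% CI uses the tightest symmetric order-statistic pair `(j, n+1−j)`
with `Binomial(n, ½)` coverage ≥ 0.95 — for 16 cultures, ranks 4 and 13
(coverage 97.9%); fewer than 6 cultures cannot reach 95% and error out.
The per-culture rates at those ranks apply the same median relation to the
ranked culture's own count and final population; this convention is
isolated in one function for easy substitution, since published accounts
rarely print it.

The simulator uses synchronized doublings with binomial mutation per
generation (mutants breed true, no back-mutation, no fitness cost), which
matches the per-generation rate definition of the estimator; a
continuous-time birth process would estimate a subtly different rate. At
the study conditions (16 cultures, μ = 10⁻⁷ per division, final
populations near 10⁷) the median count is small (2–3), so integer
granularity alone contributes ≈ 20% relative error to the median-based
estimator — the 25% recovery tolerance in the acceptance suite reflects
this floor, and CI coverage stays at or above the nominal construction.

# Transcription and activity stratification

Expression groups: decile binning on gene-level median TPM;
housekeeping-like filtering first (max TPM < 10 × median TPM) when
requested; or collapsing pre-assigned groups 1–9 into
unexpressed (1) / low (2–4) / mid (5–7) / high (8–9). Overlapping genes
are resolved hierarchically, keeping the most abundant (highest median,
ties by mean). Stratum rates are `c/(g·n)` — deletions contained in the
group's union span (containment of the leftmost deleted base; an explicit
edge rule), divided by span and by the number of mutated genomes — with
CIs from 100 gene-resampling bootstrap replicates (0.025/0.975
quantiles).

HETR (highly expressed, tissue-restricted) genes satisfy within-tissue
median TPM ≥ q90 — the 90th quantile of within-tissue gene medians — with
median over other tissues below 0.1·q90. "High expression in a tissue" is
interpreted as the within-tissue *median* reaching q90 (the any-sample
alternative would be noise-sensitive with few samples per tissue).
Enrichment across cancer–tissue pairs uses 2×2 Fisher tests
(HETR/non-HETR × cancer/rest), Bonferroni-corrected over all pairs tested,
with depleting odds ratios additionally reported as reciprocals for
display.

Signal decile rates average the two replicate tracks per bin, divide by
mappable width, assign deciles (ties broken by first occurrence, giving
near-equal decile sizes), and report per-decile deletion rates relative to
decile 1, with CIs from within-decile bin resampling. Terminal partial
bins keep their true width. Individual filtering removes totals strictly
below the 10th or above the 90th percentile, computed with type-7 linear
interpolation (the convention matters at boundaries and is therefore
pinned).

# Reporter redesign

The recoding pass slides a 5-codon (15-base) window one codon at a time.
All synonymous combinations of the window's uncensored codons are
enumerated (standard nuclear code); each candidate is substituted into the
sequence and scored with 30 bp of flanking context so repeats crossing the
window edge are credited. The ranking key is **total tandem-dinucleotide
repeat bp** (maximal 2-periodic extents with a primitive unit, ≥ 4 bp),
then the longest such extent, then the longest mononucleotide run as a
deliberately deprioritized tiebreak, with final ties going to the
lexicographically smallest window. Total coverage leads the key because
the identity permutation is always among the candidates: the greedy can
then never reduce repeat content, a guarantee a longest-run-first key does
not provide (window-local choices can otherwise break repeats spanning
window boundaries). Codons actually changed are censored from later
windows.

Stop purging scans the +2 frame (the frame exposed by a 2 bp deletion or
1 bp insertion; +1 screening is a documented extension point). Each stop
straddles two codons; among synonymous pairs that remove it without
creating an earlier +2 stop, the pair losing the least repeat coverage is
chosen (ties: fewest changed bases, then lexicographic). Stops with no
synonymous fix are reported, not fatal; purging may edit previously
censored codons but never changes the protein.

# What the synthetic data does and does not emulate

The generators provide *controlled truth*, not realism. Background
sequence is i.i.d. at a set GC fraction — no higher-order Markov
structure, no isochores, no chromatin context; this suffices for the nulls
exercised here because both null models condition only on local repeat
content. Planted repeats are guarded so they cannot extend into their
flanks, keeping truth labels exact. Deletion planting records the
placement branch as its truth flag; note that the uniform branch can land
on TNT sites by chance, so the realized compliant fraction at bias `b` is
`b + (1−b)·f_bg` — the enrichment null (`observed = background`)
corresponds to `b = 0`, which is what the calibration suite uses.
Expression tables have log-normal gene levels shared across tissues with
mild sample noise, and HETR genes planted far above/below the thresholds;
deletion counts are Poisson with expectation ∝ span × TPM^coupling.
Signal tracks are baseline-plus-coupling×count with Gaussian replicate
noise. Passing tests therefore demonstrate correctness of the estimators
and the recovery of planted effects, not robustness to mapping artefacts,
calling errors, copy-number structure or covariate confounding in real
data.

Problem sizes in the test and acceptance suites — 2–60 kb genomes,
200–300 deletions per dataset, 100–500 simulation repetitions, 100–1,000
bootstrap replicates, 2,000–10,000 null pairs — were chosen as the
smallest sizes at which the statistical properties under test are
comfortably resolved.

# Known limitations

* Repeat annotation stops at unit length 5 and treats microsatellites
  (many-unit STRs) like any other repeat, with the SSTR cutoff exposed as
  a parameter (`sstr_max_units`, default 5 total units) because published
  definitions are ambiguous on this boundary.
* The Fisher "observed versus expected" construction is a modelling
  choice; exact printed p-values from equivalent analyses depend on how
  expected counts were scaled, which published methods rarely state.
* Insertions are carried through ID-83 spectra but receive no TNT or
  canonical-class annotation (the motif model concerns deletions).
* No liftover: all inputs must share one coordinate system. Mappability
  masks are inputs, never computed.
* `register_ambiguous` flags 2 bp deletions whose equivalent registers
  span different canonical classes (AT/TA repeats); the logo rule decides
  the reported class, and downstream users can exclude flagged calls.
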