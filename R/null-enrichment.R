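# Null models for TNT-motif enrichment: the uniform genomic null and the
# matched-repeat bootstrap, plus Fisher enrichment tests and multiple-testing
# adjustment.

#' Expected TNT fraction under uniform genomic deletion placement
#'
#' Delegates to [tnt_background_fraction()] with `context = "all"`: draws
#' `n_samples` uniformly placed d-bp deletions within the mappable mask and
#' scores TNT compliance.
#'
#' @inheritParams tnt_background_fraction
#' @return One-row tibble (`fraction`, binomial CI, `n`).
#' @export
genomic_null <- function(genome, mask = NULL, d, n_samples = 1e5,
                         seed = NULL) {
  tnt_background_fraction(genome, mask, d = d, context = "all",
                          n_samples = n_samples, seed = seed)
}

#' Build a repeat catalog for matched-repeat bootstrapping
#'
#' Annotates all STR and MH regions of a genome, recording for each the
#' matching keys used by the bootstrap (kind, unit length, total region
#' length) and whether the region contains the `T N^(d-1) T` motif for its
#' implied deletion length (`unit_length` for STRs, `d` for MH sites).
#'
#' @param genome Named character vector or [syn_genome].
#' @param d_values Deletion lengths for which MH regions are catalogued and
#'   motif columns computed.
#' @return Tibble with `seqname`, `start`, `end`, `kind`, `unit_length`,
#'   `total_length`, and one logical `has_tnt_<d>` column per deletion
#'   length.
#' @export
repeat_catalog <- function(genome, d_values = 2:5) {
  seqs <- genome_sequences(genome)
  strs <- purrr::map(names(seqs), function(sq) {
    find_tandem_repeats(seqs[[sq]], seqname = sq)
  }) |> bind_rows()
  if (nrow(strs) > 0) {
    strs <- strs |>
      mutate(total_length = .data$end - .data$start) |>
      select("seqname", "start", "end", "kind", "unit_length",
             "total_length")
  } else {
    strs <- NULL
  }
  mhs <- purrr::map(d_values, function(d) {
    purrr::map(names(seqs), function(sq) {
      find_mh_sites(seqs[[sq]], d = d, seqname = sq, drop_subsumed = TRUE)
    }) |> bind_rows() |>
      mutate(total_length = .data$end - .data$start) |>
      select("seqname", "start", "end", "kind", "unit_length",
             "total_length")
  }) |> bind_rows()
  cat_tbl <- bind_rows(strs, mhs)
  if (nrow(cat_tbl) == 0) {
    for (d in d_values) cat_tbl[[paste0("has_tnt_", d)]] <- logical(0)
    return(cat_tbl)
  }
  region_seq <- substr_regions(seqs, cat_tbl)
  for (d in d_values) {
    cat_tbl[[paste0("has_tnt_", d)]] <-
      grepl(paste0("T.{", d - 1, "}T"), region_seq)
  }
  cat_tbl
}

#' Matched-repeat bootstrap null for motif fractions
#'
#' For each observed deletion, every bootstrap replicate draws (uniformly,
#' with replacement) one genomic repeat matching the deletion's category key
#' - deletion length, repeat kind (STR/MH), repeat unit length and total
#' repeat length - and records whether the drawn repeat contains the
#' `T N^(d-1) T` motif. The replicate statistic is the motif fraction; the
#' empirical enrichment p-value is `(1 + #{replicates >= observed}) /
#' (B + 1)`.
#'
#' @param observed Classified deletions ([classify_deletions()] output)
#'   restricted to STR/SNMH context.
#' @param catalog Repeat catalog from [repeat_catalog()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return A list of class `tnt_bootstrap`: `replicates` (length-B motif
#'   fractions), `observed_fraction`, `p_value`, `B`, `keys` (per-category
#'   sizes), `seed`.
#' @export
matched_repeat_bootstrap <- function(observed, catalog, B = 1000,
                                     seed = NULL) {
  stopifnot(B >= 1)
  obs <- observed |>
    filter(.data$context %in% c("STR", "SNMH")) |>
    mutate(
      kind = ifelse(.data$context == "STR", "STR", "MH"),
      # catalogued STRs carry their primitive unit, so match on the
      # primitive period of the deleted unit
      unit_length = ifelse(
        .data$context == "STR",
        vapply(.data$deleted, primitive_period, integer(1)),
        .data$length
      ),
      total_length = ifelse(
        .data$context == "STR",
        .data$length * .data$repeat_copies,
        .data$length + 1L
      )
    )
  if (nrow(obs) == 0) abort("no STR/SNMH deletions to bootstrap")
  keys <- obs |>
    count(.data$length, .data$kind, .data$unit_length, .data$total_length,
          name = "n_obs")
  n_total <- sum(keys$n_obs)
  observed_fraction <- mean(obs$tnt_compliant)
  motif_counts <- matrix(0L, nrow = B, ncol = nrow(keys))
  with_seed(seed, {
    for (k in seq_len(nrow(keys))) {
      pool <- catalog |>
        filter(.data$kind == keys$kind[k],
               .data$unit_length == keys$unit_length[k],
               .data$total_length == keys$total_length[k])
      motif_col <- paste0("has_tnt_", min(keys$length[k], 5L))
      if (!motif_col %in% names(catalog)) {
        abort(paste0("catalog lacks motif column for d=", keys$length[k]))
      }
      if (nrow(pool) == 0) {
        abort(paste0(
          "no catalog repeat matches key (d=", keys$length[k], ", ",
          keys$kind[k], ", unit=", keys$unit_length[k], ", total=",
          keys$total_length[k], ")"
        ))
      }
      draws <- matrix(
        sample(pool[[motif_col]], keys$n_obs[k] * B, replace = TRUE),
        nrow = B
      )
      motif_counts[, k] <- rowSums(draws)
    }
  })
  replicates <- rowSums(motif_counts) / n_total
  p <- (1 + sum(replicates >= observed_fraction)) / (B + 1)
  structure(
    list(replicates = replicates, observed_fraction = observed_fraction,
         p_value = p, B = B, keys = keys, seed = seed),
    class = "tnt_bootstrap"
  )
}

#' @export
print.tnt_bootstrap <- function(x, ...) {
  cat("<tnt_bootstrap> B =", x$B,
      " observed =", signif(x$observed_fraction, 4),
      " null mean =", signif(mean(x$replicates), 4),
      " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Fisher enrichment test of an observed motif fraction against expectation
#'
#' Builds a 2x2 table comparing the observed motif/non-motif split against a
#' pseudo-cohort of equal size carrying the expected fraction, and applies a
#' two-sided Fisher's exact test. With `pseudo_cohort = "rounded"` (default)
#' the cohort is deterministic (`round(expected_fraction * observed_count)`
#' motif counts), which is reproducible but conservative: the expected
#' column has no sampling variance, so null p-values pile up above uniform.
#' With `pseudo_cohort = "sampled"` the cohort is drawn as
#' `Binomial(observed_count, expected_fraction)`, the standard
#' two-independent-binomials setting in which Fisher's test is
#' approximately calibrated.
#'
#' @param observed_count Total observed deletions.
#' @param observed_motif_count Observed motif-compliant deletions.
#' @param expected_fraction Expected compliant fraction under the null.
#' @param context,d Optional annotations carried into the result.
#' @param pseudo_cohort `"rounded"` (deterministic) or `"sampled"`.
#' @param seed RNG seed for the sampled cohort.
#' @return One-row tibble: `context`, `d`, `observed_count`,
#'   `observed_motif_count`, `expected_fraction`, `expected_motif_count`,
#'   `odds_ratio`, `p_value`.
#' @export
enrichment_test <- function(observed_count, observed_motif_count,
                            expected_fraction, context = NA_character_,
                            d = NA_integer_,
                            pseudo_cohort = c("rounded", "sampled"),
                            seed = NULL) {
  pseudo_cohort <- match.arg(pseudo_cohort)
  stopifnot(observed_count >= 0, observed_motif_count >= 0,
            observed_motif_count <= observed_count)
  check_scalar_prob(expected_fraction, "expected_fraction")
  if (observed_count == 0) {
    return(tibble(
      context = context, d = d, observed_count = 0L,
      observed_motif_count = 0L, expected_fraction = expected_fraction,
      expected_motif_count = NA_integer_,
      odds_ratio = NA_real_, p_value = 1
    ))
  }
  expected_motif <- if (pseudo_cohort == "rounded") {
    round(expected_fraction * observed_count)
  } else {
    with_seed(seed, rbinom(1, observed_count, expected_fraction))
  }
  tab <- matrix(c(
    observed_motif_count, observed_count - observed_motif_count,
    expected_motif, observed_count - expected_motif
  ), nrow = 2)
  ft <- fisher.test(tab)
  tibble(
    context = context, d = d,
    observed_count = as.integer(observed_count),
    observed_motif_count = as.integer(observed_motif_count),
    expected_fraction = expected_fraction,
    expected_motif_count = as.integer(expected_motif),
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}

#' Multiple-testing adjustment
#'
#' Thin, explicit wrapper over [stats::p.adjust()]: `"bonferroni"` gives
#' `min(1, m p)`; `"bh"` the Benjamini-Hochberg step-up FDR.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @param m Number of tests (defaults to `length(p_values)`).
#' @return Adjusted q-values, same length and order.
#' @export
adjust_pvalues <- function(p_values, method = c("bonferroni", "bh"),
                           m = length(p_values)) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni",
           n = max(m, length(p_values)))
}
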