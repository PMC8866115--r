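# Expression- and activity-stratified deletion rates: expression-group
# assignment, per-stratum rates c/(g n) with gene-bootstrap CIs,
# housekeeping-like and HETR gene definitions with enrichment odds ratios,
# activity-signal decile relative rates, and per-individual outlier
# filtering.

#' Summarise per-gene expression across tissues
#'
#' @param expr_table Long tibble `gene`, `tissue`, `sample`, `tpm`.
#' @return Tibble `gene`, `tissue`, `median_tpm` (within-tissue median),
#'   `other_median_tpm` (per-gene median over all other tissues' samples),
#'   plus per-tissue `q90` (90th quantile of within-tissue gene medians).
#' @export
tissue_expression_summary <- function(expr_table) {
  stopifnot(all(c("gene", "tissue", "tpm") %in% names(expr_table)))
  within <- expr_table |>
    summarise(median_tpm = median(.data$tpm), .by = c("gene", "tissue"))
  q90 <- within |>
    summarise(q90 = quantile(.data$median_tpm, 0.9, names = FALSE),
              .by = "tissue")
  other <- purrr::map(unique(expr_table$tissue), function(tt) {
    expr_table |>
      filter(.data$tissue != tt) |>
      summarise(other_median_tpm = median(.data$tpm), .by = "gene") |>
      mutate(tissue = tt)
  }) |> bind_rows()
  within |>
    left_join(q90, by = "tissue") |>
    left_join(other, by = c("gene", "tissue"))
}

#' Assign genes to expression groups
#'
#' Three schemes: `"deciles"` bins genes into 10 groups by median TPM;
#' `"housekeeping-deciles"` first restricts to genes with housekeeping-like
#' expression (maximal TPM below ten times the median TPM) and then decile
#' bins; `"germline-4"` collapses a supplied 1-9 expression group column
#' into unexpressed (1), low (2-4), mid (5-7) and high (8-9). Overlapping
#' genes (when `gene_spans` is supplied) are resolved hierarchically,
#' starting with the most abundant: only the most abundantly expressed gene
#' of an overlapping pair (highest median, ties by mean) is retained.
#'
#' @param expr_table Long tibble `gene`, `tissue`/`sample`, `tpm`; for
#'   `"germline-4"` instead a tibble `gene`, `group` with groups 1-9.
#' @param scheme `"deciles"`, `"housekeeping-deciles"` or `"germline-4"`.
#' @param gene_spans Optional tibble `gene`, `seqname`, `start`, `end` for
#'   overlap resolution.
#' @return Tibble `gene`, `group` (factor, ordered low to high),
#'   `median_tpm`, `mean_tpm` (NA for `"germline-4"`).
#' @export
assign_expression_groups <- function(expr_table,
                                     scheme = c("deciles",
                                                "housekeeping-deciles",
                                                "germline-4"),
                                     gene_spans = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "germline-4") {
    stopifnot(all(c("gene", "group") %in% names(expr_table)))
    if (!all(expr_table$group %in% 1:9)) {
      abort("germline-4 scheme expects input groups 1 to 9")
    }
    lab <- c("unexpressed", rep("low", 3), rep("mid", 3), rep("high", 2))
    return(tibble(
      gene = expr_table$gene,
      group = factor(lab[expr_table$group],
                     levels = c("unexpressed", "low", "mid", "high")),
      median_tpm = NA_real_, mean_tpm = NA_real_
    ))
  }
  stopifnot(all(c("gene", "tpm") %in% names(expr_table)))
  stats_tbl <- expr_table |>
    summarise(median_tpm = median(.data$tpm),
              mean_tpm = mean(.data$tpm),
              max_tpm = max(.data$tpm), .by = "gene")
  if (!is.null(gene_spans)) {
    stats_tbl <- resolve_overlapping_genes(stats_tbl, gene_spans)
  }
  if (scheme == "housekeeping-deciles") {
    stats_tbl <- filter(stats_tbl,
                        .data$max_tpm < 10 * pmax(.data$median_tpm, 1e-12))
  }
  if (nrow(stats_tbl) < 10) {
    abort("decile schemes need at least 10 genes after filtering")
  }
  if (all(stats_tbl$median_tpm == 0)) {
    abort("all-zero expression cannot be decile binned")
  }
  stats_tbl |>
    mutate(group = factor(
      dplyr::ntile(rank(.data$median_tpm, ties.method = "first"), 10),
      levels = 1:10
    )) |>
    select("gene", "group", "median_tpm", "mean_tpm")
}

# Hierarchical overlap resolution: repeatedly keep the most abundantly
# expressed gene and drop genes whose span overlaps it.
resolve_overlapping_genes <- function(stats_tbl, gene_spans) {
  tbl <- stats_tbl |>
    inner_join(gene_spans, by = "gene") |>
    arrange(desc(.data$median_tpm), desc(.data$mean_tpm))
  keep <- character(0)
  dropped <- rep(FALSE, nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    if (dropped[i]) next
    keep <- c(keep, tbl$gene[i])
    ov <- tbl$seqname == tbl$seqname[i] &
      tbl$start < tbl$end[i] & tbl$end > tbl$start[i]
    ov[i] <- FALSE
    dropped <- dropped | ov
  }
  filter(stats_tbl, .data$gene %in% keep)
}

#' Per-stratum deletion rates with gene-bootstrap CIs
#'
#' Counts deletions whose leftmost deleted base falls within the union span
#' of each expression group's genes; the rate is `c / (g n)` with `g` the
#' union span in bp and `n` the number of mutated genomes. The 95% CI comes
#' from resampling the group's genes with replacement `bootstrap_B` times
#' and taking the 0.025/0.975 quantiles of the recomputed rate.
#'
#' @param indels Deletions tibble (`seqname`, `pos`).
#' @param gene_spans Tibble `gene`, `seqname`, `start`, `end`.
#' @param groups Tibble `gene`, `group` (from
#'   [assign_expression_groups()]).
#' @param n_genomes Number of mutated genomes n.
#' @param bootstrap_B Bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return Tibble per group: `group`, `c`, `g`, `n`, `rate`, `ci_low`,
#'   `ci_high`.
#' @export
stratum_rates <- function(indels, gene_spans, groups, n_genomes,
                          bootstrap_B = 100, seed = NULL) {
  stopifnot(n_genomes >= 1)
  spans <- inner_join(gene_spans, groups, by = "gene")
  count_in <- function(sp) {
    if (nrow(sp) == 0 || nrow(indels) == 0) return(0L)
    hit <- purrr::map_int(seq_len(nrow(sp)), function(i) {
      sum(indels$seqname == sp$seqname[i] &
            indels$pos >= sp$start[i] & indels$pos < sp$end[i])
    })
    sum(hit)
  }
  with_seed(seed, {
    purrr::map(levels(droplevels(factor(spans$group))), function(gr) {
      sp <- filter(spans, .data$group == gr)
      g_span <- sum(sp$end - sp$start) # spans are non-overlapping post-resolution
      cc <- count_in(sp)
      if (g_span == 0) {
        return(tibble(group = gr, c = cc, g = 0, n = n_genomes,
                      rate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_))
      }
      rate <- cc / (g_span * n_genomes)
      boots <- vapply(seq_len(bootstrap_B), function(b) {
        bi <- sample.int(nrow(sp), nrow(sp), replace = TRUE)
        bsp <- sp[bi, ]
        bg <- sum(bsp$end - bsp$start)
        if (bg == 0) return(NA_real_)
        count_in(bsp) / (bg * n_genomes)
      }, numeric(1))
      qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      tibble(group = gr, c = cc, g = g_span, n = n_genomes, rate = rate,
             ci_low = qs[1], ci_high = qs[2])
    }) |> bind_rows()
  })
}

#' Highly expressed, tissue-restricted (HETR) genes for a tissue
#'
#' Genes whose within-tissue median TPM reaches the tissue's q90 threshold
#' (90th quantile of within-tissue gene medians) while their median over
#' all other tissues stays below `0.1 * q90`.
#'
#' @param summary Output of [tissue_expression_summary()].
#' @param tissue Tissue name.
#' @return Character vector of gene names (possibly empty).
#' @export
hetr_genes <- function(summary, tissue) {
  if (length(unique(summary$tissue)) < 2) {
    abort("HETR definition requires at least 2 tissues")
  }
  s <- filter(summary, .data$tissue == !!tissue)
  if (nrow(s) == 0) abort(paste0("unknown tissue '", tissue, "'"))
  s |>
    filter(.data$median_tpm >= .data$q90,
           .data$other_median_tpm < 0.1 * .data$q90) |>
    pull("gene")
}

#' HETR deletion-enrichment odds ratios across cancer-tissue pairs
#'
#' For each cancer type and tissue, builds the 2x2 table (deletions in the
#' tissue's HETR genes vs all other genes) x (cancer of interest vs all
#' other cancers) and applies a two-tailed Fisher's exact test. q-values are
#' Bonferroni-adjusted over all pairs tested; odds ratios below 1
#' (depletion) are additionally reported as reciprocals in
#' `display_value`.
#'
#' @param deletions_by_cancer Tibble `cancer`, `seqname`, `pos`.
#' @param hetr_sets Named list: tissue -> character vector of HETR genes.
#' @param gene_spans Tibble `gene`, `seqname`, `start`, `end`.
#' @param correction_m Number of tests for Bonferroni (defaults to the
#'   number of pairs tested).
#' @return Tibble per cancer-tissue pair with counts, `odds_ratio`, `p`,
#'   `q`, `display_value`.
#' @export
hetr_enrichment <- function(deletions_by_cancer, hetr_sets, gene_spans,
                            correction_m = NULL) {
  cancers <- unique(deletions_by_cancer$cancer)
  if (length(cancers) < 2) abort("need at least 2 cancer types")
  # assign each deletion to a gene by containment of its leftmost base
  assign_gene <- function(dels) {
    idx <- rep(NA_integer_, nrow(dels))
    for (i in seq_len(nrow(gene_spans))) {
      hit <- dels$seqname == gene_spans$seqname[i] &
        dels$pos >= gene_spans$start[i] & dels$pos < gene_spans$end[i]
      idx[hit & is.na(idx)] <- i
    }
    gene_spans$gene[idx]
  }
  dels <- mutate(deletions_by_cancer,
                 gene = assign_gene(deletions_by_cancer)) |>
    filter(!is.na(.data$gene))
  res <- purrr::map(cancers, function(ca) {
    purrr::map(names(hetr_sets), function(tt) {
      in_hetr <- dels$gene %in% hetr_sets[[tt]]
      of_cancer <- dels$cancer == ca
      a <- sum(in_hetr & of_cancer)
      b <- sum(!in_hetr & of_cancer)
      cc <- sum(in_hetr & !of_cancer)
      dd <- sum(!in_hetr & !of_cancer)
      tab <- matrix(c(a, b, cc, dd), nrow = 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        return(tibble(cancer = ca, tissue = tt, hetr_cancer = a,
                      other_cancer = b, hetr_rest = cc, other_rest = dd,
                      odds_ratio = NA_real_, p = 1))
      }
      ft <- fisher.test(tab)
      tibble(cancer = ca, tissue = tt, hetr_cancer = a, other_cancer = b,
             hetr_rest = cc, other_rest = dd,
             odds_ratio = unname(ft$estimate), p = ft$p.value)
    }) |> bind_rows()
  }) |> bind_rows()
  m <- if (is.null(correction_m)) nrow(res) else correction_m
  res |>
    mutate(
      q = adjust_pvalues(.data$p, "bonferroni", m = m),
      display_value = ifelse(!is.na(.data$odds_ratio) &
                               .data$odds_ratio < 1,
                             1 / .data$odds_ratio, .data$odds_ratio)
    )
}

#' Activity-signal decile relative deletion rates
#'
#' Averages the replicate signals per bin, divides by the bin's mappable
#' width to get signal per bp, assigns bins to signal deciles, and computes
#' the deletion rate (deletions per mappable bp) per decile relative to
#' decile 1. CIs come from resampling bins with replacement within deciles.
#'
#' @param signal Tibble `seqname`, `start`, `end`, `width`, `rep1`, `rep2`
#'   (from [simulate_signal_track()] or equivalent).
#' @param deletions Deletions tibble (`seqname`, `pos`).
#' @param mask Optional mask restricting mappable bp (default: whole bins).
#' @param bootstrap_B Bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @return Tibble `decile`, `n_bins`, `mappable_bp`, `deletions`, `rate`,
#'   `relative_rate`, `ci_low`, `ci_high` (relative; decile 1 is 1 by
#'   construction).
#' @export
signal_decile_rates <- function(signal, deletions, mask = NULL,
                                bootstrap_B = 200, seed = NULL) {
  bins <- signal
  if (!is.null(mask)) {
    bins$mappable <- purrr::map_dbl(seq_len(nrow(bins)), function(i) {
      m <- mask[mask$seqname == bins$seqname[i], ]
      sum(pmax(0, pmin(m$end, bins$end[i]) - pmax(m$start, bins$start[i])))
    })
  } else {
    bins$mappable <- bins$width
  }
  bins <- filter(bins, .data$mappable > 0)
  bins$signal_bp <- (bins$rep1 + bins$rep2) / 2 / bins$mappable
  bins$decile <- dplyr::ntile(rank(bins$signal_bp, ties.method = "first"),
                              10)
  bins$dels <- purrr::map_int(seq_len(nrow(bins)), function(i) {
    sum(deletions$seqname == bins$seqname[i] &
          deletions$pos >= bins$start[i] & deletions$pos < bins$end[i])
  })
  per_decile <- function(b) {
    b |>
      summarise(n_bins = dplyr::n(), mappable_bp = sum(.data$mappable),
                deletions = sum(.data$dels), .by = "decile") |>
      mutate(rate = .data$deletions / .data$mappable_bp) |>
      arrange(.data$decile)
  }
  obs <- per_decile(bins)
  ref <- obs$rate[obs$decile == 1]
  obs$relative_rate <- if (length(ref) == 1 && ref > 0) obs$rate / ref
                       else NA_real_
  boots <- with_seed(seed, {
    vapply(seq_len(bootstrap_B), function(b) {
      bb <- bins |>
        dplyr::group_by(.data$decile) |>
        dplyr::slice_sample(prop = 1, replace = TRUE) |>
        dplyr::ungroup()
      pd <- per_decile(bb)
      r1 <- pd$rate[pd$decile == 1]
      if (length(r1) != 1 || r1 == 0) return(rep(NA_real_, 10))
      out <- rep(NA_real_, 10)
      out[pd$decile] <- pd$rate / r1
      out
    }, numeric(10))
  })
  obs$ci_low <- apply(boots, 1, quantile, 0.025, na.rm = TRUE)[obs$decile]
  obs$ci_high <- apply(boots, 1, quantile, 0.975, na.rm = TRUE)[obs$decile]
  obs
}

#' Filter individuals by total-variant percentiles
#'
#' Removes individuals whose total count lies strictly below the
#' `low_pct`-th or strictly above the `high_pct`-th percentile (linear
#' interpolation between order statistics, `stats::quantile` type 7).
#' Idempotent on already-filtered input only when the percentile bounds do
#' not move; the retained set is returned, not re-thresholded.
#'
#' @param per_individual_counts Tibble `individual`, `total` (or a named
#'   numeric vector).
#' @param low_pct,high_pct Percentile bounds (defaults 10 and 90).
#' @return Tibble `individual`, `total`, `retained`.
#' @export
filter_individuals <- function(per_individual_counts, low_pct = 10,
                               high_pct = 90) {
  if (!is.data.frame(per_individual_counts)) {
    per_individual_counts <- tibble(
      individual = names(per_individual_counts) %||%
        seq_along(per_individual_counts),
      total = as.numeric(per_individual_counts)
    )
  }
  if (nrow(per_individual_counts) < 10) {
    abort("need at least 10 individuals for percentile filtering")
  }
  qs <- quantile(per_individual_counts$total,
                 c(low_pct, high_pct) / 100, names = FALSE)
  mutate(per_individual_counts,
         retained = .data$total >= qs[1] & .data$total <= qs[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
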