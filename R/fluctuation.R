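# Fluctuation-assay mutation-rate estimation: Lea-Coulson method of the
# median with rank-based nonparametric 95% CIs and per-bp / per-copy
# normalization.

# Solve r0/m - ln(m) = const for m. The left side is strictly decreasing in
# m, so the root is unique; r0 = 0 has no positive solution and is handled
# by the caller.
lea_coulson_m <- function(r0, constant = 1.24) {
  if (r0 <= 0) return(0)
  f <- function(m) r0 / m - log(m) - constant
  uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
}

#' Order-statistic ranks for a nonparametric CI on the median
#'
#' Returns the tightest symmetric pair of ranks `(j, n + 1 - j)` whose
#' coverage for the median under `Binomial(n, 0.5)` is at least `level`.
#' For 16 cultures at the 0.95 level this is the classical (4, 13) pair.
#'
#' @param n_cultures Number of cultures (>= 6 for level 0.95).
#' @param level Nominal coverage (default 0.95).
#' @return Named integer vector `c(rank_low, rank_high)`.
#' @export
#' @examples
#' median_ci_ranks(16)
median_ci_ranks <- function(n_cultures, level = 0.95) {
  stopifnot(n_cultures >= 1, level > 0, level < 1)
  n <- n_cultures
  best <- NA_integer_
  for (j in seq_len(floor((n + 1) / 2))) {
    coverage <- 1 - 2 * pbinom(j - 1, n, 0.5)
    if (coverage >= level) best <- j else break
  }
  if (is.na(best)) {
    # minimum n: smallest n with 1 - 2 * 0.5^n >= level
    n_min <- ceiling(-log2((1 - level) / 2))
    abort(paste0(
      "n_cultures = ", n, " cannot reach ", level * 100,
      "% coverage for a median CI; need at least ", n_min, " cultures"
    ))
  }
  c(rank_low = best, rank_high = n + 1L - best)
}

#' Lea-Coulson (method of the median) mutation-rate estimate
#'
#' Solves the median relation `r0/m - ln(m) = 1.24` for `m`, the expected
#' mutations per culture, where `r0` is the median mutant count. The
#' per-locus per-generation rate is `m / N_final` (total generations
#' approximated by the final population size, the standard fluctuation-assay
#' convention) and the per-bp rate divides further by the mutational target
#' size and reporter copy number. CI limits apply the same relation to the
#' mutant counts of the cultures at the nonparametric median CI ranks
#' ([median_ci_ranks()]), using each ranked culture's own final population.
#'
#' @param experiment Tibble with `mutant_count` and `n_final` per culture
#'   (a bare numeric vector of counts plus `n_final` argument also works).
#' @param n_final Scalar final population, used when `experiment` is a bare
#'   count vector or lacks an `n_final` column.
#' @param target_bp Mutational target size in bp (default 1032, the
#'   frameshift-productive reporter span).
#' @param copies Reporter copies per genome, 1 or 2 (default 1).
#' @param level CI level (default 0.95).
#' @param constant Median-equation constant (default 1.24).
#' @return A `fluctuation_fit` object; see [tidy.fluctuation_fit()].
#' @export
lea_coulson_estimate <- function(experiment, n_final = NULL,
                                 target_bp = 1032, copies = 1,
                                 level = 0.95, constant = 1.24) {
  if (is.numeric(experiment) && is.null(dim(experiment))) {
    experiment <- tibble(mutant_count = experiment)
  }
  counts <- experiment$mutant_count
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("mutant counts must be non-negative integers")
  }
  if (!"n_final" %in% names(experiment)) {
    if (is.null(n_final)) abort("supply `n_final` per culture or as scalar")
    experiment$n_final <- n_final
  }
  stopifnot(copies %in% c(1, 2), target_bp >= 1)
  n <- length(counts)
  r0 <- median(counts)
  m <- lea_coulson_m(r0, constant)
  N <- median(experiment$n_final)
  rate_locus <- m / N
  rate_bp <- rate_locus / (target_bp * copies)
  ord <- order(counts)
  ranks <- tryCatch(median_ci_ranks(n, level), error = function(e) NULL)
  if (!is.null(ranks)) {
    rate_at <- function(rank) {
      cnt <- counts[ord[rank]]
      mm <- lea_coulson_m(cnt, constant)
      mm / experiment$n_final[ord[rank]] / (target_bp * copies)
    }
    ci <- c(rate_at(ranks[1]), rate_at(ranks[2]))
  } else {
    ci <- c(NA_real_, NA_real_)
    ranks <- c(rank_low = NA_integer_, rank_high = NA_integer_)
  }
  structure(
    list(
      m = m, rate_per_locus = rate_locus, rate_per_bp = rate_bp,
      ci_low = ci[1], ci_high = ci[2],
      rank_low = unname(ranks[1]), rank_high = unname(ranks[2]),
      median_count = r0, n_cultures = n, n_final = N,
      target_bp = target_bp, copies = copies, level = level,
      constant = constant, below_detection = r0 == 0
    ),
    class = "fluctuation_fit"
  )
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat("<fluctuation_fit> n =", x$n_cultures,
      " median count =", x$median_count, "\n")
  cat("  m =", signif(x$m, 4),
      " rate/bp/gen =", signif(x$rate_per_bp, 4),
      " 95% CI [", signif(x$ci_low, 4), ",", signif(x$ci_high, 4), "]\n")
  if (x$below_detection) cat("  (median 0: below detection)\n")
  invisible(x)
}

#' Tidy a fluctuation fit
#'
#' @param x A `fluctuation_fit`.
#' @param ... Unused.
#' @return One-row tibble of estimates and CI.
#' @method tidy fluctuation_fit
#' @export
tidy.fluctuation_fit <- function(x, ...) {
  tibble(
    m = x$m, rate_per_bp = x$rate_per_bp, ci_low = x$ci_low,
    ci_high = x$ci_high, rank_low = x$rank_low, rank_high = x$rank_high,
    median_count = x$median_count, below_detection = x$below_detection
  )
}

#' @rdname tidy.fluctuation_fit
#' @method glance fluctuation_fit
#' @export
glance.fluctuation_fit <- function(x, ...) {
  tibble(
    n_cultures = x$n_cultures, n_final = x$n_final,
    target_bp = x$target_bp, copies = x$copies, level = x$level,
    constant = x$constant
  )
}

#' Fold change between two fluctuation-rate estimates
#'
#' @param estimate_a,estimate_b `fluctuation_fit` objects (numerator,
#'   denominator).
#' @return One-row tibble: `fold_change`, `ci_overlap` (do the rank CIs
#'   overlap), and flags for zero/undefined rates.
#' @export
rate_fold_change <- function(estimate_a, estimate_b) {
  ra <- estimate_a$rate_per_bp
  rb <- estimate_b$rate_per_bp
  fold <- if (rb > 0) ra / rb else if (ra > 0) Inf else NA_real_
  overlap <- !is.na(estimate_a$ci_low) && !is.na(estimate_b$ci_low) &&
    estimate_a$ci_low <= estimate_b$ci_high &&
    estimate_b$ci_low <= estimate_a$ci_high
  tibble(
    fold_change = fold,
    ci_overlap = overlap,
    a_below_detection = estimate_a$below_detection,
    b_below_detection = estimate_b$below_detection
  )
}
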