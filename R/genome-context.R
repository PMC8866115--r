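# Sequence-context annotation: short tandem repeats, single-base
# microhomology (MH) anchor sites, TNT-motif background fractions and
# composition-adjusted site context rates.

#' Find maximal short tandem repeats in a sequence
#'
#' Scans a DNA string for maximal tandem repeat runs with unit length in
#' `unit_lengths` and at least `min_copies` full copies. Runs are reported
#' once, with their smallest (primitive) unit; non-primitive representations
#' (e.g. `CTCTCT` as a 4-bp unit) are suppressed. Any `N` breaks a run.
#'
#' @param sequence DNA string over `ACGTN`.
#' @param unit_lengths Integer vector of repeat unit lengths, subset of 1:5.
#' @param min_copies Minimum number of full tandem copies (default 2).
#' @param seqname Sequence name recorded in the output.
#' @return A tibble with columns `seqname`, `start`, `end` (0-based
#'   half-open span of the full copies), `kind` (`"STR"`), `unit`,
#'   `unit_length`, `copies`. `end - start == unit_length * copies`.
#' @export
#' @examples
#' find_tandem_repeats("ACACACG")
find_tandem_repeats <- function(sequence, unit_lengths = 1:5, min_copies = 2,
                                seqname = "seq") {
  stopifnot(all(unit_lengths %in% 1:5), min_copies >= 2)
  if (is.na(sequence) || nchar(sequence) == 0) {
    return(empty_repeat_tbl())
  }
  if (!is_dna(sequence)) abort("`sequence` must be over the ACGTN alphabet")
  ch <- seq_chars(sequence)
  L <- length(ch)
  valid <- ch %in% DNA_BASES
  out <- list()
  for (r in sort(unique(unit_lengths))) {
    if (L < 2 * r) next
    i <- seq_len(L - r)
    eq <- ch[i] == ch[i + r] & valid[i] & valid[i + r]
    rl <- rle(eq)
    run_end <- cumsum(rl$lengths)
    run_start <- run_end - rl$lengths + 1
    keep <- which(rl$values)
    for (k in keep) {
      m <- rl$lengths[k]
      n_copies <- (m + r) %/% r
      if (n_copies < min_copies) next
      s0 <- run_start[k] - 1 # 0-based, left-anchored trim of partial copy
      unit <- substr(sequence, s0 + 1, s0 + r)
      if (!is_primitive_unit(unit)) next
      out[[length(out) + 1]] <- tibble(
        seqname = seqname, start = s0, end = s0 + r * n_copies,
        kind = "STR", unit = unit, unit_length = r, copies = n_copies
      )
    }
  }
  if (length(out) == 0) return(empty_repeat_tbl())
  bind_rows(out) |> arrange(.data$start, .data$unit_length)
}

empty_repeat_tbl <- function() {
  tibble(
    seqname = character(), start = integer(), end = integer(),
    kind = character(), unit = character(), unit_length = integer(),
    copies = integer()
  )
}

#' Find single-base microhomology anchor sites for d-bp deletions
#'
#' Reports every position `i` (0-based) where `sequence[i] == sequence[i + d]`
#' with all spanned bases unambiguous. Such an anchor pair `B . N^(d-1) . B`
#' supports a d-bp deletion with 1 bp of flanking homology. Sites whose whole
#' span lies inside an annotated tandem repeat are flagged
#' (`subsumed_by_str`): repeat context takes precedence over microhomology.
#' The anchor base is recorded for any `B`; whether `B == T` (the
#' TNT-compliant case) is scored downstream.
#'
#' @param sequence DNA string.
#' @param d Deletion length, 2 to 5.
#' @param seqname Sequence name recorded in the output.
#' @param drop_subsumed Drop STR-subsumed sites instead of flagging
#'   (default `FALSE`).
#' @return Tibble with `seqname`, `start`, `end` (0-based half-open span of
#'   length `d + 1` covering both anchors), `kind` (`"MH"`), `unit_length`
#'   (= `d`), `anchor_base`, `anchor_is_t`, `subsumed_by_str`.
#' @export
#' @examples
#' find_mh_sites("AGTCTGA", d = 2)
find_mh_sites <- function(sequence, d, seqname = "seq", drop_subsumed = FALSE) {
  stopifnot(length(d) == 1, d >= 2, d <= 5)
  empty <- tibble(
    seqname = character(), start = integer(), end = integer(),
    kind = character(), unit_length = integer(), anchor_base = character(),
    anchor_is_t = logical(), subsumed_by_str = logical()
  )
  if (is.na(sequence) || nchar(sequence) < d + 1) return(empty)
  ch <- seq_chars(sequence)
  L <- length(ch)
  valid <- ch %in% DNA_BASES
  i <- seq_len(L - d)
  all_valid <- vapply(i, function(j) all(valid[j:(j + d)]), logical(1))
  hit <- which(ch[i] == ch[i + d] & all_valid)
  if (length(hit) == 0) return(empty)
  strs <- find_tandem_repeats(sequence, seqname = seqname)
  start0 <- hit - 1
  end0 <- hit + d
  subsumed <- vapply(seq_along(hit), function(k) {
    any(strs$start <= start0[k] & strs$end >= end0[k])
  }, logical(1))
  out <- tibble(
    seqname = seqname, start = start0, end = end0, kind = "MH",
    unit_length = as.integer(d), anchor_base = ch[hit],
    anchor_is_t = ch[hit] == "T", subsumed_by_str = subsumed
  )
  if (drop_subsumed) out <- filter(out, !.data$subsumed_by_str)
  out
}

#' Genome-background TNT-compliant fraction for d-bp deletions
#'
#' For `context = "all"`, draws `n_samples` uniformly placed d-bp deletions
#' within the mappable mask, scores each for TNT compliance with the
#' deletion classifier, and returns the compliant fraction with a binomial
#' normal-approximation CI. For `context = "STR"` or `"MH"` the fraction is
#' deterministic: the proportion of annotated STR (or MH) sequence, fully
#' inside the mask, whose region contains the `T N^(d-1) T` motif,
#' bp-weighted.
#'
#' @param genome A [syn_genome] object or named character vector of
#'   sequences.
#' @param mask Optional mask tibble (`seqname`, `start`, `end`); defaults to
#'   the genome's own mask or whole sequences.
#' @param d Deletion length (2-5).
#' @param context `"all"`, `"STR"` or `"MH"`.
#' @param n_samples Number of sampled deletions for `context = "all"`.
#' @param seed RNG seed for the sampling branch.
#' @param sstr_max_units Total-unit cutoff distinguishing short-short tandem
#'   repeats from microsatellites (default 5 units).
#' @return One-row tibble: `context`, `d`, `fraction`, `ci_low`, `ci_high`,
#'   `n` (samples or total bp).
#' @export
tnt_background_fraction <- function(genome, mask = NULL, d, context = "all",
                                    n_samples = 1e5, seed = NULL,
                                    sstr_max_units = 5) {
  seqs <- genome_sequences(genome)
  mask <- resolve_mask(genome, mask)
  context <- match.arg(context, c("all", "STR", "MH"))
  if (context == "all") {
    if (mask_width(mask) < 1000) {
      abort("mappable genome below 1 kb; background sampling unsupported")
    }
    dels <- with_seed(seed, sample_mask_positions(mask, d, n_samples))
    cls <- classify_deletions(dels, seqs)
    p <- mean(cls$tnt_compliant)
    se <- sqrt(p * (1 - p) / n_samples)
    return(tibble(
      context = context, d = d, fraction = p,
      ci_low = max(0, p - 1.96 * se), ci_high = min(1, p + 1.96 * se),
      n = n_samples
    ))
  }
  regions <- purrr::map(names(seqs), function(sq) {
    if (context == "STR") {
      r <- find_tandem_repeats(seqs[[sq]], seqname = sq)
      filter(r, .data$copies <= sstr_max_units)
    } else {
      find_mh_sites(seqs[[sq]], d = d, seqname = sq, drop_subsumed = TRUE)
    }
  }) |> bind_rows()
  if (nrow(regions) == 0) {
    return(tibble(context = context, d = d, fraction = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, n = 0))
  }
  regions <- filter(regions, region_in_mask(regions, mask))
  if (nrow(regions) == 0) {
    return(tibble(context = context, d = d, fraction = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, n = 0))
  }
  motif <- paste0("T.{", d - 1, "}T")
  seqs_of <- substr_regions(seqs, regions)
  has <- grepl(motif, seqs_of)
  w <- regions$end - regions$start
  frac <- sum(w[has]) / sum(w)
  tibble(context = context, d = d, fraction = frac,
         ci_low = NA_real_, ci_high = NA_real_, n = sum(w))
}

region_in_mask <- function(regions, mask) {
  vapply(seq_len(nrow(regions)), function(i) {
    m <- mask[mask$seqname == regions$seqname[i], ]
    any(m$start <= regions$start[i] & m$end >= regions$end[i])
  }, logical(1))
}

substr_regions <- function(seqs, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    substr(seqs[[regions$seqname[i]]], regions$start[i] + 1, regions$end[i])
  }, character(1))
}

# Uniform d-bp deletion starts within mask intervals, as a deletions tibble.
sample_mask_positions <- function(mask, d, n) {
  m <- mask[mask$end - mask$start >= d, ]
  if (nrow(m) == 0) abort("no mask interval can hold a deletion of this length")
  w <- m$end - m$start - d + 1
  idx <- sample.int(nrow(m), n, replace = TRUE, prob = w)
  pos <- m$start[idx] + floor(runif(n) * w[idx])
  tibble(seqname = m$seqname[idx], pos = as.integer(pos),
         length = as.integer(d))
}

#' Composition-adjusted dinucleotide context rates
#'
#' For a set of single-base sites (e.g. embedded-ribonucleotide positions),
#' computes the relative incorporation rate per dinucleotide context (5'
#' neighbour + reported base, strand-resolved), adjusted for genome
#' composition. Rates are `site_count / genome_count` normalized to sum to 1,
#' so an unbiased site set gives every context a rate near `1/n`.
#'
#' @param sites Tibble with `seqname`, `pos` (0-based position of the
#'   reported base) and `strand` (`"+"` or `"-"`).
#' @param genome Named character vector of sequences or [syn_genome].
#' @return Tibble `context`, `site_count`, `genome_count`, `relative_rate`
#'   (sums to 1).
#' @export
context_relative_rates <- function(sites, genome) {
  seqs <- genome_sequences(genome)
  stopifnot(all(c("seqname", "pos") %in% names(sites)))
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  ctx <- vapply(seq_len(nrow(sites)), function(i) {
    s <- seqs[[sites$seqname[i]]]
    p <- sites$pos[i] # 0-based
    if (is.null(s) || p < 0 || p >= nchar(s)) {
      abort("site position out of bounds")
    }
    if (strand[i] == "+") {
      if (p == 0) return(NA_character_)
      substr(s, p, p + 1)
    } else {
      if (p + 2 > nchar(s)) return(NA_character_)
      revcomp(substr(s, p + 1, p + 2))
    }
  }, character(1))
  ctx <- ctx[!is.na(ctx) & is_dna(ctx, allow_n = FALSE)]
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  site_count <- table(factor(ctx, levels = dinucs))
  fwd <- dinucleotide_counts(seqs)
  genome_count <- fwd[dinucs] + fwd[revcomp(dinucs)]
  bad <- genome_count == 0 & site_count > 0
  if (any(bad)) {
    abort(paste("context absent from genome but observed at sites:",
                paste(dinucs[bad], collapse = ", ")))
  }
  raw <- ifelse(genome_count > 0, as.numeric(site_count) / genome_count, 0)
  tibble(
    context = dinucs,
    site_count = as.integer(site_count),
    genome_count = as.integer(genome_count),
    relative_rate = if (sum(raw) > 0) raw / sum(raw) else raw
  )
}

dinucleotide_counts <- function(seqs) {
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  counts <- setNames(numeric(16), dinucs)
  for (s in seqs) {
    ch <- seq_chars(s)
    if (length(ch) < 2) next
    di <- paste0(ch[-length(ch)], ch[-1])
    tab <- table(factor(di, levels = dinucs))
    counts <- counts + as.numeric(tab)
  }
  counts
}

# Resolve sequences from either a syn_genome or a named character vector.
genome_sequences <- function(genome) {
  if (inherits(genome, "syn_genome")) return(genome$sequences)
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort("`genome` must be a syn_genome or a named character vector")
}

resolve_mask <- function(genome, mask) {
  seqs <- genome_sequences(genome)
  if (is.null(mask)) {
    if (inherits(genome, "syn_genome") && !is.null(genome$mask)) {
      mask <- genome$mask
    } else {
      mask <- tibble(
        seqname = names(seqs), start = 0L,
        end = as.integer(nchar(unname(seqs)))
      )
    }
  }
  check_mask(mask, seqs)
  mask
}
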