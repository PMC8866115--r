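# Brute-force oracles, written against the documented definitions with
# plain string operations, independent of the package's scanning code.

random_seq <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_substr <- function(s, start0, len) substr(s, start0 + 1, start0 + len)

# Smallest-period check by direct string division.
oracle_primitive <- function(unit) {
  r <- nchar(unit)
  if (r == 1) return(TRUE)
  for (p in seq_len(r - 1)) {
    if (r %% p == 0 &&
        paste(rep(substr(unit, 1, p), r / p), collapse = "") == unit) {
      return(FALSE)
    }
  }
  TRUE
}

# Every (start, r, n) triple tested directly: report left-anchored maximal
# tandem runs with primitive units and >= min_copies full copies.
oracle_repeats <- function(s, unit_lengths = 1:5, min_copies = 2) {
  L <- nchar(s)
  out <- list()
  for (r in unit_lengths) {
    for (start in 0:(L - 2 * r)) {
      unit <- oracle_substr(s, start, r)
      if (grepl("N", unit) || !oracle_primitive(unit)) next
      # periodic run must not extend left by a single base
      if (start >= 1) {
        prev <- oracle_substr(s, start - 1, 1)
        mate <- oracle_substr(s, start - 1 + r, 1)
        if (prev == mate && prev != "N") next
      }
      n <- 1
      while (start + (n + 1) * r <= L &&
             oracle_substr(s, start + n * r, r) == unit) {
        n <- n + 1
      }
      if (n >= min_copies) {
        out[[length(out) + 1]] <-
          data.frame(start = start, end = start + r * n, unit = unit,
                     unit_length = r, copies = n)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), unit_length = integer(),
                      copies = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

# All anchor-pair microhomology positions for a d-bp deletion.
oracle_mh_starts <- function(s, d) {
  L <- nchar(s)
  hits <- integer(0)
  for (i in 0:(L - d - 1)) {
    span <- oracle_substr(s, i, d + 1)
    if (grepl("N", span)) next
    if (substr(span, 1, 1) == substr(span, d + 1, d + 1)) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Full classification of a single deletion by literal string manipulation.
oracle_classify <- function(s, pos0, d) {
  L <- nchar(s)
  del <- oracle_substr(s, pos0, d)
  if (grepl("N", del)) {
    return(list(context = "other", repeat_copies = 1L, mh_length = 0L,
                tnt = NA, overlaps_n = TRUE))
  }
  # equivalent registers: the contiguous run of starts whose deletion
  # leaves the same string, found by literal string comparison outward
  # from pos0
  after <- function(p) paste0(substr(s, 1, p), substr(s, p + d + 1, L))
  target <- after(pos0)
  same <- function(p) {
    p >= 0 && p + d <= L && !grepl("N", oracle_substr(s, p, d)) &&
      after(p) == target
  }
  lo <- pos0
  while (same(lo - 1)) lo <- lo - 1
  hi <- pos0
  while (same(hi + 1)) hi <- hi + 1
  regs <- lo:hi

  copies <- 1L
  k <- pos0 - d
  while (k >= 0 && oracle_substr(s, k, d) == del) {
    copies <- copies + 1L
    k <- k - d
  }
  k <- pos0 + d
  while (k + d <= L && oracle_substr(s, k, d) == del) {
    copies <- copies + 1L
    k <- k + d
  }
  mh3 <- 0L
  while (mh3 < d && substr(s, pos0 + d + mh3 + 1, pos0 + d + mh3 + 1) ==
         substr(del, mh3 + 1, mh3 + 1) &&
         pos0 + d + mh3 + 1 <= L) {
    mh3 <- mh3 + 1L
  }
  mh5 <- 0L
  while (mh5 < d && pos0 - mh5 >= 1 &&
         substr(s, pos0 - mh5, pos0 - mh5) ==
         substr(del, d - mh5, d - mh5)) {
    mh5 <- mh5 + 1L
  }
  mh <- max(mh3, mh5)
  context <- if (copies >= 2) "STR" else if (mh >= 1) "SNMH" else "other"
  if (d == 2 || context == "other") {
    # either-strand reading: T..T with 5' T, or (complement) A..A with 3' A
    tnt <- any(vapply(regs, function(p) {
      (p > 0 && substr(s, p, p) == "T" &&
         substr(s, p + d, p + d) == "T") ||
        (p + d < L && substr(s, p + 1, p + 1) == "A" &&
           substr(s, p + d + 1, p + d + 1) == "A")
    }, logical(1)))
  } else {
    region <- substr(s, min(regs) + 1, max(regs) + d)
    tnt <- grepl(paste0("T.{", d - 1, "}T"), region) ||
      grepl(paste0("A.{", d - 1, "}A"), region)
  }
  if (d < 2 || d > 5) tnt <- NA
  list(context = context, repeat_copies = copies, mh_length = mh,
       tnt = tnt, overlaps_n = FALSE, registers = regs)
}

# Right-alignment / orientation rule applied literally.
oracle_canonical_window <- function(s, regs, flank = 5) {
  t_regs <- regs[vapply(regs, function(p) {
    substr(s, p + 2, p + 2) == "T"
  }, logical(1))]
  ra <- if (length(t_regs) > 0) max(t_regs) else max(regs)
  lo <- ra - flank + 1
  hi <- ra + 2 + flank
  w <- paste0(
    strrep("N", max(0, 1 - lo)),
    substr(s, max(1, lo), min(nchar(s), hi)),
    strrep("N", max(0, hi - nchar(s)))
  )
  del <- substr(s, ra + 1, ra + 2)
  if (grepl("A", del) && !del %in% c("AT", "TA")) {
    w <- oracle_revcomp(w)
  }
  list(window = w, ra = ra)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Scoring key recomputed by direct enumeration of 2-periodic substrings:
# (union coverage of primitive 2-periodic extents, longest extent, longest
# mononucleotide run).
oracle_dinuc_key <- function(s) {
  L <- nchar(s)
  cov <- rep(FALSE, L)
  longest <- 0
  for (i in 1:max(1, L - 3)) {
    if (L - i + 1 < 4) break
    # maximal 2-periodic extent starting at i
    j <- i + 2
    while (j <= L && substr(s, j, j) == substr(s, j - 2, j - 2)) j <- j + 1
    M <- (j - 1) - i + 1
    if (M >= 4 && substr(s, i, i) != substr(s, i + 1, i + 1)) {
      # only count if not extendable left (maximal)
      if (i == 1 || substr(s, i - 1, i - 1) != substr(s, i + 1, i + 1)) {
        cov[i:(i + M - 1)] <- TRUE
        longest <- max(longest, M)
      }
    }
  }
  mono <- max(rle(strsplit(s, "")[[1]])$lengths)
  c(sum(cov), longest, mono)
}

# Greedy left-to-right pass with an exhaustive per-window argmax under the
# documented ranking key (candidates scored in 30 bp flanking context).
oracle_greedy_redesign <- function(cds, window = 5, context_bp = 30) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  n <- length(codons)
  censored <- logical(n)
  syn <- function(codon) {
    aa <- top1tam:::CODON_AA
    names(aa)[aa == aa[[codon]]]
  }
  for (w in seq_len(n - window + 1)) {
    idx <- w:(w + window - 1)
    syns <- lapply(idx, function(i) {
      if (censored[i]) codons[i] else syn(codons[i])
    })
    combos <- expand.grid(syns, stringsAsFactors = FALSE)
    cand <- do.call(paste0, combos)
    current <- paste(codons, collapse = "")
    lo <- (w - 1) * 3 + 1
    hi <- lo + window * 3 - 1
    left <- substr(current, max(1, lo - context_bp), lo - 1)
    right <- substr(current, hi + 1, min(nchar(current), hi + context_bp))
    keys <- t(vapply(paste0(left, cand, right), oracle_dinuc_key,
                     numeric(3)))
    ord <- order(-keys[, 1], -keys[, 2], -keys[, 3], cand)
    best <- as.character(combos[ord[1], ])
    changed <- idx[best != codons[idx]]
    codons[idx] <- best
    censored[changed] <- TRUE
  }
  paste(codons, collapse = "")
}

# Textbook multiple-testing adjustments.
oracle_bonferroni <- function(p, m = length(p)) pmin(1, p * m)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
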