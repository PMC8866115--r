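# In silico reporter redesign: synonymous recoding to maximize tandem
# dinucleotide repeat content, followed by removal of stop codons exposed
# by a +2 frameshift.

# Standard nuclear genetic code.
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  setNames(aas, codons)
}

CODON_AA <- codon_table()
STOP_CODONS <- names(CODON_AA)[CODON_AA == "*"]

translate_cds <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(CODON_AA[codons], collapse = "")
}

synonyms_of <- function(codon) {
  names(CODON_AA)[CODON_AA == CODON_AA[[codon]]]
}

check_cds <- function(cds) {
  if (!is_dna(cds, allow_n = FALSE)) {
    abort("CDS must be unambiguous (ACGT only)")
  }
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  internal <- head(codons, -1)
  if (any(internal %in% STOP_CODONS)) {
    abort("CDS contains an internal stop codon")
  }
  codons
}

# Maximal 2-periodic extents with a primitive (non-homopolymer) unit and
# length >= 4: the spans counted as tandem dinucleotide repeat sequence.
dinuc_extents <- function(ch) {
  L <- length(ch)
  if (L < 4) return(NULL)
  i <- seq_len(L - 2)
  eq <- ch[i] == ch[i + 2]
  rl <- rle(eq)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  keep <- which(rl$values)
  out <- NULL
  for (k in keep) {
    M <- rl$lengths[k] + 2
    i0 <- starts[k]
    if (M >= 4 && ch[i0] != ch[i0 + 1]) {
      out <- rbind(out, c(i0, i0 + M - 1)) # 1-based inclusive
    }
  }
  out
}

# Ranking key for candidate sequences: (total bp covered by tandem
# dinucleotide extents, longest such extent, longest mononucleotide run),
# compared lexicographically; ties broken by the lexicographically smallest
# window. Total coverage leads so that a greedy pass over candidates that
# always include the identity permutation can never lose repeat content.
dinuc_score <- function(ch) {
  ext <- dinuc_extents(ch)
  mono <- max(rle(ch)$lengths)
  if (is.null(ext)) return(c(0, 0, mono))
  cov <- logical(length(ch))
  for (r in seq_len(nrow(ext))) cov[ext[r, 1]:ext[r, 2]] <- TRUE
  c(sum(cov), max(ext[, 2] - ext[, 1] + 1), mono)
}

#' Fraction of a sequence inside tandem dinucleotide repeats
#'
#' Bases covered by maximal 2-periodic runs with a primitive unit (i.e.
#' true dinucleotide repeats, homopolymers excluded) of length >= 4 bp,
#' divided by sequence length.
#'
#' @param cds DNA string.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' repeat_content("CTCTCT")
repeat_content <- function(cds) {
  ch <- seq_chars(cds)
  ext <- dinuc_extents(ch)
  if (is.null(ext)) return(0)
  cov <- logical(length(ch))
  for (r in seq_len(nrow(ext))) cov[ext[r, 1]:ext[r, 2]] <- TRUE
  sum(cov) / length(ch)
}

#' Maximize tandem dinucleotide repeat content by synonymous recoding
#'
#' Slides a `window_codons` window one codon at a time, left to right.
#' Within each window all synonymous codon combinations (censored codons
#' held fixed) are enumerated; each candidate is substituted into the
#' sequence and scored together with `context_bp` bases of flanking
#' context, so repeats crossing the window edges are credited. The ranking
#' key is: total tandem-dinucleotide-repeat bp, then the longest such
#' extent, then the longest mononucleotide run as a deprioritized tiebreak,
#' final ties going to the lexicographically smallest window. Because the
#' identity permutation is always a candidate and total repeat coverage
#' leads the key, repeat content never decreases. The winning combination
#' replaces whole codons; codons actually changed are censored from
#' subsequent windows. The protein sequence is preserved exactly.
#'
#' @param cds Coding sequence (length divisible by 3, no internal stop,
#'   unambiguous).
#' @param window_codons Sliding window width in codons (default 5).
#' @param context_bp Flanking bases included when scoring a candidate
#'   window (default 30).
#' @return A `reporter_redesign` object: `input_cds`, `output_cds`,
#'   `edited_codons` (1-based indices), `sstr_fraction_input`,
#'   `sstr_fraction`, `frameshift_stop_free`, `residual_stops`.
#' @export
maximize_dinucleotide_repeats <- function(cds, window_codons = 5,
                                          context_bp = 30) {
  codons <- check_cds(cds)
  n <- length(codons)
  censored <- logical(n)
  edited <- integer(0)
  if (n >= window_codons) {
    for (w in seq_len(n - window_codons + 1)) {
      idx <- w:(w + window_codons - 1)
      syns <- lapply(idx, function(i) {
        if (censored[i]) codons[i] else synonyms_of(codons[i])
      })
      combos <- expand.grid(syns, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
      cand <- do.call(paste0, combos)
      current <- paste(codons, collapse = "")
      lo <- (w - 1) * 3 + 1
      hi <- lo + window_codons * 3 - 1
      left <- substr(current, max(1, lo - context_bp), lo - 1)
      right <- substr(current, hi + 1, min(nchar(current), hi + context_bp))
      scores <- t(vapply(
        strsplit(paste0(left, cand, right), "", fixed = TRUE),
        dinuc_score, numeric(3)
      ))
      ord <- order(-scores[, 1], -scores[, 2], -scores[, 3], cand)
      best <- ord[1]
      new_codons <- as.character(combos[best, ])
      changed <- idx[new_codons != codons[idx]]
      if (length(changed) > 0) {
        codons[idx] <- new_codons
        censored[changed] <- TRUE
        edited <- c(edited, changed)
      }
    }
  }
  out <- paste(codons, collapse = "")
  stopifnot(translate_cds(out) == translate_cds(cds))
  new_redesign(cds, out, sort(unique(edited)))
}

frameshift2_stops <- function(cds) {
  L <- nchar(cds)
  if (L < 5) return(integer(0))
  q <- seq(3, L - 2, by = 3) # 1-based starts of +2 frame triplets
  q[substring(cds, q, q + 2) %in% STOP_CODONS]
}

new_redesign <- function(input_cds, output_cds, edited,
                         residual = frameshift2_stops(output_cds)) {
  structure(
    list(
      input_cds = input_cds, output_cds = output_cds,
      edited_codons = edited,
      sstr_fraction_input = repeat_content(input_cds),
      sstr_fraction = repeat_content(output_cds),
      residual_stops = residual,
      frameshift_stop_free = length(residual) == 0
    ),
    class = "reporter_redesign"
  )
}

#' @export
print.reporter_redesign <- function(x, ...) {
  cat("<reporter_redesign>", nchar(x$input_cds) / 3, "codons;",
      length(x$edited_codons), "edited\n")
  cat("  dinucleotide repeat fraction:",
      signif(x$sstr_fraction_input, 3), "->", signif(x$sstr_fraction, 3),
      "\n")
  cat("  +2-frame stops remaining:", length(x$residual_stops), "\n")
  invisible(x)
}

#' Remove stop codons exposed by a +2 frameshift
#'
#' Scans the +2 reading frame (the frame exposed by a 2 bp deletion or a
#' 1 bp insertion) for stop triplets. Each stop straddles two codons; all
#' synonymous substitutions of that codon pair are enumerated, and among
#' those that remove the stop without creating a new +2-frame stop earlier
#' in the sequence, the one losing the least tandem-repeat coverage is
#' applied (ties: fewest changed bases, then lexicographically smallest).
#' Stops with no synonymous fix are reported in `residual_stops`, not
#' fatal. The protein sequence is preserved exactly.
#'
#' @param cds Coding sequence (or a `reporter_redesign`, whose output is
#'   taken up).
#' @return A `reporter_redesign` object (see
#'   [maximize_dinucleotide_repeats()]); `edited_codons` lists codons
#'   changed by this step (plus any prior step's when chained).
#' @export
purge_frameshift_stops <- function(cds) {
  prior_edits <- integer(0)
  input_cds <- cds
  if (inherits(cds, "reporter_redesign")) {
    prior_edits <- cds$edited_codons
    input_cds <- cds$input_cds
    cds <- cds$output_cds
  }
  codons <- check_cds(cds)
  n <- length(codons)
  edited <- integer(0)
  unresolved <- integer(0)
  for (pass in seq_len(4 * n + 10)) { # one stop handled per pass
    current <- paste(codons, collapse = "")
    stops <- setdiff(frameshift2_stops(current), unresolved)
    if (length(stops) == 0) break
    q <- stops[1]
    k <- (q - 1) %/% 3 + 1 # codon carrying the triplet's first base
    if (k + 1 > n) {
      unresolved <- c(unresolved, q)
      next
    }
    pair_syns <- expand.grid(synonyms_of(codons[k]),
                             synonyms_of(codons[k + 1]),
                             stringsAsFactors = FALSE)
    lo <- (k - 1) * 3 + 1
    old_pair <- substr(current, lo, lo + 5)
    fixed <- logical(nrow(pair_syns))
    keys <- matrix(0, nrow(pair_syns), 2)
    cand_seqs <- character(nrow(pair_syns))
    for (r in seq_len(nrow(pair_syns))) {
      cand <- current
      substr(cand, lo, lo + 5) <- paste0(pair_syns[r, 1], pair_syns[r, 2])
      cand_seqs[r] <- cand
      new_stops <- setdiff(frameshift2_stops(cand), unresolved)
      fixed[r] <- !(q %in% new_stops) && (length(new_stops) == 0 ||
                                            min(new_stops) > q)
      keys[r, 1] <- repeat_content(cand)
      keys[r, 2] <- -sum(seq_chars(paste0(pair_syns[r, 1],
                                          pair_syns[r, 2])) !=
                           seq_chars(old_pair))
    }
    if (!any(fixed)) {
      unresolved <- c(unresolved, q)
      next
    }
    ok <- which(fixed)
    ord <- ok[order(-keys[ok, 1], -keys[ok, 2], cand_seqs[ok])]
    r <- ord[1]
    changed <- c(k, k + 1)[c(pair_syns[r, 1] != codons[k],
                             pair_syns[r, 2] != codons[k + 1])]
    codons[k] <- pair_syns[r, 1]
    codons[k + 1] <- pair_syns[r, 2]
    edited <- c(edited, changed)
  }
  out <- paste(codons, collapse = "")
  stopifnot(translate_cds(out) == translate_cds(cds))
  new_redesign(input_cds, out, sort(unique(c(prior_edits, edited))),
               residual = unresolved)
}
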