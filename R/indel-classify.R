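# Deletion normalization, repeat/microhomology classification, canonical
# dinucleotide classes and TNT-motif compliance scoring.
#
# Deletion calls are tibbles with columns `seqname`, `pos` (0-based start of
# the deleted bases) and `length`; insertions additionally carry `type =
# "insertion"` and an `inserted` sequence. VCF conversion is centralized in
# io.R.

#' Normalize (left-align) deletion calls
#'
#' Shifts each deletion to its leftmost equivalent register: while the base
#' immediately 5' of the deletion equals the last deleted base, the deletion
#' can slide left without changing the resulting sequence. Idempotent; the
#' parsimonious `pos`/`length` representation is assumed (anchor bases are
#' handled by the VCF converters).
#'
#' @param deletions Tibble with `seqname`, `pos` (0-based), `length`.
#' @param genome Named character vector of sequences or [syn_genome].
#' @return The input tibble with `pos` left-aligned and a `deleted` column
#'   holding the deleted reference bases.
#' @export
normalize_indels <- function(deletions, genome) {
  seqs <- genome_sequences(genome)
  if (nrow(deletions) == 0) {
    return(mutate(deletions, deleted = character(0)))
  }
  chs <- lapply(seqs, seq_chars)
  pos <- integer(nrow(deletions))
  deleted <- character(nrow(deletions))
  for (i in seq_len(nrow(deletions))) {
    ch <- chs[[deletions$seqname[i]]]
    if (is.null(ch)) abort(paste0("unknown sequence ", deletions$seqname[i]))
    s <- deletions$pos[i]
    d <- deletions$length[i]
    if (s < 0 || s + d > length(ch)) {
      abort(paste0("deletion out of bounds at ", deletions$seqname[i], ":", s))
    }
    if ("deleted" %in% names(deletions) &&
        !is.na(deletions$deleted[i]) &&
        paste(ch[(s + 1):(s + d)], collapse = "") != deletions$deleted[i]) {
      abort(paste0("reference mismatch at ", deletions$seqname[i], ":", s))
    }
    while (s > 0 && ch[s] %in% DNA_BASES && ch[s] == ch[s + d]) s <- s - 1
    pos[i] <- s
    deleted[i] <- paste(ch[(s + 1):(s + d)], collapse = "")
  }
  deletions$pos <- pos
  deletions$deleted <- deleted
  deletions
}

# Register range [smin, smax] of equivalent deletion start positions
# (0-based): sliding by one is allowed when the base entering the deletion
# equals the base leaving it. N breaks sliding.
deletion_registers <- function(ch, s, d) {
  L <- length(ch)
  smin <- s
  while (smin > 0 && ch[smin] %in% DNA_BASES && ch[smin] == ch[smin + d]) {
    smin <- smin - 1
  }
  smax <- s
  while (smax + d < L && ch[smax + 1] %in% DNA_BASES &&
         ch[smax + 1] == ch[smax + 1 + d]) {
    smax <- smax + 1
  }
  c(smin, smax)
}

#' Map a dinucleotide to its canonical (strand-collapsed) class
#'
#' The dinucleotides deleted at 2 bp repeat/microhomology sites collapse
#' into six non-redundant classes by grouping complementary sequences:
#' `AT`; `TA`; `CC` (CC, GG); `CG` (CG, GC); `CT` (CT, TC, AG, GA);
#' `AC` (AC, CA, GT, TG). The homopolymer dinucleotides `AA` and `TT` have
#' no class (`NA`): deleting them is a homopolymer contraction, not the
#' loss of a 2 bp repeat unit, so they fall outside this taxonomy.
#'
#' @param dinucleotide Character vector of 2-letter `ACGT` strings.
#' @return Character vector of class labels (`NA` for AA/TT).
#' @export
#' @examples
#' canonical_dinucleotide_class(c("GA", "AT", "GT"))
canonical_dinucleotide_class <- function(dinucleotide) {
  bad <- !dinucleotide %in% as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  if (any(bad)) abort("input must be dinucleotides over ACGT")
  map <- c(
    AT = "AT", TA = "TA",
    CC = "CC", GG = "CC",
    CG = "CG", GC = "CG",
    CT = "CT", TC = "CT", AG = "CT", GA = "CT",
    AC = "AC", CA = "AC", GT = "AC", TG = "AC",
    AA = NA_character_, TT = NA_character_
  )
  unname(map[dinucleotide])
}

# Classification of one deletion on a cached character vector. Returns a
# named list; s is 0-based.
classify_one_deletion <- function(ch, s, d) {
  L <- length(ch)
  del <- ch[(s + 1):(s + d)]
  res <- list(
    deleted = paste(del, collapse = ""), context = "other",
    repeat_copies = 1L, mh_length = 0L, canonical_class = NA_character_,
    tnt_compliant = NA, right_aligned_start = as.integer(s),
    register_ambiguous = FALSE, overlaps_n = FALSE
  )
  if (!all(del %in% DNA_BASES)) {
    res$overlaps_n <- TRUE
    return(res)
  }
  # tandem copies of the deleted unit spanning the site (incl. deleted copy)
  copies <- 1L
  k <- s - d
  while (k >= 0 && identical(ch[(k + 1):(k + d)], del)) {
    copies <- copies + 1L
    k <- k - d
  }
  k <- s + d
  while (k + d <= L && identical(ch[(k + 1):(k + d)], del)) {
    copies <- copies + 1L
    k <- k + d
  }
  # flanking homology: deleted prefix vs 3' flank, deleted suffix vs 5' flank
  mh3 <- 0L
  while (mh3 < d && s + d + mh3 < L &&
         ch[s + d + mh3 + 1] %in% DNA_BASES &&
         ch[s + d + mh3 + 1] == del[mh3 + 1]) {
    mh3 <- mh3 + 1L
  }
  mh5 <- 0L
  while (mh5 < d && s - mh5 > 0 &&
         ch[s - mh5] %in% DNA_BASES &&
         ch[s - mh5] == del[d - mh5]) {
    mh5 <- mh5 + 1L
  }
  mh <- max(mh3, mh5)
  res$repeat_copies <- copies
  res$mh_length <- mh
  res$context <- if (copies >= 2) "STR" else if (mh >= 1) "SNMH" else "other"

  regs <- deletion_registers(ch, s, d)
  reg_seq <- regs[1]:regs[2]
  # right alignment: most 3' register whose final deleted base is a T,
  # otherwise the limit of the repeat/MH region
  t_regs <- reg_seq[ch[reg_seq + d] == "T"]
  ra <- if (length(t_regs) > 0) max(t_regs) else regs[2]
  res$right_aligned_start <- as.integer(ra)
  if (d == 2) {
    classes <- canonical_dinucleotide_class(
      paste0(ch[reg_seq + 1], ch[reg_seq + 2])
    )
    res$canonical_class <- canonical_dinucleotide_class(
      paste0(ch[ra + 1], ch[ra + 2])
    )
    res$register_ambiguous <-
      length(unique(classes[!is.na(classes)])) > 1
  }
  if (d >= 2 && d <= 5) {
    if (d == 2 || res$context == "other") {
      # some register places the deleted bases as N^(d-1).T with a T
      # immediately 5', on either strand (the complementary-strand reading
      # is: first deleted base A with an A immediately 3')
      fwd <- reg_seq > 0 & ch[pmax(reg_seq, 1)] == "T" &
        ch[reg_seq + d] == "T"
      rev <- reg_seq + d < L & ch[reg_seq + 1] == "A" &
        ch[pmin(reg_seq + d + 1, L)] == "A"
      res$tnt_compliant <- any(fwd | rev)
    } else {
      region <- paste(ch[(regs[1] + 1):(regs[2] + d)], collapse = "")
      res$tnt_compliant <- grepl(paste0("T.{", d - 1, "}T"), region) ||
        grepl(paste0("A.{", d - 1, "}A"), region)
    }
  }
  res
}

#' Classify deletions by repeat context, microhomology and TNT compliance
#'
#' Annotates each (normalized) deletion with: `repeat_copies`, the maximal
#' tandem count of the deleted unit spanning the site (including the deleted
#' copy); `mh_length`, the longest homology between the deleted sequence and
#' its immediate flanks; `context` (`STR` when `repeat_copies >= 2`, else
#' `SNMH` when `mh_length >= 1`, else `other`; STR takes precedence);
#' `canonical_class` for 2 bp deletions; `right_aligned_start`, the register
#' chosen by the logo right-alignment rule (most 3' T, else region limit);
#' and `tnt_compliant`. TNT compliance for 2 bp deletions (and any deletion
#' outside a repeat/MH region) requires a register placing the deleted bases
#' as `N^(d-1) T` with a T immediately 5'; for 3-5 bp deletions within a
#' repeat/MH region it requires the region to contain `T N^(d-1) T`. A
#' deletion is an unoriented double-stranded event, so the rule is applied
#' on both strands (on the written strand the complementary reading is an A
#' motif); this matches scoring after canonical A-to-T reorientation and
#' makes the flag reverse-complement invariant. Deletions overlapping `N`,
#' or of length 1 or > 5, get `tnt_compliant = NA`.
#'
#' @param deletions Tibble with `seqname`, `pos` (0-based), `length`.
#' @param genome Named character vector or [syn_genome].
#' @param normalize Left-align calls first (default `TRUE`).
#' @return Input tibble with classification columns appended.
#' @export
classify_deletions <- function(deletions, genome, normalize = TRUE) {
  seqs <- genome_sequences(genome)
  if (normalize) deletions <- normalize_indels(deletions, genome)
  n <- nrow(deletions)
  if (n == 0) {
    return(mutate(deletions,
      deleted = character(0), context = character(0),
      repeat_copies = integer(0), mh_length = integer(0),
      canonical_class = character(0), tnt_compliant = logical(0),
      right_aligned_start = integer(0), register_ambiguous = logical(0),
      overlaps_n = logical(0)
    ))
  }
  chs <- lapply(seqs, seq_chars)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- classify_one_deletion(
      chs[[deletions$seqname[i]]], deletions$pos[i], deletions$length[i]
    )
  }
  ann <- bind_rows(lapply(rows, as_tibble))
  if (any(ann$overlaps_n)) {
    warn("deletions overlapping N classified as context 'other'")
  }
  deletions$deleted <- NULL
  bind_cols(deletions, ann)
}

#' Score TNT-motif compliance of classified deletions
#'
#' Recomputes the TNT flag for each deletion (see [classify_deletions()] for
#' the rule). Exposed separately so compliance can be re-scored after manual
#' edits or on externally classified calls.
#'
#' @param classified Output of [classify_deletions()] (or any tibble with
#'   `seqname`, `pos`, `length`).
#' @param genome Named character vector or [syn_genome].
#' @return Logical vector of TNT compliance flags.
#' @export
score_tnt <- function(classified, genome) {
  classify_deletions(classified[c("seqname", "pos", "length")], genome,
                     normalize = FALSE)$tnt_compliant
}

# Tandem copies of `unit` present in the reference around an insertion point
# (0-based `pos`: inserted sequence goes before ch0[pos]).
insertion_ref_copies <- function(ch, pos, unit) {
  d <- nchar(unit)
  u <- seq_chars(unit)
  copies <- 0L
  k <- pos
  while (k + d <= length(ch) && identical(ch[(k + 1):(k + d)], u)) {
    copies <- copies + 1L
    k <- k + d
  }
  k <- pos - d
  while (k >= 0 && identical(ch[(k + 1):(k + d)], u)) {
    copies <- copies + 1L
    k <- k - d
  }
  copies
}
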