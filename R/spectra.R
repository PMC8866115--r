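# Indel spectra: COSMIC-style ID-83 category binning, the
# frameshift-productive reporter subset, and wild-type background
# subtraction.

#' Category labels for an indel classification scheme
#'
#' `"id83"` is the standard 83-category layout: 1 bp deletions and
#' insertions by C/T base and homopolymer length; 2, 3, 4 and 5+ bp
#' deletions and insertions by repeat-unit count; and deletions at
#' microhomology by homology length. `"frameshift2"` is the subset whose
#' events expose the +2 reading frame of a reporter (deletion lengths
#' 2 and 5+, insertion lengths 1 and 4; 36 categories).
#'
#' @param scheme `"id83"` or `"frameshift2"`.
#' @return Character vector of ordered category labels.
#' @export
spectrum_scheme_labels <- function(scheme = c("id83", "frameshift2")) {
  scheme <- match.arg(scheme)
  id83 <- c(
    paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    paste0("2:Del:R:", 0:5), paste0("3:Del:R:", 0:5),
    paste0("4:Del:R:", 0:5), paste0("5:Del:R:", 0:5),
    paste0("2:Ins:R:", 0:5), paste0("3:Ins:R:", 0:5),
    paste0("4:Ins:R:", 0:5), paste0("5:Ins:R:", 0:5),
    "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
    paste0("4:Del:M:", 1:3), paste0("5:Del:M:", 1:5)
  )
  if (scheme == "id83") return(id83)
  keep_del <- grepl("^(2|5):Del", id83)
  keep_ins <- grepl("^(1|4):Ins", id83)
  id83[keep_del | keep_ins]
}

# Category of a single classified deletion row (list from
# classify_one_deletion + length d), or of an insertion.
id83_category <- function(type, d, deleted_base = NULL, copies = 1L,
                          mh = 0L) {
  dd <- min(d, 5L)
  if (type == "deletion") {
    if (d == 1) {
      base <- if (deleted_base %in% c("C", "G")) "C" else "T"
      return(paste0("1:Del:", base, ":", min(copies, 6L) - 1L))
    }
    if (copies >= 2) {
      return(paste0(dd, ":Del:R:", min(copies, 6L) - 1L))
    }
    if (mh >= 1) {
      cap <- c(`2` = 1L, `3` = 2L, `4` = 3L, `5` = 5L)[as.character(dd)]
      return(paste0(dd, ":Del:M:", min(mh, cap)))
    }
    return(paste0(dd, ":Del:R:0"))
  }
  # insertion: `copies` = tandem copies of the inserted unit already in the
  # reference
  if (d == 1) {
    base <- if (deleted_base %in% c("C", "G")) "C" else "T"
    return(paste0("1:Ins:", base, ":", min(copies, 5L)))
  }
  paste0(dd, ":Ins:R:", min(copies, 5L))
}

#' Build an indel spectrum from calls
#'
#' Classifies each indel (deletions via [classify_deletions()]; insertions
#' by tandem copies of the inserted unit in the reference) and bins counts
#' into the requested scheme. Category order is fixed and shared across
#' spectra so spectra are directly comparable.
#'
#' @param indels Tibble with `seqname`, `pos` (0-based), `length`, and
#'   optionally `type` (`"deletion"` default, or `"insertion"`) and
#'   `inserted` (required for insertions).
#' @param genome Named character vector or [syn_genome].
#' @param scheme `"id83"` or `"frameshift2"`. Indels falling outside the
#'   scheme's categories (only possible for `"frameshift2"`) are dropped.
#' @return An `indel_spectrum`: tibble `category`, `count` in scheme order,
#'   with the scheme stored as an attribute.
#' @export
spectrum_from_indels <- function(indels, genome, scheme = "id83") {
  labels <- spectrum_scheme_labels(scheme)
  type <- if ("type" %in% names(indels)) indels$type else
    rep("deletion", nrow(indels))
  cats <- character(nrow(indels))
  dels <- indels[type == "deletion", , drop = FALSE]
  if (nrow(dels) > 0) {
    cls <- classify_deletions(dels, genome)
    cats[type == "deletion"] <- vapply(seq_len(nrow(cls)), function(i) {
      id83_category("deletion", cls$length[i],
                    deleted_base = substr(cls$deleted[i], 1, 1),
                    copies = cls$repeat_copies[i], mh = cls$mh_length[i])
    }, character(1))
  }
  ins_idx <- which(type == "insertion")
  if (length(ins_idx) > 0) {
    if (!"inserted" %in% names(indels)) {
      abort("insertions require an `inserted` column")
    }
    seqs <- genome_sequences(genome)
    chs <- lapply(seqs, seq_chars)
    cats[ins_idx] <- vapply(ins_idx, function(i) {
      unit <- indels$inserted[i]
      copies <- insertion_ref_copies(
        chs[[indels$seqname[i]]], indels$pos[i], unit
      )
      id83_category("insertion", nchar(unit),
                    deleted_base = substr(unit, 1, 1), copies = copies)
    }, character(1))
  }
  counts <- table(factor(cats, levels = labels))
  new_spectrum(tibble(category = labels, count = as.integer(counts)), scheme)
}

new_spectrum <- function(tbl, scheme) {
  structure(tbl, class = c("indel_spectrum", class(tbl)), scheme = scheme)
}

#' @export
print.indel_spectrum <- function(x, ...) {
  cat("<indel_spectrum> scheme:", attr(x, "scheme"),
      " total:", sum(x$count), "\n")
  NextMethod()
}

spectrum_counts <- function(x) {
  if (inherits(x, "indel_spectrum") || (is.data.frame(x) &&
                                        "count" %in% names(x))) {
    return(as.numeric(x$count))
  }
  if (is.numeric(x)) return(as.numeric(x))
  abort("expected an indel_spectrum, a tibble with `count`, or a numeric vector")
}

spectrum_scheme <- function(x) {
  if (inherits(x, "indel_spectrum")) attr(x, "scheme") else NA_character_
}

#' Subtract a wild-type background from a knockout spectrum
#'
#' Per category: `max(0, ko - mean(wt))`, the average taken across the
#' supplied wild-type spectra; negative values are set to 0.
#'
#' @param ko_spectrum An `indel_spectrum` (or tibble with `category`,
#'   `count`).
#' @param wt_spectra List of spectra on the same scheme.
#' @return An `indel_spectrum` of non-negative background-subtracted counts.
#' @export
subtract_background <- function(ko_spectrum, wt_spectra) {
  if (!is.list(wt_spectra) || is.data.frame(wt_spectra)) {
    wt_spectra <- list(wt_spectra)
  }
  ko_cat <- ko_spectrum$category
  for (w in wt_spectra) {
    if (!identical(w$category, ko_cat)) {
      abort("all spectra must share one scheme (identical category order)")
    }
  }
  wt_mean <- rowMeans(vapply(wt_spectra, spectrum_counts,
                             numeric(length(ko_cat))))
  out <- tibble(category = ko_cat,
                count = pmax(0, spectrum_counts(ko_spectrum) - wt_mean))
  new_spectrum(out, spectrum_scheme(ko_spectrum))
}
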