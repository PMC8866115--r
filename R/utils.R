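# Low-level sequence and coordinate helpers shared across modules.
# Coordinates are 0-based half-open internally; VCF conversion is centralized
# in vcf_from_deletions() / deletions_from_vcf() (io.R).

DNA_BASES <- c("A", "C", "G", "T")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' Plain-string reverse complement over the alphabet `ACGTN` (case preserved
#' for upper case input only).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse-complemented strings.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(seq_chars(chartr("ACGTN", "TGCAN", s))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single probability in [0, 1]."))
  }
  invisible(x)
}

# Deterministic, parameter-localized RNG: every stochastic operation takes a
# `seed` and restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      abort("`seed` must be a single integer.")
    }
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Smallest period check: TRUE when `unit` is not a repetition of a shorter
# unit (primitive units only are reported by the repeat scanner).
is_primitive_unit <- function(unit) {
  r <- nchar(unit)
  if (r == 1) return(TRUE)
  for (p in seq_len(r - 1)) {
    if (r %% p == 0 &&
        unit == strrep(substr(unit, 1, p), r / p)) {
      return(FALSE)
    }
  }
  TRUE
}

primitive_period <- function(unit) {
  r <- nchar(unit)
  for (p in seq_len(r)) {
    if (r %% p == 0 && unit == strrep(substr(unit, 1, p), r / p)) {
      return(as.integer(p))
    }
  }
  as.integer(r)
}

# Validate a mask tibble (seqname, start, end; 0-based half-open) against a
# set of sequences; intervals must be sorted, non-overlapping and in bounds.
check_mask <- function(mask, sequences) {
  stopifnot(all(c("seqname", "start", "end") %in% names(mask)))
  for (sq in unique(mask$seqname)) {
    if (!sq %in% names(sequences)) {
      abort(paste0("mask names sequence '", sq, "' absent from the genome"))
    }
    m <- mask[mask$seqname == sq, ]
    m <- m[order(m$start), ]
    if (any(m$start < 0) || any(m$end > nchar(sequences[[sq]]))) {
      abort("mask interval out of sequence bounds")
    }
    if (any(m$end <= m$start)) abort("mask interval empty or inverted")
    if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
      abort("mask intervals overlap")
    }
  }
  invisible(mask)
}

mask_width <- function(mask) sum(mask$end - mask$start)
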