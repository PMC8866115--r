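# File interchange: FASTA (via Biostrings when available), BED (0-based
# half-open), VCF v4.2 deletion calls, and TSV tables. All VCF/internal
# coordinate conversion lives here.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_genome_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    return(setNames(toupper(as.character(ss)),
                    sub("\\s.*$", "", names(ss))))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0) abort("no FASTA records found")
  nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[idx])
  ends <- c(idx[-1] - 1, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    toupper(paste(lines[(idx[i] + 1):ends[i]], collapse = ""))
  }, character(1))
  setNames(seqs, nm)
}

#' Write sequences to FASTA
#'
#' @param genome Named character vector or [syn_genome].
#' @param path Output file.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  seqs <- genome_sequences(genome)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(seqs), path, width = width
    )
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read/write BED intervals (0-based half-open)
#'
#' @param path File path.
#' @param extra_names Names for columns beyond chrom/start/end.
#' @return Tibble `seqname`, `start`, `end` (+ extras).
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("seqname", "start", "end")
  if (!is.null(extra_names) && ncol(df) > 3) {
    names(df)[3 + seq_along(extra_names)] <- extra_names
  }
  as_tibble(df)
}

#' @rdname read_bed
#' @param tbl Tibble with `seqname`, `start`, `end` and optional extra
#'   columns (written in order).
#' @export
write_bed <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert internal deletion calls to VCF v4.2 records
#'
#' Internal calls are 0-based starts of the deleted bases; VCF records are
#' 1-based with an anchor base (`REF` = anchor + deleted, `ALT` = anchor).
#' A deletion at position 0 is anchored on the base following it instead.
#'
#' @param deletions Tibble `seqname`, `pos`, `length` (+ optional `id`).
#' @param genome Named character vector or [syn_genome].
#' @return Tibble `CHROM`, `POS`, `ID`, `REF`, `ALT`.
#' @export
vcf_from_deletions <- function(deletions, genome) {
  seqs <- genome_sequences(genome)
  n <- nrow(deletions)
  out <- tibble(CHROM = deletions$seqname, POS = NA_integer_,
                ID = if ("id" %in% names(deletions)) deletions$id
                     else paste0("del", seq_len(n)),
                REF = NA_character_, ALT = NA_character_)
  for (i in seq_len(n)) {
    s <- seqs[[deletions$seqname[i]]]
    p <- deletions$pos[i]
    d <- deletions$length[i]
    if (p >= 1) {
      out$POS[i] <- p # 1-based anchor = 0-based p-1
      out$REF[i] <- substr(s, p, p + d)
      out$ALT[i] <- substr(s, p, p)
    } else {
      out$POS[i] <- 1L
      out$REF[i] <- substr(s, 1, d + 1)
      out$ALT[i] <- substr(s, d + 1, d + 1)
    }
  }
  out
}

#' Write deletion calls as a VCF v4.2 file
#'
#' @inheritParams vcf_from_deletions
#' @param path Output file.
#' @export
write_indel_vcf <- function(deletions, genome, path) {
  seqs <- genome_sequences(genome)
  rec <- vcf_from_deletions(deletions, genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(seqs), ",length=", nchar(seqs), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(rec) > 0) {
    writeLines(paste(rec$CHROM, rec$POS, rec$ID, rec$REF, rec$ALT,
                     ".", "PASS", ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Read deletion calls from a VCF file
#'
#' Uses vcfR when available (any VCF v4.x), else a minimal parser for
#' uncompressed single-allele files. Non-deletion records are dropped with
#' a warning; calls are returned in the internal 0-based representation
#' (not yet normalized).
#'
#' @param path VCF file.
#' @return Tibble `seqname`, `pos` (0-based), `length`, `id`.
#' @export
deletions_from_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (length(body) == 0) {
      return(tibble(seqname = character(), pos = integer(),
                    length = integer(), id = character()))
    }
    parts <- strsplit(body, "\t", fixed = TRUE)
    fix <- data.frame(
      CHROM = vapply(parts, `[`, "", 1), POS = vapply(parts, `[`, "", 2),
      ID = vapply(parts, `[`, "", 3), REF = vapply(parts, `[`, "", 4),
      ALT = vapply(parts, `[`, "", 5), stringsAsFactors = FALSE
    )
  }
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  prefix_anchor <- nchar(ref) > nchar(alt) & nchar(alt) == 1 &
    substr(ref, 1, 1) == alt
  # deletions at position 1 are anchored on the base after the deletion
  suffix_anchor <- !prefix_anchor & nchar(ref) > nchar(alt) &
    nchar(alt) == 1 & substr(ref, nchar(ref), nchar(ref)) == alt
  is_del <- prefix_anchor | suffix_anchor
  if (any(!is_del)) warn("dropping non-deletion VCF records")
  pos1 <- as.integer(fix$POS)
  pos0 <- ifelse(prefix_anchor, pos1, pos1 - 1L) # 0-based deleted start
  tibble(
    seqname = fix$CHROM[is_del],
    pos = as.integer(pos0[is_del]),
    length = nchar(ref[is_del]) - 1L,
    id = fix$ID[is_del]
  )
}

#' Read/write tab-separated tables
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_tsv_table <- function(path) {
  if (requireNamespace("readr", quietly = TRUE)) {
    return(readr::read_tsv(path, show_col_types = FALSE))
  }
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_tsv_table
#' @param tbl Tibble to write.
#' @export
write_tsv_table <- function(tbl, path) {
  if (requireNamespace("readr", quietly = TRUE)) {
    readr::write_tsv(tbl, path)
  } else {
    utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
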