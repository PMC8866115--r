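test_that("normalization left-aligns and is idempotent", {
  g <- c(chr = "AACTCTCTGG")
  # deletion written at the 3' end of (CT)3 shifts to the leftmost register
  d <- tibble::tibble(seqname = "chr", pos = 6L, length = 2L)
  n1 <- normalize_indels(d, g)
  expect_equal(n1$pos, 2L)
  expect_equal(n1$deleted, "CT")
  expect_equal(normalize_indels(n1, g)$pos, 2L)
  # already-minimal call unchanged
  d2 <- tibble::tibble(seqname = "chr", pos = 0L, length = 1L)
  expect_equal(normalize_indels(d2, g)$pos, 0L)
  # reference mismatch is an error
  d3 <- tibble::tibble(seqname = "chr", pos = 2L, length = 2L,
                       deleted = "GG")
  expect_error(normalize_indels(d3, g), "mismatch")
})

test_that("all equivalent re-writings normalize to the planted record", {
  g <- generate_genome(3000, seed = 11)
  set.seed(2)
  dels <- plant_deletions(g, n = 50, tnt_bias = 0.5,
                          length_distribution = c(`2` = 2, `3` = 1),
                          seed = 3)
  canon <- normalize_indels(dels[c("seqname", "pos", "length")], g)
  ch <- strsplit(g$sequences[[1]], "")[[1]]
  for (i in seq_len(nrow(canon))) {
    regs <- top1tam:::deletion_registers(ch, canon$pos[i], canon$length[i])
    for (p in regs[1]:regs[2]) {
      re <- normalize_indels(
        tibble::tibble(seqname = canon$seqname[i], pos = p,
                       length = canon$length[i]), g
      )
      expect_equal(re$pos, canon$pos[i])
      expect_equal(re$deleted, canon$deleted[i])
    }
  }
})

test_that("classifier annotates the canonical worked examples", {
  g <- c(chr = "AAGCTCTCTGGA")
  cls <- classify_deletions(tibble::tibble(seqname = "chr", pos = 3L,
                                           length = 2L), g)
  expect_equal(cls$context, "STR")
  expect_equal(cls$repeat_copies, 3L)
  expect_true(cls$tnt_compliant)
  expect_equal(cls$canonical_class, "CT")

  cls <- classify_deletions(tibble::tibble(seqname = "chr", pos = 3L,
                                           length = 2L), c(chr = "AGTCTGA"))
  expect_equal(cls$context, "SNMH")
  expect_equal(cls$mh_length, 1L)
  expect_true(cls$tnt_compliant)

  # (CA)3 carries the motif on the complementary strand ((TG)3 reads
  # T G T): compliant either way round
  ca <- classify_deletions(tibble::tibble(seqname = "chr", pos = 2L,
                                          length = 2L),
                           c(chr = "GGCACACAGG"))
  expect_equal(ca$context, "STR")
  expect_true(ca$tnt_compliant)
  # no T on either strand (CC/GG runs): never compliant
  cc <- classify_deletions(tibble::tibble(seqname = "chr", pos = 2L,
                                          length = 2L),
                           c(chr = "AGCCCCTTAA"))
  expect_false(cc$tnt_compliant)
})

test_that("classification matches the exhaustive string oracle field by field", {
  s <- random_seq(2000, seed = 13)
  g <- c(chr = s)
  for (d in 2:5) {
    pos <- 0:(nchar(s) - d)
    cls <- classify_deletions(
      tibble::tibble(seqname = "chr", pos = pos, length = d), g,
      normalize = FALSE
    )
    ora <- lapply(pos, function(p) oracle_classify(s, p, d))
    expect_equal(cls$context, vapply(ora, `[[`, "", "context"),
                 info = paste("d =", d))
    expect_equal(cls$repeat_copies,
                 vapply(ora, `[[`, integer(1), "repeat_copies"))
    expect_equal(cls$mh_length, vapply(ora, `[[`, integer(1), "mh_length"))
    expect_equal(cls$tnt_compliant, vapply(ora, `[[`, logical(1), "tnt"))
  }
})

test_that("six canonical dinucleotide classes partition the 16 dinucleotides", {
  expect_equal(canonical_dinucleotide_class("GA"), "CT")
  expect_equal(canonical_dinucleotide_class("AT"), "AT")
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  classes <- canonical_dinucleotide_class(all16)
  # brute force over all 16: the 14 repeat-unit dinucleotides land in
  # exactly six classes; homopolymer AA/TT fall outside the taxonomy
  expect_equal(sort(unique(classes[!is.na(classes)])),
               c("AC", "AT", "CC", "CG", "CT", "TA"))
  expect_true(all(is.na(classes[all16 %in% c("AA", "TT")])))
  expect_equal(sum(!is.na(classes)), 14)
  # classes closed under reverse complement
  expect_equal(canonical_dinucleotide_class(revcomp(all16)), classes)
  expect_error(canonical_dinucleotide_class("NX"))
})

test_that("classification is reverse-complement invariant", {
  s <- random_seq(1200, seed = 23)
  g <- c(chr = s)
  rg <- c(chr = revcomp(s))
  set.seed(4)
  for (d in c(2L, 3L)) {
    pos <- sample(0:(nchar(s) - d), 150)
    fw <- classify_deletions(tibble::tibble(seqname = "chr", pos = pos,
                                            length = d), g,
                             normalize = FALSE)
    rv <- classify_deletions(
      tibble::tibble(seqname = "chr", pos = nchar(s) - pos - d, length = d),
      rg, normalize = FALSE
    )
    expect_equal(rv$context, fw$context)
    expect_equal(rv$repeat_copies, fw$repeat_copies)
    expect_equal(rv$mh_length, fw$mh_length)
    expect_equal(rv$tnt_compliant, fw$tnt_compliant)
    if (d == 2L) expect_equal(rv$canonical_class, fw$canonical_class)
  }
})

test_that("spectra bin indels into the fixed category layout", {
  expect_length(spectrum_scheme_labels("id83"), 83)
  expect_length(spectrum_scheme_labels("frameshift2"), 36)
  g <- c(chr = "AAGCTCTCTGGA")
  empty <- spectrum_from_indels(
    tibble::tibble(seqname = character(), pos = integer(),
                   length = integer()), g
  )
  expect_equal(sum(empty$count), 0)
  expect_length(empty$count, 83)

  one <- spectrum_from_indels(
    tibble::tibble(seqname = "chr", pos = 3L, length = 2L), g
  )
  expect_equal(one$count[one$category == "2:Del:R:2"], 1L)
  expect_equal(sum(one$count), 1)
  expect_error(spectrum_from_indels(tibble::tibble(), g, scheme = "nope"))
})

test_that("spectrum counts equal the oracle-derived category histogram", {
  s <- random_seq(3000, seed = 31)
  g <- c(chr = s)
  set.seed(7)
  rows <- tibble::tibble(
    seqname = "chr",
    length = sample(1:4, 400, replace = TRUE),
    pos = NA_integer_
  )
  rows$pos <- vapply(rows$length, function(d) {
    sample(0:(nchar(s) - d), 1)
  }, integer(1))
  spec <- spectrum_from_indels(rows, g)
  # conservation: every classifiable indel lands in exactly one category
  expect_equal(sum(spec$count), nrow(rows))
  # oracle histogram: classify each normalized deletion independently
  norm <- normalize_indels(rows, g)
  cats <- vapply(seq_len(nrow(norm)), function(i) {
    o <- oracle_classify(s, norm$pos[i], norm$length[i])
    d <- norm$length[i]
    if (d == 1) {
      base <- substr(norm$deleted[i], 1, 1)
      base <- if (base %in% c("C", "G")) "C" else "T"
      paste0("1:Del:", base, ":", min(o$repeat_copies, 6) - 1)
    } else if (o$repeat_copies >= 2) {
      paste0(min(d, 5), ":Del:R:", min(o$repeat_copies, 6) - 1)
    } else if (o$mh_length >= 1) {
      cap <- c(1, 2, 3, 5)[min(d, 5) - 1]
      paste0(min(d, 5), ":Del:M:", min(o$mh_length, cap))
    } else {
      paste0(min(d, 5), ":Del:R:0")
    }
  }, character(1))
  expected <- table(factor(cats, levels = spec$category))
  expect_equal(spec$count, as.integer(expected))
})

test_that("insertions are binned by reference copies of the inserted unit", {
  g <- c(chr = "AACTCTCTGG")
  ins <- tibble::tibble(seqname = "chr", pos = c(2L, 0L), length = c(2L, 1L),
                        type = "insertion", inserted = c("CT", "G"))
  spec <- spectrum_from_indels(ins, g)
  expect_equal(spec$count[spec$category == "2:Ins:R:3"], 1L) # (CT)3 present
  expect_equal(spec$count[spec$category == "1:Ins:C:0"], 1L) # no G at pos 0
  expect_equal(sum(spec$count), 2)
})

test_that("background subtraction clamps at zero per category", {
  g <- c(chr = "AACTCTCTGG")
  mk <- function(counts) {
    top1tam:::new_spectrum(
      tibble::tibble(category = spectrum_scheme_labels("id83"),
                     count = counts), "id83"
    )
  }
  set.seed(8)
  wt1 <- mk(rpois(83, 3)); wt2 <- mk(rpois(83, 3)); wt3 <- mk(rpois(83, 3))
  ko <- mk(rpois(83, 4))
  res <- subtract_background(ko, list(wt1, wt2, wt3))
  manual <- pmax(0, ko$count - (wt1$count + wt2$count + wt3$count) / 3)
  expect_equal(res$count, manual)
  expect_true(all(res$count >= 0))
  # ko equal to the wild-type mean everywhere gives the zero vector
  m <- mk(round((wt1$count + wt1$count) / 2))
  expect_equal(sum(subtract_background(wt1, list(wt1))$count), 0)
  # scheme mismatch fails
  fs <- spectrum_from_indels(
    tibble::tibble(seqname = character(), pos = integer(),
                   length = integer()), g, scheme = "frameshift2"
  )
  expect_error(subtract_background(ko, list(fs)), "scheme")
})
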