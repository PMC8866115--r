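test_that("cosine similarity follows the displayed formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  # scale invariance and symmetry
  a <- c(3, 1, 4, 1, 5); b <- c(2, 7, 1, 8, 2)
  expect_equal(cosine_similarity(a, b), cosine_similarity(10 * a, b / 3))
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 1, 1), c(1, 1)), "scheme")
})

test_that("DM cosine null matches full enumeration at n = 2, m = 1", {
  # each null vector is (1,0) or (0,1) with probability 1/2 (flat
  # Dirichlet); a pair matches (cosine 1) with probability 1/2
  res <- dm_cosine_pvalue(c(1, 0), c(1, 0), n_pairs = 4000, seed = 11)
  expect_equal(res$cosine, 1)
  expect_true(all(res$null_cosines %in% c(0, 1)))
  expect_equal(mean(res$null_cosines), 0.5, tolerance = 0.05)
  expect_equal(res$p_value, 0.5, tolerance = 0.05)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("sharply concentrated identical spectra are significant", {
  a <- c(200, rep(1, 9))
  res <- dm_cosine_pvalue(a, a, n_pairs = 2000, seed = 3)
  expect_lt(res$p_value, 0.05)
})

test_that("clustering joins identical spectra first with full support", {
  s1 <- c(10, 10, 0, 0)
  s3 <- c(0, 0, 12, 9)
  cl <- cluster_spectra(list(A = s1, B = s1, C = s3), B = 100, seed = 5)
  td <- tidy(cl)
  expect_equal(td$members[1], "A|B")
  expect_equal(td$support_pct[1], 100)
  # input order permutation leaves the topology unchanged
  cl2 <- cluster_spectra(list(C = s3, B = s1, A = s1), B = 100, seed = 5)
  expect_equal(sort(tidy(cl2)$members), sort(td$members))
  expect_error(cluster_spectra(list(A = s1, B = s1)), "3")
})

test_that("planted two-profile structure is recovered with high support", {
  set.seed(9)
  p1 <- c(40, 30, 5, 1, 1, 1)
  p2 <- c(1, 1, 5, 30, 40, 10)
  spectra <- list(
    w1 = rmultinom(1, 400, p1 / sum(p1))[, 1],
    w2 = rmultinom(1, 400, p1 / sum(p1))[, 1],
    k1 = rmultinom(1, 400, p2 / sum(p2))[, 1],
    k2 = rmultinom(1, 400, p2 / sum(p2))[, 1]
  )
  cl <- cluster_spectra(spectra, B = 200, seed = 13)
  td <- tidy(cl)
  pair_rows <- td[td$members %in% c("w1|w2", "k1|k2"), ]
  expect_equal(nrow(pair_rows), 2)
  expect_true(all(pair_rows$support_pct > 90))
  # Newick export carries the support labels
  nwk <- as_newick(cl)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "100|9[0-9]")
})

test_that("canonical windows follow the orientation and alignment rules", {
  # GA deletion: contains A, not AT/TA: window reverse complemented
  g <- c(chr = "CCCGTAGACCC")
  cls <- classify_deletions(tibble::tibble(seqname = "chr", pos = 6L,
                                           length = 2L), g)
  w <- canonicalize_context(cls, g, flank = 3)
  expect_true(w$flipped)
  expect_equal(w$oriented_dinucleotide, "TC")

  # AT deletion: orientation unchanged
  g2 <- c(chr = "CCCGATGCCCC")
  cls2 <- classify_deletions(tibble::tibble(seqname = "chr", pos = 4L,
                                            length = 2L), g2)
  w2 <- canonicalize_context(cls2, g2, flank = 3)
  expect_false(w2$flipped)
  expect_equal(w2$oriented_dinucleotide, "AT")

  # (CT)3: register abuts the most 3' T of the repeat region
  g3 <- c(chr = "AAGCTCTCTGGA")
  cls3 <- classify_deletions(tibble::tibble(seqname = "chr", pos = 3L,
                                            length = 2L), g3)
  expect_equal(cls3$right_aligned_start, 7L) # deleted pair ends at last T
  w3 <- canonicalize_context(cls3, g3, flank = 2)
  expect_equal(w3$window, substr("AAGCTCTCTGGA", 6, 11))

  # windows at sequence edges are N padded and flagged
  w4 <- canonicalize_context(cls3, g3, flank = 9)
  expect_true(w4$padded)
  expect_match(w4$window, "N")
})

test_that("right alignment and orientation match the rule-literal oracle", {
  s <- random_seq(1500, seed = 33)
  g <- c(chr = s)
  set.seed(10)
  pos <- sample(6:(nchar(s) - 8), 120)
  cls <- classify_deletions(tibble::tibble(seqname = "chr", pos = pos,
                                           length = 2L), g,
                            normalize = FALSE)
  got <- canonicalize_context(cls, g, flank = 5)
  for (i in seq_len(nrow(got))) {
    o <- oracle_classify(s, pos[i], 2)
    exp <- oracle_canonical_window(s, o$registers, flank = 5)
    expect_equal(got$right_aligned_start[i], exp$ra)
    expect_equal(got$window[i], exp$window)
  }
})

test_that("logo information content matches closed-form entropy", {
  # identical windows: every column totals 2 bits
  lg <- build_logo(rep("ACGT", 50))
  expect_equal(unname(rowSums(lg)), rep(2, 4))
  # uniform column: 0 bits
  lg2 <- build_logo(c("A", "C", "G", "T"))
  expect_equal(sum(lg2), 0)
  # planted 0.9/0.1 T/A bias at one position
  windows <- c(rep("TG", 90), rep("AG", 10))
  lg3 <- build_logo(windows)
  info <- 2 + 0.9 * log2(0.9) + 0.1 * log2(0.1)
  expect_equal(sum(lg3[1, ]), info, tolerance = 1e-12)
  # bounded in [0, 2]; invariant to duplicating the window set
  expect_true(all(rowSums(lg3) >= 0 & rowSums(lg3) <= 2))
  expect_equal(unclass(build_logo(c(windows, windows)))[, ],
               unclass(lg3)[, ], ignore_attr = "n_sequences")
  # N excluded per column
  lgN <- build_logo(c("AN", "AN", "AC"))
  expect_equal(sum(lgN[1, ]), 2)
  expect_error(build_logo(character(0)))
})
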