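test_that("tandem repeat scanner finds maximal primitive runs", {
  r <- find_tandem_repeats("ACACACG")
  expect_equal(nrow(r), 1)
  expect_equal(r$unit, "AC")
  expect_equal(r$unit_length, 2L)
  expect_equal(r$copies, 3L)
  expect_equal(c(r$start, r$end), c(0, 6))

  expect_equal(nrow(find_tandem_repeats("ACGT")), 0)

  # primitive-unit reporting: no additional r = 4 record for (CT)3
  r <- find_tandem_repeats("CTCTCT")
  expect_equal(r$unit_length, 2L)

  # homopolymers only at r = 1 (unit "AA" is not primitive)
  r <- find_tandem_repeats("GGAAAAGG")
  expect_setequal(r$unit, c("G", "A"))
  expect_true(all(r$unit_length == 1))
  expect_equal(r$copies[r$unit == "A"], 4L)

  # N breaks repeats
  expect_equal(nrow(find_tandem_repeats("ACNACAC")), 1)
})

test_that("repeat scanner agrees with the exhaustive (start, r, n) oracle", {
  s <- random_seq(2000, seed = 13)
  got <- find_tandem_repeats(s)
  exp <- oracle_repeats(s)
  expect_equal(nrow(got), nrow(exp))
  expect_equal(got$start, exp$start)
  expect_equal(got$end, exp$end)
  expect_equal(got$unit, exp$unit)
  expect_equal(got$copies, exp$copies)
})

test_that("repeat annotation is strand symmetric", {
  s <- random_seq(1500, seed = 41)
  L <- nchar(s)
  # compare full periodic extents (trim-invariant): extend each reported
  # span while the periodicity continues
  extent_keys <- function(seq, regions, mirror = FALSE) {
    keys <- vapply(seq_len(nrow(regions)), function(i) {
      r <- regions$unit_length[i]
      a <- regions$start[i]; b <- regions$end[i] # 0-based half-open
      while (a >= 1 &&
             substr(seq, a, a) == substr(seq, a + r, a + r)) a <- a - 1
      while (b < nchar(seq) &&
             substr(seq, b + 1, b + 1) == substr(seq, b + 1 - r, b + 1 - r))
        b <- b + 1
      if (mirror) c(nchar(seq) - b, nchar(seq) - a, r)
      else c(a, b, r)
    }, numeric(3))
    sorted <- t(keys)[order(keys[1, ], keys[3, ]), , drop = FALSE]
    unname(sorted)
  }
  fw <- extent_keys(s, find_tandem_repeats(s))
  rv <- extent_keys(revcomp(s), find_tandem_repeats(revcomp(s)),
                    mirror = TRUE)
  rv <- rv[order(rv[, 1], rv[, 3]), , drop = FALSE]
  expect_equal(fw, rv)
})

test_that("microhomology sites match the anchor-pair definition", {
  mh <- find_mh_sites("AGTCTGA", d = 2)
  expect_equal(nrow(mh), 1)
  expect_equal(mh$start, 2)
  expect_equal(mh$end, 5)
  expect_equal(mh$anchor_base, "T")
  expect_false(mh$subsumed_by_str)

  mh <- find_mh_sites("CCCC", d = 2)
  expect_true(all(mh$subsumed_by_str))
  expect_equal(nrow(find_mh_sites("CCCC", d = 2, drop_subsumed = TRUE)), 0)

  s <- random_seq(2000, seed = 17)
  for (d in 2:4) {
    got <- find_mh_sites(s, d = d)
    expect_equal(got$start, oracle_mh_starts(s, d))
    # subsumption flag agrees with containment in oracle repeat spans
    reps <- oracle_repeats(s)
    exp_sub <- vapply(got$start, function(st) {
      any(reps$start <= st & reps$end >= st + d + 1)
    }, logical(1))
    expect_equal(got$subsumed_by_str, exp_sub)
  }
})

test_that("background TNT fractions behave at the analytic extremes", {
  all_c <- c(chr = strrep("C", 2000))
  expect_equal(
    tnt_background_fraction(all_c, d = 2, n_samples = 500, seed = 1)$fraction,
    0
  )
  ta <- c(chr = strrep("TA", 1000))
  expect_equal(
    tnt_background_fraction(ta, d = 2, n_samples = 500, seed = 1)$fraction,
    1
  )
  tiny <- c(chr = strrep("A", 500))
  expect_error(tnt_background_fraction(tiny, d = 2), "1 kb")
})

test_that("sampled background fraction converges to the exhaustive fraction", {
  g <- generate_genome(5000, seed = 13)
  sites <- deletion_site_compliance(g, d = 2)
  exact <- mean(sites$tnt_compliant)
  est <- tnt_background_fraction(g, d = 2, n_samples = 20000, seed = 99)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(est$fraction - exact), 3 * se + 1e-12)
  # deterministic STR/MH context fractions are probabilities
  for (ctx in c("STR", "MH")) {
    f <- tnt_background_fraction(g, d = 2, context = ctx)$fraction
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("context relative rates recover planted composition biases", {
  g <- c(chr = random_seq(20000, seed = 13, gc = 0.5))
  # uniform sites: every dinucleotide rate near 1/16
  set.seed(5)
  pos <- sample(1:(nchar(g) - 2), 4000)
  rates <- context_relative_rates(
    tibble::tibble(seqname = "chr", pos = pos, strand = "+"), g
  )
  expect_equal(sum(rates$relative_rate), 1, tolerance = 1e-12)
  expect_true(all(abs(rates$relative_rate - 1 / 16) < 0.03))

  # all sites at CT dinucleotides: rate concentrated on CT
  s <- g[["chr"]]
  ct_pos <- gregexpr("CT", s)[[1]] # match start, 1-based
  sites <- tibble::tibble(seqname = "chr", pos = ct_pos, strand = "+")
  rates <- context_relative_rates(sites, g)
  expect_equal(unname(rates$relative_rate[rates$context == "CT"]), 1)
  expect_true(all(rates$relative_rate[rates$context != "CT"] == 0))

  # planted 3:1 CT:GT mixture recovered against closed-form expectation
  gt_pos <- gregexpr("GT", s)[[1]]
  set.seed(6)
  mix <- tibble::tibble(
    seqname = "chr",
    pos = c(sample(ct_pos, 1200, replace = TRUE),
            sample(gt_pos, 400, replace = TRUE)),
    strand = "+"
  )
  rates <- context_relative_rates(mix, g)
  n_ct <- length(ct_pos); n_gt <- length(gt_pos)
  di <- top1tam:::dinucleotide_counts(g)
  g_ct <- di[["CT"]] + di[["AG"]]
  g_gt <- di[["GT"]] + di[["AC"]]
  expected_ratio <- (1200 / g_ct) / (400 / g_gt)
  got_ratio <- unname(rates$relative_rate[rates$context == "CT"] /
                        rates$relative_rate[rates$context == "GT"])
  expect_equal(got_ratio, unname(expected_ratio), tolerance = 1e-9)
})
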