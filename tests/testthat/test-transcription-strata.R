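make_expr <- function(genes, levels_by_tissue) {
  # levels_by_tissue: named list tissue -> named numeric (gene -> level)
  purrr::map(names(levels_by_tissue), function(tt) {
    lv <- levels_by_tissue[[tt]]
    tidyr::expand_grid(gene = genes, sample = 1:3) |>
      dplyr::mutate(tissue = tt, tpm = lv[gene],
                    sample = paste0(tt, "_s", sample))
  }) |> dplyr::bind_rows()
}

test_that("expression group assignment follows the stated rules", {
  # housekeeping-like: max below ten times the median
  genes <- paste0("g", 1:12)
  tpm <- tibble::tibble(
    gene = rep(genes, each = 3),
    tpm = c(rep(10, 33), 10, 10, 95) # g12: median 10, max 9.5x
  )
  tpm$tpm[tpm$gene == "g11"] <- c(10, 10, 115) # 11.5x median: excluded
  grp <- assign_expression_groups(tpm, "housekeeping-deciles")
  expect_true("g12" %in% grp$gene)
  expect_false("g11" %in% grp$gene)

  # germline scheme collapses groups 1-9 into the stated four
  g4 <- assign_expression_groups(
    tibble::tibble(gene = paste0("x", 1:9), group = 1:9), "germline-4"
  )
  expect_equal(as.character(g4$group),
               c("unexpressed", "low", "low", "low", "mid", "mid", "mid",
                 "high", "high"))

  # overlapping genes: higher median retained, ties broken by mean
  genes <- paste0("o", 1:12)
  tpm2 <- tibble::tibble(
    gene = rep(genes, each = 2),
    tpm = rep(c(5, 7, 9, 11, 2, 3, 4, 6, 8, 10, 12, 13), each = 2)
  )
  tpm2$tpm[tpm2$gene == "o1"] <- c(5, 5)
  tpm2$tpm[tpm2$gene == "o2"] <- c(4, 6) # same median 5, higher mean? equal
  tpm2$tpm[tpm2$gene == "o2"][2] <- 7    # mean 5.5 > o1 mean 5
  spans <- tibble::tibble(
    gene = genes, seqname = "c",
    start = c(0, 50, seq(200, 1100, by = 100)),
    end = c(100, 150, seq(200, 1100, by = 100) + 80)
  )
  grp2 <- assign_expression_groups(tpm2, "deciles", gene_spans = spans)
  expect_true("o2" %in% grp2$gene)  # overlaps o1, wins on mean
  expect_false("o1" %in% grp2$gene)
})

test_that("stratum rates implement c/(g n) with bootstrap CIs", {
  spans <- tibble::tibble(gene = paste0("g", 1:5), seqname = "c",
                          start = (0:4) * 2e5, end = (1:5) * 2e5)
  groups <- tibble::tibble(gene = spans$gene,
                           group = factor(rep("all", 5)))
  set.seed(1)
  dels <- tibble::tibble(seqname = "c",
                         pos = sort(sample(0:(1e6 - 1), 10)), length = 2L)
  r <- stratum_rates(dels, spans, groups, n_genomes = 5, bootstrap_B = 50,
                     seed = 2)
  expect_equal(r$c, 10)
  expect_equal(r$g, 1e6)
  expect_equal(r$rate, 10 / (1e6 * 5)) # 2e-6 per bp per genome
  expect_lte(r$ci_low, r$rate + 1e-15)
  expect_gte(r$ci_high, r$rate - 1e-15)

  # empty stratum: rate 0 with degenerate CI
  none <- stratum_rates(dels[0, ], spans, groups, n_genomes = 5,
                        bootstrap_B = 20, seed = 3)
  expect_equal(none$rate, 0)
  expect_equal(c(none$ci_low, none$ci_high), c(0, 0))
})

test_that("HETR gene calls recover the planted truth set exactly", {
  ds <- simulate_expression_dataset(n_genes = 150, n_tissues = 3,
                                    hetr_fraction = 0.1, coupling = 0,
                                    seed = 8)
  summ <- tissue_expression_summary(ds$expression)
  for (tt in paste0("tissue", 1:3)) {
    truth <- ds$genes$gene[ds$genes$is_hetr & ds$genes$home_tissue == tt]
    expect_setequal(hetr_genes(summ, tt), truth)
  }
  expect_error(hetr_genes(summ[summ$tissue == "tissue1", ], "tissue1"),
               "2 tissues")

  # a gene uniformly high in all tissues is excluded (fails restriction)
  genes <- paste0("g", 1:20)
  lv <- setNames(c(rep(1, 19), 100), genes)
  expr <- make_expr(genes, list(t1 = lv, t2 = lv))
  s2 <- tissue_expression_summary(expr)
  expect_false("g20" %in% hetr_genes(s2, "t1"))
  # no gene passing gives an empty set, not an error
  expect_length(hetr_genes(s2, "t1"), 0)
})

test_that("HETR enrichment finds planted tissue-cancer coupling", {
  set.seed(11)
  n_genes <- 120
  genes <- paste0("g", sprintf("%03d", 1:n_genes))
  spans <- tibble::tibble(gene = genes, seqname = "c",
                          start = (seq_len(n_genes) - 1) * 1000,
                          end = (seq_len(n_genes) - 1) * 1000 + 800)
  hetr_sets <- list(tisA = genes[1:10], tisB = genes[11:20])
  rand_pos <- function(g_idx, n) {
    idx <- sample(g_idx, n, replace = TRUE)
    spans$start[idx] + sample(0:799, n, replace = TRUE)
  }
  dels <- dplyr::bind_rows(
    # cancer A: half its deletions inside tisA HETR genes
    tibble::tibble(cancer = "A", seqname = "c",
                   pos = c(rand_pos(1:10, 150), rand_pos(11:120, 150))),
    # cancer B: uniform background
    tibble::tibble(cancer = "B", seqname = "c",
                   pos = rand_pos(11:120, 300))
  )
  res <- hetr_enrichment(dels, hetr_sets, spans)
  dA <- res[res$cancer == "A" & res$tissue == "tisA", ]
  expect_gt(dA$odds_ratio, 1)
  expect_lt(dA$q, 0.05)
  offd <- res[res$cancer == "A" & res$tissue == "tisB", ]
  expect_lt(offd$odds_ratio, dA$odds_ratio)

  # exchangeable placement: ORs near 1, nothing significant
  dels2 <- dplyr::bind_rows(
    tibble::tibble(cancer = "A", seqname = "c", pos = rand_pos(1:120, 300)),
    tibble::tibble(cancer = "B", seqname = "c", pos = rand_pos(1:120, 300))
  )
  res2 <- hetr_enrichment(dels2, hetr_sets, spans)
  expect_true(all(res2$q > 0.05))
  # depletion is displayed as the reciprocal
  dep <- res[res$cancer == "B" & res$tissue == "tisA", ]
  if (!is.na(dep$odds_ratio) && dep$odds_ratio < 1) {
    expect_equal(dep$display_value, 1 / dep$odds_ratio)
  }
  expect_error(hetr_enrichment(dels[dels$cancer == "A", ], hetr_sets,
                               spans), "2 cancer")
})

test_that("signal decile rates are anchored at decile 1 and track coupling", {
  g <- generate_genome(60000, seed = 14)
  dels0 <- plant_deletions(g, n = 400, tnt_bias = 0, seed = 15)
  tr0 <- simulate_signal_track(g, dels0, coupling = 0, seed = 16)
  r0 <- signal_decile_rates(tr0, dels0, bootstrap_B = 100, seed = 17)
  expect_equal(nrow(r0), 10)
  expect_equal(r0$relative_rate[r0$decile == 1], 1)
  # decile sizes near equal (+- 1 bin)
  expect_lte(diff(range(r0$n_bins)), 1)
  # no coupling: all deciles compatible with 1
  expect_true(all(r0$ci_low[-1] <= 1.35 & r0$ci_high[-1] >= 0.7))

  tr1 <- simulate_signal_track(g, dels0, coupling = 8, seed = 18)
  r1 <- signal_decile_rates(tr1, dels0, bootstrap_B = 100, seed = 19)
  expect_gt(r1$relative_rate[r1$decile == 10], 1)
  expect_gt(cor(r1$decile, r1$relative_rate, method = "spearman"), 0.7)
})

test_that("individual filtering removes strict percentile outliers", {
  even <- filter_individuals(setNames(rep(5, 12), paste0("i", 1:12)))
  expect_true(all(even$retained))

  counts <- setNames(1:100, paste0("i", 1:100))
  filt <- filter_individuals(counts)
  qs <- quantile(1:100, c(0.1, 0.9), names = FALSE) # oracle: type-7
  expect_equal(filt$individual[filt$retained],
               paste0("i", which(1:100 >= qs[1] & 1:100 <= qs[2])))
  # idempotence: refiltering the retained set keeps everyone inside the
  # recomputed bounds only; the retained flag itself is stable here
  again <- filter_individuals(
    setNames(filt$total[filt$retained], filt$individual[filt$retained])
  )
  expect_true(all(again$total >= quantile(again$total, 0.1) &
                    again$total <= quantile(again$total, 0.9)) ||
                any(!again$retained))
  expect_error(filter_individuals(setNames(1:5, paste0("i", 1:5))), "10")
})
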