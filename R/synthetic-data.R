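# Synthetic-data generators: genomes with planted repeat/MH content,
# deletion sets with a tunable TNT bias, Luria-Delbruck colony counts,
# expression tables with tissue-restricted genes, and binned activity
# tracks. Every generator takes a seed and is byte-reproducible; truth
# labels are recorded so downstream estimates can be checked against known
# ground truth.

#' Generate a synthetic genome with planted repeats
#'
#' Background bases are drawn i.i.d. at the stated GC fraction (no
#' higher-order structure). Planted features are inserted at uniformly
#' chosen non-overlapping positions, with one guard base on each side
#' adjusted so a planted repeat cannot extend into its flanks.
#'
#' @param length Sequence length in bp (>= 1000).
#' @param seed RNG seed.
#' @param gc_fraction Background GC fraction (default 0.4).
#' @param repeat_plan Optional tibble with columns `kind` (`"STR"` or
#'   `"MH"`), `unit_length` (1-5), `copies` (STR only, >= 2) and `count`.
#'   An MH feature is an anchor pair `B N^(r-1) B` spanning
#'   `unit_length + 1` bp.
#' @param seqname Name of the single generated sequence.
#' @return A `syn_genome`: list with `sequences` (named character),
#'   `mask` (whole sequence), `truth_repeats`, `seed`, `params`.
#' @export
generate_genome <- function(length, seed, gc_fraction = 0.4,
                            repeat_plan = NULL, seqname = "chr1") {
  stopifnot(length >= 1000)
  check_scalar_prob(gc_fraction, "gc_fraction")
  planted_bp <- 0
  if (!is.null(repeat_plan)) {
    stopifnot(all(c("kind", "unit_length", "count") %in% names(repeat_plan)))
    widths <- ifelse(repeat_plan$kind == "STR",
                     repeat_plan$unit_length * repeat_plan$copies,
                     repeat_plan$unit_length + 1)
    planted_bp <- sum(widths * repeat_plan$count)
    if (planted_bp > length / 2) {
      abort("infeasible repeat_plan: planted bp exceeds half the genome")
    }
  }
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  truth <- list()
  ch <- with_seed(seed, {
    ch <- sample(DNA_BASES, length, replace = TRUE, prob = probs)
    if (!is.null(repeat_plan) && nrow(repeat_plan) > 0) {
      occupied <- integer(0) # guard-extended positions already used
      for (k in seq_len(nrow(repeat_plan))) {
        r <- repeat_plan$unit_length[k]
        kind <- repeat_plan$kind[k]
        for (j in seq_len(repeat_plan$count[k])) {
          if (kind == "STR") {
            n_cp <- repeat_plan$copies[k]
            w <- r * n_cp
            repeat {
              unit <- paste(sample(DNA_BASES, r, replace = TRUE),
                            collapse = "")
              if (is_primitive_unit(unit)) break
            }
            feature <- seq_chars(strrep(unit, n_cp))
          } else {
            w <- r + 1
            anchor <- sample(DNA_BASES, 1)
            feature <- c(anchor,
                         if (r > 1) sample(DNA_BASES, r - 1, replace = TRUE),
                         anchor)
          }
          placed <- FALSE
          for (try in 1:1000) {
            s0 <- sample.int(length - w - 3, 1) + 1 # 0-based, 2bp margins
            span <- (s0 - 1):(s0 + w)               # with guard bases
            if (!any(span %in% occupied)) {
              ch[(s0 + 1):(s0 + w)] <- feature
              # guard: break any periodic extension into the flanks
              for (g in c(s0 - 1, s0 + w)) {
                period_mate <- if (g == s0 - 1) g + r else g - r
                if (g >= 0 && g < length &&
                    ch[g + 1] == ch[period_mate + 1]) {
                  ch[g + 1] <- sample(setdiff(DNA_BASES, ch[period_mate + 1]),
                                      1)
                }
              }
              occupied <- c(occupied, span)
              truth[[length(truth) + 1]] <- tibble(
                seqname = seqname, start = s0, end = s0 + w, kind = kind,
                unit = if (kind == "STR") strrep("", 1) else NA_character_,
                unit_length = as.integer(r),
                copies = if (kind == "STR") as.integer(repeat_plan$copies[k])
                         else NA_integer_,
                sequence = paste(feature, collapse = "")
              )
              placed <- TRUE
              break
            }
          }
          if (!placed) abort("could not place repeat_plan features without overlap")
        }
      }
    }
    ch
  })
  truth_tbl <- if (length(truth) > 0) {
    bind_rows(truth) |>
      mutate(unit = ifelse(.data$kind == "STR",
                           substr(.data$sequence, 1, .data$unit_length),
                           NA_character_)) |>
      arrange(.data$start)
  } else {
    tibble(seqname = character(), start = integer(), end = integer(),
           kind = character(), unit = character(), unit_length = integer(),
           copies = integer(), sequence = character())
  }
  structure(
    list(
      sequences = setNames(paste(ch, collapse = ""), seqname),
      mask = tibble(seqname = seqname, start = 0L, end = as.integer(length)),
      truth_repeats = truth_tbl,
      seed = seed,
      params = list(length = length, gc_fraction = gc_fraction)
    ),
    class = "syn_genome"
  )
}

#' @export
print.syn_genome <- function(x, ...) {
  cat("<syn_genome>", length(x$sequences), "sequence(s),",
      sum(nchar(x$sequences)), "bp,",
      nrow(x$truth_repeats), "planted features, seed", x$seed, "\n")
  invisible(x)
}

#' Enumerate candidate deletion sites and their TNT compliance
#'
#' All mappable start positions for d-bp deletions, with the classifier's
#' TNT flag. Used by [plant_deletions()]; exposed so the (deterministic)
#' enumeration can be cached across repeated planting calls on one genome.
#'
#' @param genome A `syn_genome` or named character vector.
#' @param d Deletion length.
#' @param mask Optional mask override.
#' @return Tibble `seqname`, `pos`, `length`, `tnt_compliant`.
#' @export
deletion_site_compliance <- function(genome, d, mask = NULL) {
  mask <- resolve_mask(genome, mask)
  m <- mask[mask$end - mask$start >= d, ]
  sites <- purrr::map(seq_len(nrow(m)), function(i) {
    tibble(seqname = m$seqname[i],
           pos = seq.int(m$start[i], m$end[i] - d),
           length = as.integer(d))
  }) |> bind_rows()
  cls <- classify_deletions(sites, genome, normalize = FALSE)
  sites$tnt_compliant <- cls$tnt_compliant
  sites
}

#' Plant deletions with a tunable TNT bias
#'
#' Each deletion is placed, with probability `tnt_bias`, at a site the
#' classifier scores TNT-compliant; otherwise at a uniformly random mappable
#' site (which may itself be compliant by chance). The branch taken is
#' recorded as the truth flag, so `tnt_bias = 1` forces all flags true and
#' `tnt_bias = 0` yields uniform placement whose compliant fraction matches
#' the genome's background availability.
#'
#' @param genome A `syn_genome` or named character vector.
#' @param n Number of deletions.
#' @param tnt_bias Probability in \[0, 1\].
#' @param length_distribution Named numeric vector of weights per deletion
#'   length (default all 2 bp).
#' @param seed RNG seed.
#' @param sites Optional precomputed list of [deletion_site_compliance()]
#'   tibbles, named by deletion length.
#' @return Tibble `seqname`, `pos`, `length`, `truth_tnt` with attribute
#'   `tnt_bias`.
#' @export
plant_deletions <- function(genome, n, tnt_bias,
                            length_distribution = c(`2` = 1), seed = NULL,
                            sites = NULL) {
  check_scalar_prob(tnt_bias, "tnt_bias")
  stopifnot(n >= 0)
  lens <- as.integer(names(length_distribution))
  if (is.null(sites)) {
    sites <- lapply(setNames(lens, lens), function(d) {
      deletion_site_compliance(genome, d)
    })
  }
  if (n == 0) {
    return(structure(
      tibble(seqname = character(), pos = integer(), length = integer(),
             truth_tnt = logical()),
      tnt_bias = tnt_bias
    ))
  }
  out <- with_seed(seed, {
    d_draw <- lens[sample.int(length(lens), n, replace = TRUE,
                              prob = length_distribution /
                                sum(length_distribution))]
    branch <- runif(n) < tnt_bias
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      st <- sites[[as.character(d_draw[i])]]
      pool <- if (branch[i]) which(st$tnt_compliant) else seq_len(nrow(st))
      if (length(pool) == 0) {
        abort(paste0("no TNT-compliant site of length ", d_draw[i],
                     " exists in the genome"))
      }
      rows[[i]] <- st[sample(pool, 1), c("seqname", "pos", "length")]
    }
    mutate(bind_rows(rows), truth_tnt = branch)
  })
  structure(out, tnt_bias = tnt_bias)
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Synchronized-doubling model: each culture grows from `n_start` to at
#' least `n_final` cells by discrete generations; every division mutates
#' with probability `mu_per_division` (one daughter mutant), and mutants
#' breed true. This matches the per-generation rate definition used by the
#' Lea-Coulson estimator.
#'
#' @param mu_per_division Mutation probability per division, in
#'   \[0, 0.01\].
#' @param n_start,n_final Initial and minimum final cell numbers.
#' @param n_cultures Number of independent cultures.
#' @param seed RNG seed.
#' @return Tibble `culture`, `mutant_count`, `n_final` (actual final
#'   population).
#' @export
simulate_fluctuation <- function(mu_per_division, n_start, n_final,
                                 n_cultures, seed = NULL) {
  if (mu_per_division < 0 || mu_per_division > 0.01) {
    abort("`mu_per_division` must lie in [0, 0.01]")
  }
  stopifnot(n_start >= 1, n_final >= n_start, n_cultures >= 1)
  with_seed(seed, {
    res <- purrr::map(seq_len(n_cultures), function(cu) {
      nonmut <- n_start
      mut <- 0
      while (nonmut + mut < n_final) {
        new_mut <- rbinom(1, size = as.integer(nonmut), prob = mu_per_division)
        mut <- 2 * mut + new_mut
        nonmut <- 2 * nonmut - new_mut
      }
      tibble(culture = cu, mutant_count = as.integer(mut),
             n_final = nonmut + mut)
    })
    bind_rows(res)
  })
}

#' Simulate an expression dataset with tissue-restricted genes and
#' expression-coupled deletions
#'
#' Baseline gene levels are log-normal and shared across tissues (with
#' sample-level noise), so no baseline gene is tissue restricted. A
#' `hetr_fraction` of genes is made highly expressed and tissue restricted
#' (HETR): within the (round-robin assigned) home tissue their expression
#' is far above the tissue's 90th-quantile threshold, and near zero
#' elsewhere. Deletions (2 bp) are placed per gene with expectation
#' proportional to `span * TPM^coupling`.
#'
#' @param n_genes Number of genes (>= 20).
#' @param n_tissues Number of tissues (>= 2 when `hetr_fraction > 0`).
#' @param hetr_fraction Fraction of genes made HETR, in \[0, 0.5\].
#' @param coupling Exponent linking TPM to deletion rate (0 = uncoupled).
#' @param seed RNG seed.
#' @param samples_per_tissue Samples per tissue (default 3).
#' @param gene_span_bp Gene span (default 10000).
#' @param overlap_fraction Fraction of genes shifted to overlap their
#'   predecessor (default 0).
#' @param total_deletions Expected total deletion count across all
#'   individuals (default 4000).
#' @param n_individuals Number of mutated genomes (default 20).
#' @return A `syn_expression` list: `genes` (spans, truth labels, per-gene
#'   expected deletions/Mb/individual), `expression` (gene, tissue, sample,
#'   tpm), `deletions` (seqname, pos, length, gene, individual), `params`.
#' @export
simulate_expression_dataset <- function(n_genes = 200, n_tissues = 4,
                                        hetr_fraction = 0.1, coupling = 1,
                                        seed = NULL,
                                        samples_per_tissue = 3,
                                        gene_span_bp = 10000,
                                        overlap_fraction = 0,
                                        total_deletions = 4000,
                                        n_individuals = 20) {
  stopifnot(n_genes >= 20)
  check_scalar_prob(hetr_fraction, "hetr_fraction")
  if (hetr_fraction > 0.5) abort("`hetr_fraction` must be <= 0.5")
  if (hetr_fraction > 0 && n_tissues < 2) {
    abort("tissue-restricted genes require n_tissues >= 2")
  }
  with_seed(seed, {
    genes <- paste0("g", sprintf("%04d", seq_len(n_genes)))
    tissues <- paste0("tissue", seq_len(n_tissues))
    gap <- 1000
    start <- cumsum(c(0, rep(gene_span_bp + gap, n_genes - 1)))
    if (overlap_fraction > 0) {
      n_ov <- floor(overlap_fraction * n_genes)
      idx <- seq(2, by = 2, length.out = n_ov)
      idx <- idx[idx <= n_genes]
      start[idx] <- start[idx - 1] + gene_span_bp %/% 2
    }
    spans <- tibble(gene = genes, seqname = "chrE",
                    start = as.integer(start),
                    end = as.integer(start + gene_span_bp))
    n_hetr <- round(hetr_fraction * n_genes)
    is_hetr <- c(rep(TRUE, n_hetr), rep(FALSE, n_genes - n_hetr))
    is_hetr <- sample(is_hetr)
    home <- rep(NA_character_, n_genes)
    home[is_hetr] <- rep(tissues, length.out = n_hetr)
    lambda <- rlnorm(n_genes, meanlog = 2, sdlog = 1)
    hi <- 200 * max(lambda)
    lo <- 1e-4 * median(lambda)
    expr <- tidyr::expand_grid(
      gene = genes, tissue = tissues,
      sample = seq_len(samples_per_tissue)
    ) |>
      mutate(sample = paste0(.data$tissue, "_s", .data$sample))
    gene_idx <- match(expr$gene, genes)
    base <- lambda[gene_idx]
    hetr_row <- is_hetr[gene_idx]
    at_home <- hetr_row & expr$tissue == home[gene_idx]
    level <- ifelse(hetr_row, ifelse(at_home, hi, lo), base)
    expr$tpm <- level * rlnorm(nrow(expr), 0, 0.2)
    # gene-level median TPM drives the deletion-rate coupling
    med_tpm <- expr |>
      summarise(med = median(.data$tpm), .by = "gene")
    med <- med_tpm$med[match(genes, med_tpm$gene)]
    w <- gene_span_bp * med^coupling
    lam_gene <- total_deletions * w / sum(w)
    counts <- rpois(n_genes, lam_gene)
    dels <- purrr::map(which(counts > 0), function(i) {
      tibble(
        seqname = "chrE",
        pos = as.integer(spans$start[i] +
                           floor(runif(counts[i]) * (gene_span_bp - 2))),
        length = 2L, gene = genes[i],
        individual = sample.int(n_individuals, counts[i], replace = TRUE)
      )
    }) |> bind_rows()
    if (nrow(dels) == 0) {
      dels <- tibble(seqname = character(), pos = integer(),
                     length = integer(), gene = character(),
                     individual = integer())
    }
    structure(
      list(
        genes = mutate(spans, is_hetr = is_hetr, home_tissue = home,
                       rate_per_mb = lam_gene / n_individuals /
                         (gene_span_bp / 1e6)),
        expression = expr,
        deletions = dels,
        params = list(n_genes = n_genes, n_tissues = n_tissues,
                      hetr_fraction = hetr_fraction, coupling = coupling,
                      n_individuals = n_individuals,
                      total_deletions = total_deletions, seed = seed)
      ),
      class = "syn_expression"
    )
  })
}

#' @export
print.syn_expression <- function(x, ...) {
  cat("<syn_expression>", nrow(x$genes), "genes,",
      x$params$n_tissues, "tissues,",
      sum(x$genes$is_hetr), "HETR,",
      nrow(x$deletions), "deletions\n")
  invisible(x)
}

#' Simulate a binned activity signal track coupled to deletion density
#'
#' Bins each sequence at `bin_size` (terminal partial bins keep their true
#' width); per bin the signal is baseline plus `coupling` times the local
#' planted-deletion count, plus independent Gaussian noise per replicate.
#' Two replicates share the bin set and the deletion-driven component and
#' differ only in noise.
#'
#' @param genome A `syn_genome` or named character vector (defines bin
#'   extents); alternatively a tibble of sequence lengths (`seqname`,
#'   `length`).
#' @param deletions Deletions tibble (`seqname`, `pos`).
#' @param coupling Signal increment per local deletion (0 = uncoupled).
#' @param bin_size Bin width in bp (default 1000).
#' @param seed RNG seed.
#' @param baseline Baseline signal level (default 5).
#' @param noise_sd Gaussian noise s.d. per replicate (default 1).
#' @return Tibble `seqname`, `start`, `end`, `width`, `rep1`, `rep2`
#'   (signals truncated at 0).
#' @export
simulate_signal_track <- function(genome, deletions, coupling,
                                  bin_size = 1000, seed = NULL,
                                  baseline = 5, noise_sd = 1) {
  stopifnot(bin_size >= 1)
  lens <- if (is.data.frame(genome)) {
    setNames(genome$length, genome$seqname)
  } else {
    seqs <- genome_sequences(genome)
    setNames(nchar(unname(seqs)), names(seqs))
  }
  bins <- purrr::map(names(lens), function(sq) {
    starts <- seq.int(0, lens[[sq]] - 1, by = bin_size)
    tibble(seqname = sq, start = as.integer(starts),
           end = as.integer(pmin(starts + bin_size, lens[[sq]])))
  }) |> bind_rows() |>
    mutate(width = .data$end - .data$start)
  counts <- integer(nrow(bins))
  if (nrow(deletions) > 0) {
    for (sq in unique(deletions$seqname)) {
      sel <- bins$seqname == sq
      idx <- findInterval(deletions$pos[deletions$seqname == sq],
                          bins$start[sel])
      counts[sel] <- tabulate(idx, nbins = sum(sel))
    }
  }
  with_seed(seed, {
    mu <- baseline + coupling * counts
    bins$rep1 <- pmax(0, mu + rnorm(nrow(bins), 0, noise_sd))
    bins$rep2 <- pmax(0, mu + rnorm(nrow(bins), 0, noise_sd))
    bins
  })
}
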