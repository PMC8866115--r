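# Spectrum comparison: cosine similarity, Dirichlet-multinomial null,
# complete-linkage clustering with bootstrap support, and sequence-logo
# construction with canonical orientation / right-alignment of 2 bp
# deletions.

#' Cosine similarity between two spectra
#'
#' `sum(a b) / (||a|| ||b||)`; scale-invariant, so counts and proportions
#' give the same value.
#'
#' @param a,b `indel_spectrum` objects or non-negative numeric vectors of
#'   equal length (same category order).
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0, 1), c(1, 1, 0))
cosine_similarity <- function(a, b) {
  av <- spectrum_counts(a)
  bv <- spectrum_counts(b)
  if (length(av) != length(bv)) abort("spectra must share one scheme")
  sa <- spectrum_scheme(a); sb <- spectrum_scheme(b)
  if (!is.na(sa) && !is.na(sb) && sa != sb) {
    abort("spectra must share one scheme")
  }
  na <- sqrt(sum(av^2)); nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for zero vectors")
  sum(av * bv) / (na * nb)
}

# n_pairs Dirichlet(1)-multinomial count-vector pairs and their cosines;
# vectorized via gamma draws.
dm_null_cosines <- function(n_categories, m1, m2, n_pairs) {
  draw <- function(m) {
    g <- matrix(rgamma(n_pairs * n_categories, shape = 1), nrow = n_categories)
    p <- sweep(g, 2, colSums(g), "/")
    vapply(seq_len(n_pairs), function(j) rmultinom(1, m, p[, j])[, 1],
           numeric(n_categories))
  }
  x <- draw(m1)
  y <- draw(m2)
  num <- colSums(x * y)
  den <- sqrt(colSums(x^2)) * sqrt(colSums(y^2))
  ifelse(den == 0, 0, num / den)
}

#' Empirical p-value for a cosine similarity under a Dirichlet-multinomial
#' null
#'
#' Simulates `n_pairs` pairs of count vectors: each vector is a multinomial
#' draw (trials `m1` resp. `m2` = the observed totals) over probabilities
#' drawn from a flat Dirichlet (concentration 1 per category). The p-value
#' is the add-one-smoothed fraction of null pairs whose cosine similarity
#' is at least the observed one.
#'
#' @param a,b Observed spectra (counts).
#' @param n_pairs Null pairs to simulate (default 10000).
#' @param seed RNG seed.
#' @return List: `cosine`, `p_value`, `n_pairs`, `null_cosines`.
#' @export
dm_cosine_pvalue <- function(a, b, n_pairs = 10000, seed = NULL) {
  av <- spectrum_counts(a)
  bv <- spectrum_counts(b)
  obs <- cosine_similarity(av, bv)
  nulls <- with_seed(seed,
    dm_null_cosines(length(av), sum(av), sum(bv), n_pairs))
  p <- (1 + sum(nulls >= obs)) / (n_pairs + 1)
  list(cosine = obs, p_value = p, n_pairs = n_pairs, null_cosines = nulls)
}

# Leaf-label sets of every internal node of an hclust tree.
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    take <- function(j) {
      if (j < 0) hc$labels[-j] else members[[j]]
    }
    members[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
  }
  lapply(members, paste, collapse = "|")
}

#' Cluster spectra with bootstrap support
#'
#' Complete-linkage hierarchical clustering on pairwise cosine distance
#' (1 - cosine similarity). Bootstrap replicates resample each spectrum's
#' mutations with replacement (multinomial at the observed totals),
#' recluster, and a join is supported when the exact leaf set of its subtree
#' reappears as a clade in the replicate tree; support is the percentage of
#' replicates supporting the join.
#'
#' @param spectra Named list of >= 3 spectra sharing one scheme.
#' @param B Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return `spectra_clust` object: `hclust`, `support` (percent per internal
#'   node, in `hclust` merge order), `B`, `labels`.
#' @export
cluster_spectra <- function(spectra, B = 1000, seed = NULL) {
  if (length(spectra) < 3) abort("need at least 3 spectra to cluster")
  counts <- vapply(spectra, spectrum_counts,
                   numeric(length(spectrum_counts(spectra[[1]]))))
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("S", seq_along(spectra))
  }
  cos_dist <- function(m) {
    nm <- ncol(m)
    dm <- matrix(0, nm, nm, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(nm)) {
      for (j in seq_len(nm)) {
        if (j > i) {
          dm[i, j] <- dm[j, i] <- 1 - cosine_similarity(m[, i], m[, j])
        }
      }
    }
    as.dist(dm)
  }
  hc <- hclust(cos_dist(counts), method = "complete")
  clades <- hclust_clades(hc)
  hits <- numeric(length(clades))
  with_seed(seed, {
    for (b in seq_len(B)) {
      bm <- apply(counts, 2, function(v) {
        tot <- sum(v)
        if (tot == 0) v else rmultinom(1, tot, v / tot)[, 1]
      })
      bhc <- hclust(cos_dist(bm), method = "complete")
      bclades <- hclust_clades(bhc)
      hits <- hits + (unlist(clades) %in% unlist(bclades))
    }
  })
  structure(
    list(hclust = hc, support = 100 * hits / B, B = B, labels = hc$labels),
    class = "spectra_clust"
  )
}

#' @export
print.spectra_clust <- function(x, ...) {
  cat("<spectra_clust>", length(x$labels), "spectra;",
      "bootstrap support (%):", paste(round(x$support), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export a spectra clustering as a Newick string with support values
#'
#' @param x A `spectra_clust` object.
#' @return Newick string (internal node labels carry bootstrap support).
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "spectra_clust"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the ape package")
  }
  ph <- ape::as.phylo(x$hclust)
  support_by_clade <- setNames(x$support, unlist(hclust_clades(x$hclust)))
  parts <- ape::prop.part(ph) # tip-index sets, one per internal node in order
  labs <- vapply(parts, function(idx) {
    key <- paste(sort(ph$tip.label[idx]), collapse = "|")
    val <- support_by_clade[key]
    if (is.na(val)) "" else as.character(round(val))
  }, character(1))
  ph$node.label <- labs
  ape::write.tree(ph)
}

#' Canonical oriented sequence window around a 2 bp deletion
#'
#' Extracts a window of `flank` bases on each side of the deleted
#' dinucleotide at its right-aligned register (most 3' T of the repeat/MH
#' region, else the region limit). The window is reverse-complemented when
#' the deleted dinucleotide contains an A, except when it is AT or TA.
#' Windows running off the sequence end are padded with `N`.
#'
#' @param classified One or more classified 2 bp deletions
#'   ([classify_deletions()] output).
#' @param genome Named character vector or [syn_genome].
#' @param flank Flanking bases on each side (default 10).
#' @return Tibble: input columns plus `window` (length `2 * flank + 2`),
#'   `oriented_dinucleotide`, `flipped`, `padded`.
#' @export
canonicalize_context <- function(classified, genome, flank = 10) {
  seqs <- genome_sequences(genome)
  stopifnot(all(classified$length == 2))
  n <- nrow(classified)
  window <- character(n); flipped <- logical(n); padded <- logical(n)
  oriented <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[[classified$seqname[i]]]
    ra <- classified$right_aligned_start[i] # 0-based
    lo <- ra - flank + 1                    # 1-based window coords
    hi <- ra + 2 + flank
    pad_l <- max(0, 1 - lo)
    pad_r <- max(0, hi - nchar(s))
    core <- substr(s, max(1, lo), min(nchar(s), hi))
    w <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
    del <- substr(s, ra + 1, ra + 2)
    flip <- grepl("A", del) && !del %in% c("AT", "TA")
    if (flip) {
      w <- revcomp(w)
      del <- revcomp(del)
    }
    window[i] <- w
    flipped[i] <- flip
    padded[i] <- pad_l > 0 || pad_r > 0
    oriented[i] <- del
  }
  mutate(classified, window = window, oriented_dinucleotide = oriented,
         flipped = flipped, padded = padded)
}

#' Build a two-bit information-content logo matrix
#'
#' Per column, information content is `2 + sum_b f_b log2 f_b` (Shannon; no
#' small-sample correction, available via `correct = TRUE`); each cell is
#' `f_b * information`. `N` characters are excluded per column.
#'
#' @param windows Character vector of equal-length windows over `ACGTN`.
#' @param correct Apply the small-sample correction `(3 / (2 ln 2)) / n`
#'   subtracted from column information (default `FALSE`).
#' @return `logo_matrix` object: positions x 4 numeric matrix of bit
#'   contributions, with `n_sequences` attribute.
#' @export
build_logo <- function(windows, correct = FALSE) {
  if (length(windows) == 0) abort("no windows supplied")
  wl <- unique(nchar(windows))
  if (length(wl) != 1) abort("windows must have equal length")
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  mat <- matrix(0, nrow = wl, ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(wl)) {
    col <- chars[, j]
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0) next
    f <- as.numeric(table(factor(col, levels = DNA_BASES))) / length(col)
    nz <- f > 0
    info <- 2 + sum(f[nz] * log2(f[nz]))
    if (correct) info <- max(0, info - (3 / (2 * log(2))) / length(col))
    mat[j, ] <- f * info
  }
  structure(mat, class = c("logo_matrix", "matrix"),
            n_sequences = length(windows))
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("<logo_matrix>", nrow(x), "positions,",
      attr(x, "n_sequences"), "sequences\n")
  print(unclass(round(x, 3)))
  invisible(x)
}
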