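#' Beta-sim compositional turnover between two assemblages
#'
#' Richness-independent turnover index `min(b, c) / (min(b, c) + a)`,
#' where `a` is the number of taxa shared by the two cells and `b`, `c`
#' the numbers unique to each.  0 means identical taxon lists, 1 means no
#' shared taxa; inflating the richer cell's unique count leaves the value
#' unchanged, which is what makes the index suitable for regionalization
#' across strong richness gradients.
#'
#' @param set_i,set_j vectors of taxon identifiers (at least one
#'   non-empty).
#' @return turnover in \[0, 1\].
#' @export
beta_sim <- function(set_i, set_j) {
  set_i <- unique(set_i); set_j <- unique(set_j)
  if (length(set_i) == 0 && length(set_j) == 0) {
    abort("beta-sim is undefined for two empty assemblages")
  }
  a <- length(intersect(set_i, set_j))
  b <- length(set_i) - a
  c_ <- length(set_j) - a
  m <- min(b, c_)
  if (m + a == 0) return(NaN)  # one empty cell; excluded upstream
  m / (m + a)
}

#' Pairwise beta-sim dissimilarity matrix
#'
#' Computes beta-sim between every pair of non-empty cells of a stacked
#' presence/absence matrix, optionally after aggregating species to
#' genera (a cell has a genus iff it has at least one member species).
#' Cells with zero taxa are excluded with an informative census.
#'
#' @param pa a `pa_matrix` or binary matrix (rows = cells, named).
#' @param level `"species"` or `"genus"`.
#' @param genus_map tibble `species`, `genus` (required at genus level).
#' @return a `dissim_matrix`: symmetric numeric matrix with zero diagonal,
#'   dimnames = retained cell ids, and attribute `excluded_cells`.
#' @export
dissimilarity_matrix <- function(pa, level = c("species", "genus"),
                                 genus_map = NULL) {
  level <- match.arg(level)
  m <- if (inherits(pa, "pa_matrix")) pa$pa else pa
  if (level == "genus") {
    if (is.null(genus_map)) abort("genus level requires `genus_map`")
    gen <- genus_map$genus[match(colnames(m), genus_map$species)]
    if (anyNA(gen)) abort("genus_map does not cover all species")
    m <- t(rowsum(t(m), gen)) > 0
    storage.mode(m) <- "integer"
  }
  occ <- rowSums(m)
  excluded <- rownames(m)[occ == 0]
  if (length(excluded) > 0) {
    inform(sprintf("%d empty cells excluded from the dissimilarity matrix",
                   length(excluded)))
    m <- m[occ > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least two non-empty cells")
  a <- tcrossprod(m)                      # shared taxa per pair
  r <- rowSums(m)
  b <- outer(r, rep(1, length(r))) - a    # unique to cell i
  cc <- t(b)                              # unique to cell j
  mn <- pmin(b, cc)
  d <- mn / (mn + a)
  d[mn + a == 0] <- NaN
  diag(d) <- 0
  dimnames(d) <- dimnames(a)
  structure(d, class = c("dissim_matrix", "matrix"),
            excluded_cells = excluded)
}

#' Shared/unique taxon counts for one cell pair
#'
#' @param pa a `pa_matrix` or binary matrix.
#' @param cell_i,cell_j cell ids (row names).
#' @return one-row tibble `a`, `b`, `c`.
#' @export
beta_sim_components <- function(pa, cell_i, cell_j) {
  m <- if (inherits(pa, "pa_matrix")) pa$pa else pa
  si <- m[as.character(cell_i), ] > 0
  sj <- m[as.character(cell_j), ] > 0
  tibble(a = sum(si & sj), b = sum(si & !sj), c = sum(!si & sj))
}

#' UPGMA dendrogram of a dissimilarity matrix
#'
#' Unweighted pair-group average-linkage agglomeration, the standard
#' choice for floristic cluster analysis; the result is an ultrametric
#' merge tree with non-decreasing heights.
#'
#' @param d a `dissim_matrix` (or any symmetric dissimilarity matrix /
#'   `dist`).
#' @return an `hclust` object (labels = cell ids).
#' @export
upgma <- function(d) {
  dd <- if (inherits(d, "dist")) d else as.dist(d)
  if (attr(dd, "Size") < 2) abort("need at least two items to cluster")
  hclust(dd, method = "average")
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Indicator species analysis (IndVal) for a clustering
#'
#' Dufrene-Legendre indicator value of each species for each cluster:
#' specificity (the species' relative frequency in the cluster divided by
#' the sum of its relative frequencies over all clusters) times fidelity
#' (the fraction of the cluster's cells holding the species) times 100.
#' A species' score is its maximum over clusters; significance comes from
#' Monte-Carlo permutation of the cell-to-cluster labels.
#'
#' @param pa a `pa_matrix` or binary matrix (rows = cells).
#' @param labels cluster label per row of `pa` (>= 2 non-empty clusters).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed.
#' @return tibble `species`, `cluster` (the maximizing cluster),
#'   `indval`, `p_value` where
#'   `p_value = (1 + #\{perm >= observed\}) / (n_perm + 1)`.
#' @export
indval <- function(pa, labels, n_perm = 999, seed = NULL) {
  m <- if (inherits(pa, "pa_matrix")) pa$pa else pa
  labels <- as.vector(labels)
  if (length(labels) != nrow(m)) abort("one label per cell required")
  if (dplyr::n_distinct(labels) < 2) abort("need at least two clusters")
  obs <- indval_scores(m, labels)
  with_seed(seed, {
    exceed <- rep(0L, ncol(m))
    for (r in seq_len(n_perm)) {
      perm <- indval_scores(m, sample(labels))
      exceed <- exceed + (perm$score >= obs$score)
    }
    tibble(species = colnames(m), cluster = obs$cluster,
           indval = obs$score, p_value = (1 + exceed) / (n_perm + 1))
  })
}

indval_scores <- function(m, labels) {
  lev <- sort(unique(labels))
  member <- outer(labels, lev, "==") * 1
  nk <- colSums(member)
  counts <- crossprod(m, member)          # species x cluster presence counts
  relfreq <- sweep(counts, 2, nk, "/")    # fidelity B
  tot <- rowSums(relfreq)
  spec <- relfreq / ifelse(tot > 0, tot, 1)  # specificity A
  iv <- spec * relfreq * 100
  best <- max.col(iv, ties.method = "first")
  list(score = iv[cbind(seq_len(nrow(iv)), best)], cluster = lev[best])
}

#' Select the number of bioregions by summed indicator p-values
#'
#' For each of `n_repeats` seeded subsamples of cells, the subsample's
#' UPGMA tree is cut at every candidate `k`, indicator species analysis
#' is run on the resulting labels, and the sum of the species p-values is
#' recorded; the curves are averaged over repeats and the `k` minimizing
#' the mean summed p-value is chosen.  Final region labels come from
#' cutting the full-matrix dendrogram at the chosen `k`.
#'
#' @param pa a `pa_matrix` (or binary matrix) over the cells to
#'   regionalize.
#' @param d optional precomputed `dissim_matrix` for the full cell set
#'   (computed from `pa` if `NULL`).
#' @param k_range candidate cluster numbers (default `2:30`).
#' @param subsample_size cells per subsample (default `min(1000,
#'   n_cells)`).
#' @param n_repeats number of subsampling repeats (default 5).
#' @param n_perm permutations per indicator analysis (default 999).
#' @param seed RNG seed.
#' @return a `regionalization` object: list with `k` (chosen), `labels`
#'   (tibble `cell_id`, `region` over non-empty cells), `dendrogram`
#'   (full-matrix `hclust`), `curve` (tibble `k`, `repeat`, `summed_p`)
#'   and `mean_curve` (tibble `k`, `summed_p`).
#' @export
optimal_k <- function(pa, d = NULL, k_range = 2:30, subsample_size = NULL,
                      n_repeats = 5, n_perm = 999, seed = NULL) {
  m <- if (inherits(pa, "pa_matrix")) pa$pa else pa
  m <- m[rowSums(m) > 0, , drop = FALSE]
  n <- nrow(m)
  if (is.null(subsample_size)) subsample_size <- min(1000L, n)
  subsample_size <- min(subsample_size, n)
  if (max(k_range) >= subsample_size) {
    abort("max(k_range) must be smaller than the subsample size")
  }
  if (is.null(d)) d <- dissimilarity_matrix(m)
  seeds <- child_seeds(seed, n_repeats + 1)
  curves <- purrr::map(seq_len(n_repeats), function(r) {
    idx <- with_seed(seeds[[r]], sort(sample(n, subsample_size)))
    ms <- m[idx, , drop = FALSE]
    ds <- unclass(d)[idx, idx]
    hc <- upgma(ds)
    perm_seeds <- child_seeds(seeds[[r]], length(k_range))
    purrr::map2(k_range, perm_seeds, function(k, s) {
      labels <- cutree(hc, k)
      iv <- indval(ms, labels, n_perm = n_perm, seed = s)
      tibble(k = k, rep = r, summed_p = sum(iv$p_value))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  mean_curve <- curves |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(summed_p = mean(.data$summed_p), .groups = "drop")
  k_best <- mean_curve$k[which.min(mean_curve$summed_p)]
  hc_full <- upgma(d)
  labels <- cutree(hc_full, k_best)
  structure(list(
    k = k_best,
    labels = tibble(cell_id = as.integer(rownames(m)),
                    region = as.integer(labels)),
    dendrogram = hc_full,
    curve = dplyr::rename(curves, `repeat` = "rep"),
    mean_curve = mean_curve,
    subsample_size = subsample_size, n_repeats = n_repeats,
    n_perm = n_perm, seed = seed
  ), class = "regionalization")
}

#' Cut an existing regionalization dendrogram at a different k
#'
#' @param x a `regionalization` object.
#' @param k number of regions.
#' @return tibble `cell_id`, `region`.
#' @export
cut_regions <- function(x, k) {
  tibble(cell_id = x$labels$cell_id,
         region = as.integer(cutree(x$dendrogram, k)))
}

#' @export
print.regionalization <- function(x, ...) {
  cat(sprintf(
    "<regionalization> %d cells in %d regions (chosen from k = %d..%d, %d x %d-cell subsamples)\n",
    nrow(x$labels), x$k, min(x$mean_curve$k), max(x$mean_curve$k),
    x$n_repeats, x$subsample_size))
  invisible(x)
}

#' Tidy a regionalization
#'
#' `tidy()` returns the per-cell region labels; `glance()` the chosen k
#' and the summed-p minimum.
#'
#' @param x a `regionalization`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy regionalization
#' @export
tidy.regionalization <- function(x, ...) x$labels

#' @rdname tidy.regionalization
#' @method glance regionalization
#' @export
glance.regionalization <- function(x, ...) {
  tibble(k = x$k, min_summed_p = min(x$mean_curve$summed_p),
         n_cells = nrow(x$labels), n_repeats = x$n_repeats,
         subsample_size = x$subsample_size)
}
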