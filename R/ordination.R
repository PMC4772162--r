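#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (monotone regression of ordination distances on
#' the input dissimilarities) with `n_starts` seeded random initial
#' configurations to avoid local minima; the best (lowest-stress)
#' solution is returned, centered and rotated to its principal axes.
#' Stress lies in \[0, 1\]: 0 means the configuration reproduces the rank
#' order of the dissimilarities perfectly.
#'
#' @param d a `dissim_matrix`, symmetric matrix or `dist`.
#' @param n_dims ordination dimensionality (default 2).
#' @param n_starts number of random starts (default 100).
#' @param max_iter iteration cap per start.
#' @param seed RNG seed; the same seed reproduces the scores exactly.
#' @return an `ordination` object: list with `scores` (n x `n_dims`
#'   matrix, rownames = cell ids, columns centered), `stress` (best),
#'   `stresses` (per start), `converged` (logical per start),
#'   `best_start`, `n_starts`.
#' @export
nmds_ordination <- function(d, n_dims = 2, n_starts = 100, max_iter = 500,
                            seed = NULL) {
  if (n_dims < 1) abort("`n_dims` must be >= 1")
  dd <- if (inherits(d, "dist")) d else as.dist(d)
  n <- attr(dd, "Size")
  seeds <- child_seeds(seed, n_starts)
  best <- NULL
  stresses <- numeric(n_starts)
  converged <- logical(n_starts)
  for (s in seq_len(n_starts)) {
    init <- with_seed(seeds[[s]], matrix(rnorm(n * n_dims), n, n_dims))
    fit <- vegan::monoMDS(dd, y = init, k = n_dims, model = "global",
                          maxit = max_iter, smin = 1e-7, sratmax = 0.999999)
    stresses[s] <- fit$stress
    converged[s] <- fit$icause %in% c(2L, 3L, 4L)  # a stopping criterion other
                                                   # than the iteration cap
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_start <- s
    }
  }
  if (!any(converged)) {
    abort(sprintf(
      "no NMDS start converged in %d iterations (stress range %.4g-%.4g)",
      max_iter, min(stresses), max(stresses)))
  }
  scores <- best$points
  scores <- scale(scores, scale = FALSE)
  if (n_dims > 1) scores <- prcomp(scores, center = FALSE)$x
  colnames(scores) <- paste0("NMDS", seq_len(n_dims))
  rownames(scores) <- labels(dd) %||% as.character(seq_len(n))
  structure(list(scores = scores, stress = best$stress,
                 stresses = stresses, converged = converged,
                 best_start = best_start, n_starts = n_starts),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d points, %d axes, stress %.4f (best of %d starts, %d converged)\n",
              nrow(x$scores), ncol(x$scores), x$stress, x$n_starts,
              sum(x$converged)))
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each predictor, the standardized variable is regressed on the
#' ordination axes; the squared multiple correlation r^2 measures how
#' much of the predictor's variance the ordination explains, the
#' normalized coefficient vector gives the direction of fastest increase,
#' and a permutation test (shuffling the predictor across cells) gives
#' the p-value.  Vectors significant at `alpha` are the environmental
#' correlates of the turnover pattern.
#'
#' @param ord an [nmds_ordination()] result.
#' @param env tibble `cell_id` + predictors; must cover the ordination's
#'   cells (matched by cell id).
#' @param n_perm number of permutations (default 999).
#' @param alpha significance threshold for the `significant` flag
#'   (default 0.001).
#' @param seed RNG seed.
#' @return tibble with one row per predictor: `predictor`, direction
#'   cosines `cos1`, `cos2`, ..., `r2`,
#'   `p_value = (1 + #\{perm r2 >= observed\}) / (n_perm + 1)`,
#'   `significant`.
#' @export
fit_env_vectors <- function(ord, env, n_perm = 999, alpha = 0.001,
                            seed = NULL) {
  cells <- rownames(ord$scores)
  idx <- match(cells, as.character(env$cell_id))
  if (anyNA(idx)) abort("`env` does not cover all ordination cells")
  vals <- env_values(env)[idx, , drop = FALSE]
  X <- scale(ord$scores, scale = FALSE)
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  n <- nrow(X)
  k <- ncol(X)
  with_seed(seed, {
    rows <- purrr::map(colnames(vals), function(p) {
      v <- vals[, p]
      if (sd(v) == 0) {
        return(tibble(predictor = p,
                      !!!setNames(as.list(rep(NA_real_, k)),
                                  paste0("cos", seq_len(k))),
                      r2 = 0, p_value = 1, significant = FALSE))
      }
      vc <- v - mean(v)
      sst <- sum(vc^2)
      r2 <- sum(crossprod(Q, vc)^2) / sst
      b <- qr.coef(qrX, vc)
      dir <- b / sqrt(sum(b^2))
      perms <- vapply(seq_len(n_perm), function(r) {
        vp <- vc[sample.int(n)]
        vp <- vp - mean(vp)
        sum(crossprod(Q, vp)^2) / sum(vp^2)
      }, numeric(1))
      pv <- (1 + sum(perms >= r2)) / (n_perm + 1)
      tibble(predictor = p,
             !!!setNames(as.list(unname(dir)), paste0("cos", seq_len(k))),
             r2 = r2, p_value = pv, significant = pv < alpha)
    })
    dplyr::bind_rows(rows)
  })
}

#' Getis-Ord Gi* statistic for a cell set
#'
#' Tests whether the values inside a region differ from the global
#' distribution, with binary weights (1 for region cells, 0 otherwise):
#' `z = (sum_region x - n_r * mean(x)) / (S * sqrt((n * n_r - n_r^2) /
#' (n - 1)))` with `S` the global (population) standard deviation.
#' |z| > 2 marks a region whose environment differs significantly from
#' the whole domain; the sign follows the region mean relative to the
#' global mean.
#'
#' @param values per-cell numeric vector over all cells (non-constant).
#' @param region_cells indices (1-based positions into `values`) or, if
#'   `values` is named, names of the region's cells; must be a strict
#'   non-empty subset.
#' @return the z value.
#' @export
gi_star <- function(values, region_cells) {
  n <- length(values)
  if (is.character(region_cells)) {
    region_cells <- match(region_cells, names(values))
  }
  n_r <- length(region_cells)
  if (n_r == 0 || n_r >= n) {
    abort("region must be a non-empty strict subset of the cells")
  }
  if (sd(values) == 0) abort("Gi* is undefined for constant values")
  xbar <- mean(values)
  s_pop <- sqrt(mean(values^2) - xbar^2)
  (sum(values[region_cells]) - n_r * xbar) /
    (s_pop * sqrt((n * n_r - n_r^2) / (n - 1)))
}

#' Relative environmental turnover table (per-region Gi*)
#'
#' Characterizes each bioregion environmentally: the predictors are
#' aggregated to a coarsened grid (mean within each block of
#' `factor x factor` cells), region labels are transferred by majority
#' vote, and the Getis-Ord Gi* statistic is computed for every (region,
#' predictor) pair.  Regions that vanish after coarsening are flagged
#' with `NA` rows.
#'
#' @param labels tibble `cell_id`, `region` (e.g. from a
#'   `regionalization`).
#' @param env tibble `cell_id` + predictors on the fine grid.
#' @param grid the fine [make_grid()] domain.
#' @param factor integer coarsening factor (1 = no coarsening).
#' @return a `gi_star_table`: long tibble `region`, `predictor`, `gi_z`,
#'   `significant` (|z| > 2).
#' @export
ret_table <- function(labels, env, grid, factor = 2) {
  if (inherits(labels, "regionalization")) labels <- labels$labels
  co <- coarsen_grid(grid, factor)
  map <- co$mapping
  lab <- dplyr::left_join(map, labels, by = c(fine_cell_id = "cell_id"))
  # majority-vote region per coarse cell (ties -> smallest region id)
  clab <- lab |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::count(.data$coarse_cell_id, .data$region) |>
    dplyr::group_by(.data$coarse_cell_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$region, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  ev <- env_values(env)
  cenv <- rowsum(ev[match(map$fine_cell_id, env$cell_id), , drop = FALSE],
                 map$coarse_cell_id) /
    as.vector(table(map$coarse_cell_id)[as.character(sort(unique(map$coarse_cell_id)))])
  coarse_ids <- sort(unique(map$coarse_cell_id))
  region_of <- clab$region[match(coarse_ids, clab$coarse_cell_id)]
  regions <- sort(unique(labels$region))
  rows <- purrr::map(regions, function(r) {
    in_r <- which(!is.na(region_of) & region_of == r)
    purrr::map(colnames(cenv), function(p) {
      z <- if (length(in_r) == 0 || length(in_r) >= length(coarse_ids)) {
        NA_real_
      } else {
        gi_star(cenv[, p], in_r)
      }
      tibble(region = r, predictor = p, gi_z = z,
             significant = !is.na(z) & abs(z) > 2)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(rows, class = c("gi_star_table", class(tibble())))
}

#' Pivot a Gi* table to the regions-as-columns layout
#'
#' @param x a `gi_star_table`.
#' @return wide tibble, one row per predictor, one column per region.
#' @export
gi_star_wide <- function(x) {
  tidyr::pivot_wider(as_tibble(x)[c("region", "predictor", "gi_z")],
                     names_from = "region", values_from = "gi_z",
                     names_prefix = "region_")
}
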