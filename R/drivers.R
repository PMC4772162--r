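#' Cubic trend-surface terms of the grid coordinates
#'
#' The nine spatial terms of a third-degree trend surface — LON, LAT,
#' LON^2, LON*LAT, LAT^2, LON^3, LON^2*LAT, LON*LAT^2, LAT^3 — computed on
#' coordinates centered on their mean and scaled to unit range (an affine
#' change that leaves the explained variance of any model using the block
#' unchanged while keeping the cubic terms well-conditioned).
#'
#' @param grid a [make_grid()] domain with at least two distinct
#'   longitudes and latitudes.
#' @return tibble `cell_id` + nine term columns `LON`, `LAT`, `LON2`,
#'   `LONxLAT`, `LAT2`, `LON3`, `LON2xLAT`, `LONxLAT2`, `LAT3`.
#' @export
trend_surface_terms <- function(grid) {
  if (dplyr::n_distinct(grid$lon) < 2 || dplyr::n_distinct(grid$lat) < 2) {
    abort("grid must span at least two distinct longitudes and latitudes")
  }
  x <- (grid$lon - mean(grid$lon)) / diff(range(grid$lon))
  y <- (grid$lat - mean(grid$lat)) / diff(range(grid$lat))
  tibble(cell_id = grid$cell_id,
         LON = x, LAT = y,
         LON2 = x^2, LONxLAT = x * y, LAT2 = y^2,
         LON3 = x^3, LON2xLAT = x^2 * y, LONxLAT2 = x * y^2, LAT3 = y^3)
}

adj_r2 <- function(y, X) {
  fit <- lm(y ~ ., data = as.data.frame(X))
  summary(fit)$adj.r.squared
}

#' Variation partitioning of richness between environment and space
#'
#' Fits three least-squares models — environment only (E), trend-surface
#' space only (S), and combined (E+S) — and decomposes the combined
#' adjusted R^2 into the classic fractions: pure environment
#' `R2(E+S) - R2(S)`, pure space `R2(E+S) - R2(E)`, shared
#' `R2(E) + R2(S) - R2(E+S)` and unexplained `1 - R2(E+S)`.  Slightly
#' negative fractions can occur (an adjusted-R^2 artifact) and are
#' reported as-is; the four fractions always sum to 1.
#'
#' @param richness per-cell response: numeric vector ordered by cell id,
#'   or a tibble with columns `cell_id`, `richness`.
#' @param env tibble `cell_id` + environmental predictors.
#' @param space tibble from [trend_surface_terms()].
#' @return one-row tibble: `adj_r2_env`, `adj_r2_space`,
#'   `adj_r2_combined`, `pure_env`, `pure_space`, `shared`, `unexplained`.
#' @export
variation_partition <- function(richness, env, space) {
  y <- resolve_response(richness, env$cell_id)
  E <- env_values(env)
  S <- as.matrix(space[setdiff(names(space), "cell_id")])
  if (nrow(env) <= ncol(E) + ncol(S) + 1) {
    abort("need more cells than combined predictors")
  }
  r2_e <- adj_r2(y, E)
  r2_s <- adj_r2(y, S)
  r2_es <- adj_r2(y, cbind(E, S))
  tibble(adj_r2_env = r2_e, adj_r2_space = r2_s, adj_r2_combined = r2_es,
         pure_env = r2_es - r2_s, pure_space = r2_es - r2_e,
         shared = r2_e + r2_s - r2_es, unexplained = 1 - r2_es)
}

resolve_response <- function(richness, cell_ids) {
  if (is.data.frame(richness)) {
    y <- richness$richness[match(cell_ids, richness$cell_id)]
    if (anyNA(y)) abort("richness missing for some cells")
    y
  } else {
    if (length(richness) != length(cell_ids)) {
      abort("richness vector length must match the number of cells")
    }
    as.numeric(richness)
  }
}

#' Forward stepwise regression of richness on environmental predictors
#'
#' Predictors are standardized internally so coefficients are standardized
#' betas.  At each step the candidate whose addition yields the largest
#' gain in cumulative adjusted R^2 — among candidates whose partial-F
#' p-value is below `alpha_enter` — is entered; selection stops when no
#' candidate qualifies.  Betas and t-values are reported for the final
#' model.
#'
#' @param richness response (vector ordered by cell id, or tibble
#'   `cell_id`, `richness`).
#' @param env tibble `cell_id` + predictors.
#' @param alpha_enter entry significance level (default 0.05).
#' @return a `richness_model`: list with `steps` (tibble `step`, `term`,
#'   `adj_r2_cum`), `coefficients` (tibble `term`, `beta`, `t_value`,
#'   `p_value` for the final model), and the final `lm` fit (`model`).
#'   An empty model (no qualifying predictor) is returned with a warning.
#' @export
stepwise_regression <- function(richness, env, alpha_enter = 0.05) {
  y <- resolve_response(richness, env$cell_id)
  X <- zscore_cols(env_values(env))
  ys <- (y - mean(y)) / if (sd(y) > 0) sd(y) else 1
  preds <- colnames(X)
  selected <- character()
  steps <- list()
  repeat {
    remaining <- setdiff(preds, selected)
    if (length(remaining) == 0) break
    base_r2 <- if (length(selected) == 0) 0 else
      adj_r2(ys, X[, selected, drop = FALSE])
    cand <- purrr::map(remaining, function(p) {
      d <- as.data.frame(X[, c(selected, p), drop = FALSE])
      fit <- lm(ys ~ ., data = d)
      sm <- summary(fit)
      co <- sm$coefficients
      pv <- if (p %in% rownames(co)) co[p, 4] else NA_real_
      tibble(term = p, adj_r2 = sm$adj.r.squared, p_value = pv)
    }) |> dplyr::bind_rows()
    ok <- dplyr::filter(cand, !is.na(.data$p_value),
                        .data$p_value < alpha_enter,
                        .data$adj_r2 > base_r2)
    if (nrow(ok) == 0) break
    best <- ok$term[which.max(ok$adj_r2)]
    selected <- c(selected, best)
    steps[[length(steps) + 1]] <- tibble(
      step = length(selected), term = best,
      adj_r2_cum = max(ok$adj_r2))
  }
  if (length(selected) == 0) {
    warn("no predictor qualified for entry; returning an empty model")
    return(structure(list(
      steps = tibble(step = integer(), term = character(),
                     adj_r2_cum = numeric()),
      coefficients = tibble(term = character(), beta = numeric(),
                            t_value = numeric(), p_value = numeric()),
      model = NULL), class = "richness_model"))
  }
  final <- lm(ys ~ ., data = as.data.frame(X[, selected, drop = FALSE]))
  co <- summary(final)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  # lm backticks non-syntactic names; map back to predictor names
  rn <- gsub("`", "", rownames(co))
  structure(list(
    steps = dplyr::bind_rows(steps),
    coefficients = tibble(term = rn, beta = co[, 1], t_value = co[, 3],
                          p_value = co[, 4]),
    model = final), class = "richness_model")
}

#' @export
print.richness_model <- function(x, ...) {
  cat(sprintf("<richness_model> %d predictors entered", nrow(x$steps)))
  if (nrow(x$steps) > 0) {
    cat(sprintf(", final adjusted R^2 = %.3f",
                x$steps$adj_r2_cum[nrow(x$steps)]))
  }
  cat("\n")
  if (nrow(x$steps) > 0) print(x$steps)
  invisible(x)
}

#' Tidy a stepwise richness model
#'
#' `tidy()` returns the entry-ordered table of selected predictors with
#' cumulative adjusted R^2, standardized beta and final-model t-value;
#' `glance()` a one-row model summary.
#'
#' @param x a `richness_model`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy richness_model
#' @export
tidy.richness_model <- function(x, ...) {
  dplyr::left_join(x$steps, x$coefficients, by = "term")
}

#' @rdname tidy.richness_model
#' @method glance richness_model
#' @export
glance.richness_model <- function(x, ...) {
  tibble(n_predictors = nrow(x$steps),
         adj_r2 = if (nrow(x$steps) > 0)
           x$steps$adj_r2_cum[nrow(x$steps)] else 0)
}

#' Moran's I spatial autocorrelation
#'
#' Standard Moran's I with row-standardized rook-contiguity weights (or a
#' caller-supplied weight matrix), expected value -1/(n-1) under the
#' null, and the normal-approximation z and two-sided p-value.
#'
#' @param values per-cell numeric vector ordered by `cell_id` (non
#'   constant).
#' @param grid a [make_grid()] domain (ignored if `weights` given).
#' @param weights optional n x n spatial weight matrix.
#' @return one-row tibble: `i`, `expected`, `sd`, `z`, `p_value`.
#' @export
morans_i <- function(values, grid = NULL, weights = NULL) {
  if (sd(values) == 0) abort("Moran's I is undefined for constant values")
  if (is.null(weights)) {
    if (is.null(grid)) abort("supply `grid` or `weights`")
    weights <- rook_weights(grid)
  }
  res <- ape::Moran.I(values, weight = weights, scaled = FALSE,
                      alternative = "two.sided")
  tibble(i = res$observed, expected = res$expected, sd = res$sd,
         z = (res$observed - res$expected) / res$sd, p_value = res$p.value)
}
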