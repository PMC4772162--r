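#' Prune collinear environmental predictors
#'
#' Greedy rank-correlation pruning: predictors are visited in priority
#' order (the analyst's ranking of ecological meaningfulness); a predictor
#' is dropped when its absolute Spearman correlation with any
#' already-retained predictor reaches `rho_max`.  The surviving set has
#' all pairwise |rho| below the cutoff, and the result is independent of
#' the column order of `env` given a fixed priority list.
#'
#' @param env tibble `cell_id` + predictor columns.
#' @param rho_max Spearman correlation cutoff (default 0.75).
#' @param priority character vector ordering all predictors from most to
#'   least preferred; defaults to the column order of `env`.
#' @return the pruned `env` tibble (columns in priority order), with
#'   attribute `dropped`: a tibble `dropped`, `partner`, `rho` listing
#'   each removed predictor, the retained predictor that triggered the
#'   removal, and their correlation.
#' @export
prune_predictors <- function(env, rho_max = 0.75, priority = NULL) {
  if (rho_max <= 0 || rho_max >= 1) abort("`rho_max` must be in (0, 1)")
  preds <- setdiff(names(env), "cell_id")
  if (is.null(priority)) priority <- preds
  if (!setequal(priority, preds)) {
    abort("`priority` must list exactly the predictors in `env`")
  }
  vals <- env_values(env)
  rho <- cor(vals, method = "spearman")
  kept <- character()
  dropped <- list()
  for (p in priority) {
    r <- abs(rho[p, kept, drop = TRUE])
    hit <- which(r >= rho_max)
    if (length(hit) == 0) {
      kept <- c(kept, p)
    } else {
      partner <- kept[hit[which.max(r[hit])]]
      dropped[[p]] <- tibble(dropped = p, partner = partner,
                             rho = rho[p, partner])
    }
  }
  out <- env[c("cell_id", kept)]
  attr(out, "dropped") <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble(dropped = character(), partner = character(), rho = numeric())
  out
}

#' Chi-square test for environmental collection bias
#'
#' Tests, per predictor, whether the collection localities are a random
#' subsample of the domain's environmental space: the predictor's range
#' over all domain cells is split into `n_bins` equal-interval bins,
#' expected counts are the domain bin proportions scaled to the number of
#' collection cells, observed counts are the collection-cell bin counts,
#' and a Pearson chi-square statistic is computed.  Bins empty over the
#' whole domain are merged into their nearest non-empty neighbour with the
#' degrees of freedom reduced accordingly.
#'
#' @param env tibble `cell_id` + predictor columns (all domain cells).
#' @param collection_cells integer vector of cell ids holding collections.
#' @param n_bins number of equal-interval bins (default 10).
#' @param alpha significance level for the biased flag (default 0.05).
#' @return a `bias_report` tibble with one row per predictor: `predictor`,
#'   `statistic`, `df`, `p_value`, `biased`, `n_bins_used`; constant
#'   (untestable) predictors get `NA` statistics and `biased = NA` with a
#'   warning.  Attributes: `n_bins`, `n_collection_cells`, `alpha`.
#' @export
bias_test <- function(env, collection_cells, n_bins = 10, alpha = 0.05) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  if (!all(collection_cells %in% env$cell_id)) {
    abort("collection cells must lie inside the domain")
  }
  vals <- env_values(env)
  sel <- match(collection_cells, env$cell_id)
  rows <- purrr::map(colnames(vals), function(p) {
    x <- vals[, p]
    rng <- range(x)
    if (diff(rng) == 0) {
      return(tibble(predictor = p, statistic = NA_real_, df = NA_integer_,
                    p_value = NA_real_, biased = NA, n_bins_used = NA_integer_))
    }
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE)
    dom <- tabulate(bin, n_bins)
    obs <- tabulate(bin[sel], n_bins)
    # merge domain-empty bins into the nearest occupied bin
    occupied <- which(dom > 0)
    grp <- vapply(seq_len(n_bins), function(b) {
      occupied[which.min(abs(occupied - b))]
    }, integer(1))
    dom_m <- as.numeric(tapply(dom, grp, sum))
    obs_m <- as.numeric(tapply(obs, grp, sum))
    expect <- dom_m / sum(dom_m) * length(sel)
    stat <- sum((obs_m - expect)^2 / expect)
    df <- length(dom_m) - 1L
    pv <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else 1
    tibble(predictor = p, statistic = stat, df = df, p_value = pv,
           biased = pv < alpha, n_bins_used = length(dom_m))
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$statistic)) {
    warn(sprintf("constant predictors excluded from bias test: %s",
                 paste(out$predictor[is.na(out$statistic)], collapse = ", ")))
  }
  structure(out,
            class = c("bias_report", class(tibble())),
            n_bins = n_bins, n_collection_cells = length(collection_cells),
            alpha = alpha)
}
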