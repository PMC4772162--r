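#' Null AUC distribution from collection localities
#'
#' Bias-corrected null model for presence-only SDM accuracy: each
#' replicate draws `n_records` cells uniformly without replacement from
#' the actual collection localities, fits an SDM with the same feature
#' rule a real species of that sample size would get, and records its AUC
#' against the same background.  Because the null species inherit the
#' collecting bias, a species must outperform what bias alone produces to
#' be declared non-random.  All species with the same number of records
#' share one null distribution, so results are cached by `n_records`.
#'
#' @param n_records number of presence cells of the species being tested.
#' @param collection_cells integer vector of all collection localities.
#' @param env pruned predictor tibble over the whole domain.
#' @param n_null number of null replicates (default 1000).
#' @param regularization_multiplier passed to [fit_sdm()].
#' @param seed RNG seed; replicates use independent child seeds.
#' @param cache optional environment from [null_cache()]; identical
#'   arguments then return the cached (bit-identical) vector.
#' @return numeric vector of `n_null` null AUC values.
#' @export
null_auc_distribution <- function(n_records, collection_cells, env,
                                  n_null = 1000,
                                  regularization_multiplier = 1,
                                  seed = NULL, cache = NULL) {
  if (n_null < 1) abort("`n_null` must be >= 1")
  if (n_records > length(collection_cells)) {
    abort("`n_records` exceeds the number of collection localities")
  }
  key <- sprintf("m%d_n%d_s%s", n_records, n_null,
                 if (is.null(seed)) "NULL" else seed)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  seeds <- child_seeds(seed, n_null)
  aucs <- vapply(seq_len(n_null), function(r) {
    cells <- with_seed(seeds[[r]],
                       sample(collection_cells, n_records))
    fit <- fit_sdm(cells, env, species_id = sprintf("null_%d", r),
                   regularization_multiplier = regularization_multiplier)
    fit$train_auc
  }, numeric(1))
  if (!is.null(cache)) cache[[key]] <- aucs
  aucs
}

#' Create a null-distribution cache
#'
#' @return an environment used by [null_auc_distribution()] to share null
#'   AUC distributions between species with equal record counts.
#' @export
null_cache <- function() new.env(parent = emptyenv())

#' Test an SDM's AUC against its null distribution
#'
#' A species has a significant non-random distribution when its observed
#' AUC is strictly above the empirical 95th percentile (nearest-rank) of
#' the null AUCs; ties are conservatively non-significant.
#'
#' @param fit an `sdm_fit`.
#' @param null_aucs numeric vector from [null_auc_distribution()].
#' @return a one-row tibble: `species`, `n_records`, `observed_auc`,
#'   `critical_auc`, `p_rank` (= `(1 + #\{null >= observed\}) /
#'   (n_null + 1)`), `significant`.
#' @export
null_auc_test <- function(fit, null_aucs) {
  if (length(null_aucs) == 0) abort("`null_aucs` must be non-empty")
  obs <- fit$train_auc
  crit <- sort(null_aucs)[ceiling(0.95 * length(null_aucs))]
  tibble(
    species = fit$species_id,
    n_records = fit$n_records,
    observed_auc = obs,
    critical_auc = crit,
    p_rank = (1 + sum(null_aucs >= obs)) / (length(null_aucs) + 1),
    significant = obs > crit
  )
}

#' Null-model screen over all species of an occurrence set
#'
#' Fits every species, builds (cached) null AUC distributions keyed on
#' record count from the occurrence set's collection localities, and
#' tests each species.
#'
#' @param occ an `occurrence_set` (already rarity-filtered).
#' @param env pruned predictor tibble.
#' @param n_null null replicates per distinct record count.
#' @param regularization_multiplier passed to [fit_sdm()].
#' @param seed RNG seed (one child seed per distinct record count).
#' @return list with `tests` (tibble, one row per species, as
#'   [null_auc_test()]) and `fits` (named list of `sdm_fit` objects).
#' @export
null_model_screen <- function(occ, env, n_null = 1000,
                              regularization_multiplier = 1, seed = NULL) {
  localities <- collection_localities(occ)
  counts <- species_records(occ)
  cache <- null_cache()
  sizes <- sort(unique(counts$n_records))
  size_seeds <- setNames(child_seeds(seed, length(sizes)), sizes)
  fits <- purrr::map(counts$species, function(sp) {
    fit_sdm(presence_cells(occ, sp), env, species_id = sp,
            regularization_multiplier = regularization_multiplier)
  })
  names(fits) <- counts$species
  tests <- purrr::map(fits, function(fit) {
    nulls <- null_auc_distribution(
      fit$n_records, localities, env, n_null = n_null,
      regularization_multiplier = regularization_multiplier,
      seed = size_seeds[[as.character(fit$n_records)]], cache = cache)
    null_auc_test(fit, nulls)
  })
  list(tests = dplyr::bind_rows(tests), fits = fits)
}
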