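#' Feature class from sample size
#'
#' Maps a species' number of presence cells to the MaxEnt feature class
#' used for its model: 5-10 records use linear features, 11-14 quadratic,
#' and 15 or more hinge features.  Model complexity thereby grows with the
#' information available.
#'
#' @param n_records number of distinct presence cells (>= 5).
#' @return `"linear"`, `"quadratic"` or `"hinge"`.
#' @export
select_features <- function(n_records) {
  if (n_records < 5) {
    abort("species with fewer than 5 records should have been filtered out")
  }
  if (n_records <= 10) "linear" else if (n_records <= 14) "quadratic" else "hinge"
}

# regularization multiplier by feature class and sample size
# (package defaults in the spirit of MaxEnt's tabulated values)
reg_beta <- function(feature_class, m) {
  tbl <- switch(feature_class,
    linear = list(ss = c(10, 30, 100), beta = c(1.0, 0.2, 0.05)),
    quadratic = list(ss = c(10, 17, 30, 100), beta = c(1.3, 0.8, 0.5, 0.05)),
    hinge = list(ss = c(10, 100), beta = c(0.5, 0.5))
  )
  approx(tbl$ss, tbl$beta, xout = m, rule = 2)$y
}

# feature expansion of z-scored predictors; hinge knots at equally spaced
# quantiles of the background values (both opening directions)
build_features <- function(z, feature_class, n_knots = 10) {
  preds <- colnames(z)
  if (feature_class == "linear") return(z)
  if (feature_class == "quadratic") {
    q <- z^2
    colnames(q) <- paste0(preds, "^2")
    return(cbind(z, q))
  }
  probs <- seq(1, n_knots) / (n_knots + 1)
  blocks <- purrr::map(preds, function(p) {
    x <- z[, p]
    ks <- unique(quantile(x, probs, names = FALSE))
    lo <- min(x); hi <- max(x)
    fwd <- vapply(ks, function(k) pmax(0, x - k) / max(hi - k, 1e-12),
                  numeric(length(x)))
    rev <- vapply(ks, function(k) pmax(0, k - x) / max(k - lo, 1e-12),
                  numeric(length(x)))
    colnames(fwd) <- sprintf("hinge(%s>%.3g)", p, ks)
    colnames(rev) <- sprintf("hinge(%s<%.3g)", p, ks)
    cbind(fwd, rev)
  })
  cbind(z, do.call(cbind, blocks))
}

#' Fit a presence-background (MaxEnt-style) species distribution model
#'
#' Estimates a maximum-entropy habitat-suitability surface as an
#' L1-penalized log-linear model contrasting the presence cells against
#' all domain cells (the background), following the established
#' equivalence between MaxEnt and penalized logistic regression with
#' heavily weighted background.  Predictors are standardized over the
#' background and expanded into the feature class implied by the sample
#' size (see [select_features()]); per-feature penalties scale with the
#' feature's spread at the presence sites and a sample-size-dependent
#' default multiplier.  The fitted exponential intensity is transformed to
#' a \[0,1\] suitability with the complementary log-log transform
#' `1 - exp(-exp(H) * raw)`, `raw` being the normalized intensity and `H`
#' its entropy over the background.
#'
#' @param presences integer vector of presence cell ids (>= 5).
#' @param env tibble `cell_id` + (pruned) predictor columns covering the
#'   whole domain.
#' @param species_id label stored on the fit.
#' @param feature_class `NULL` (auto from sample size) or one of
#'   `"linear"`, `"quadratic"`, `"hinge"`.
#' @param regularization_multiplier scales all penalties (default 1).
#' @param background optional integer vector of background cell ids
#'   (default: all domain cells).
#' @param seed RNG seed (only used if a random background subsample is
#'   requested upstream; the fit itself is deterministic).
#' @return an `sdm_fit` object: list with `species_id`, `feature_class`,
#'   `coefficients` (named, non-zero features only), `suitability`
#'   (named per-cell vector in \[0,1\]), `train_auc`, `n_records`,
#'   `presences`.
#' @export
fit_sdm <- function(presences, env, species_id = "species",
                    feature_class = NULL, regularization_multiplier = 1,
                    background = NULL, seed = NULL) {
  presences <- unique(presences)
  m <- length(presences)
  if (m < 5) abort("need at least 5 presence cells")
  if (!all(presences %in% env$cell_id)) abort("presences outside the domain")
  if (is.null(feature_class)) feature_class <- select_features(m)
  if (is.null(background)) background <- env$cell_id
  bg_idx <- match(background, env$cell_id)
  vals <- env_values(env)
  keep <- apply(vals[bg_idx, , drop = FALSE], 2, sd) > 0
  if (!all(keep)) {
    warn(sprintf("dropping zero-variance predictors: %s",
                 paste(colnames(vals)[!keep], collapse = ", ")))
    vals <- vals[, keep, drop = FALSE]
    if (ncol(vals) == 0) abort("no usable predictors")
  }
  mu <- colMeans(vals[bg_idx, , drop = FALSE])
  sds <- apply(vals[bg_idx, , drop = FALSE], 2, sd)
  z <- sweep(sweep(vals, 2, mu), 2, sds, "/")
  feats <- build_features(z, feature_class)
  p_idx <- match(presences, env$cell_id)

  if (ncol(feats) == 1) {
    # glmnet requires >= 2 columns; pad with an inert all-zero feature
    feats <- cbind(feats, `.zero` = 0)
  }
  x <- rbind(feats[p_idx, , drop = FALSE], feats[bg_idx, , drop = FALSE])
  y <- c(rep(1, m), rep(0, length(bg_idx)))
  w <- c(rep(1, m), rep(100, length(bg_idx)))
  sd_pres <- apply(feats[p_idx, , drop = FALSE], 2, sd)
  beta_m <- reg_beta(feature_class, m)
  reg <- beta_m * sd_pres / sqrt(m) * regularization_multiplier
  floor_ <- if (feature_class == "hinge") 0.5 / sqrt(m) else 1e-4
  reg <- pmax(reg, floor_ * regularization_multiplier)
  lambdas <- 10^seq(4, 0, length.out = 100) * mean(reg) * sum(y) / sum(w)
  fit <- withCallingHandlers(
    glmnet::glmnet(x = x, y = y, family = "binomial", weights = w,
                   standardize = FALSE, penalty.factor = reg,
                   lambda = lambdas),
    warning = function(wng) {
      # small presence samples are the norm here; glmnet's class-size
      # caution is expected and uninformative for presence-background fits
      if (grepl("fewer than 8", conditionMessage(wng))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- fit$beta[, ncol(fit$beta)]
  lp <- drop(feats %*% beta)
  lp <- lp - max(lp)
  raw <- exp(lp) / sum(exp(lp))
  entropy <- -sum(raw[raw > 0] * log(raw[raw > 0]))
  suit <- 1 - exp(-exp(entropy) * raw)
  names(suit) <- as.character(env$cell_id)
  out <- structure(list(
    species_id = species_id,
    feature_class = feature_class,
    coefficients = beta[beta != 0],
    suitability = suit,
    n_records = m,
    presences = sort(presences),
    background = background,
    train_auc = NA_real_
  ), class = "sdm_fit")
  out$train_auc <- sdm_auc(suit, presences, background)
  out
}

#' Area under the ROC curve against background
#'
#' Mann-Whitney form of the AUC: the probability that a randomly chosen
#' presence cell outranks a randomly chosen background cell in
#' suitability, with ties counted 1/2.  The background may overlap the
#' presences (pseudo-absence contract); constant suitability gives 0.5.
#'
#' @param suitability named per-cell suitability vector (names = cell ids)
#'   or an `sdm_fit`.
#' @param presences integer vector of presence cell ids.
#' @param background integer vector of background cell ids.
#' @return AUC in \[0, 1\].
#' @export
sdm_auc <- function(suitability, presences, background) {
  if (inherits(suitability, "sdm_fit")) suitability <- suitability$suitability
  if (length(presences) == 0 || length(background) == 0) {
    abort("presences and background must be non-empty")
  }
  sp <- suitability[as.character(presences)]
  sb <- suitability[as.character(background)]
  r <- rank(c(sp, sb))
  np <- length(sp); nb <- length(sb)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf(
    "<sdm_fit> %s: %d records, %s features, %d non-zero coefficients, AUC %.3f\n",
    x$species_id, x$n_records, x$feature_class, length(x$coefficients),
    x$train_auc))
  invisible(x)
}

#' @rdname tidy.sdm_fit
#' @method glance sdm_fit
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble(species = x$species_id, n_records = x$n_records,
         feature_class = x$feature_class, train_auc = x$train_auc,
         n_nonzero = length(x$coefficients))
}

#' Tidy an SDM fit
#'
#' `tidy()` returns the non-zero feature coefficients; `glance()` the
#' one-row model summary.
#'
#' @param x an `sdm_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy sdm_fit
#' @export
tidy.sdm_fit <- function(x, ...) {
  tibble(feature = names(x$coefficients), estimate = unname(x$coefficients))
}
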