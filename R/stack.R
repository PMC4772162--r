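#' Choose a presence/absence threshold for an SDM
#'
#' Converts continuous suitability to presence/absence with one of three
#' standard rules: `"sens_spec_equal"` picks the threshold minimizing
#' |sensitivity - specificity| (specificity measured against the
#' background), `"sum_max"` maximizes sensitivity + specificity, and
#' `"p10"` is the 10th percentile (linear interpolation between order
#' statistics) of the suitability values at the training presences, so
#' roughly 10% of training records fall below it.  When `rule` is `NULL`
#' it is selected by sample size: species with 5-9 records use
#' `sens_spec_equal`, species with >= 10 records use `p10`.
#'
#' @param fit an `sdm_fit`.
#' @param rule `NULL` (auto) or one of `"sens_spec_equal"`, `"sum_max"`,
#'   `"p10"`.
#' @return numeric threshold with attribute `rule`; cells with
#'   suitability >= threshold are scored present.
#' @export
choose_threshold <- function(fit, rule = NULL) {
  if (is.null(rule)) rule <- if (fit$n_records <= 9) "sens_spec_equal" else "p10"
  rule <- match.arg(rule, c("sens_spec_equal", "sum_max", "p10"))
  sp <- fit$suitability[as.character(fit$presences)]
  if (rule == "p10") {
    if (length(sp) < 10) {
      warn("p10 threshold with fewer than 10 presences is a percentile of few points")
    }
    thr <- unname(quantile(sp, 0.10, type = 7))
  } else {
    sb <- fit$suitability[as.character(fit$background)]
    cand <- sort(unique(c(sp, sb)))
    sens <- vapply(cand, function(t) mean(sp >= t), numeric(1))
    spec <- vapply(cand, function(t) mean(sb < t), numeric(1))
    thr <- if (rule == "sens_spec_equal") {
      cand[which.min(abs(sens - spec))]
    } else {
      cand[which.max(sens + spec)]
    }
  }
  structure(thr, rule = rule)
}

#' Stack thresholded SDMs into a presence/absence matrix
#'
#' Applies each species' threshold and assembles the binary cells x
#' species matrix whose row sums are the stacked-SDM species richness.
#'
#' @param fits list of `sdm_fit` objects sharing one grid/background.
#' @param rules `NULL` (auto per species), a single rule name, or a named
#'   character vector by species.
#' @param grid the grid the fits are indexed on (stored on the result).
#' @return a `pa_matrix` object: list with `pa` (binary matrix, rows =
#'   cells, columns = species), `thresholds` (tibble `species`,
#'   `n_records`, `rule`, `threshold`, `n_presence_cells`) and `grid`.
#' @export
stack_sdms <- function(fits, rules = NULL, grid = NULL) {
  cells <- names(fits[[1]]$suitability)
  for (f in fits) {
    if (!identical(names(f$suitability), cells)) {
      abort("all fits must share the same grid cells")
    }
  }
  species <- vapply(fits, function(f) f$species_id, character(1))
  pa <- matrix(0L, length(cells), length(fits),
               dimnames = list(cells, species))
  thr_rows <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    rule <- if (is.null(rules)) NULL else if (length(rules) == 1) rules else
      rules[[f$species_id]]
    thr <- choose_threshold(f, rule)
    pa[, i] <- as.integer(f$suitability >= as.numeric(thr))
    thr_rows[[i]] <- tibble(species = f$species_id, n_records = f$n_records,
                            rule = attr(thr, "rule"),
                            threshold = as.numeric(thr),
                            n_presence_cells = sum(pa[, i]))
  }
  thr_tbl <- dplyr::bind_rows(thr_rows)
  empty <- thr_tbl$species[thr_tbl$n_presence_cells == 0]
  if (length(empty) > 0) {
    inform(sprintf("%d species have zero presence cells after thresholding",
                   length(empty)))
  }
  structure(list(pa = pa, thresholds = thr_tbl, grid = grid),
            class = "pa_matrix")
}

#' Per-cell species richness of a stacked presence/absence matrix
#'
#' @param pa a `pa_matrix` (or plain binary matrix, rows = cells).
#' @return tibble `cell_id`, `richness`.
#' @export
richness <- function(pa) {
  m <- if (inherits(pa, "pa_matrix")) pa$pa else pa
  tibble(cell_id = as.integer(rownames(m)), richness = as.integer(rowSums(m)))
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d cells x %d species, %d presences\n",
              nrow(x$pa), ncol(x$pa), sum(x$pa)))
  invisible(x)
}

#' Tidy a presence/absence matrix
#'
#' @param x a `pa_matrix`.
#' @param ... unused.
#' @return long tibble `cell_id`, `species` (one row per presence).
#' @method tidy pa_matrix
#' @export
tidy.pa_matrix <- function(x, ...) {
  nz <- which(x$pa == 1L, arr.ind = TRUE)
  tibble(cell_id = as.integer(rownames(x$pa)[nz[, 1]]),
         species = colnames(x$pa)[nz[, 2]]) |>
    dplyr::arrange(.data$cell_id, .data$species)
}

#' @rdname tidy.pa_matrix
#' @method glance pa_matrix
#' @export
glance.pa_matrix <- function(x, ...) {
  r <- rowSums(x$pa)
  tibble(n_cells = nrow(x$pa), n_species = ncol(x$pa),
         n_presences = sum(x$pa), mean_richness = mean(r),
         max_richness = max(r))
}
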