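# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one seed (kept below 2^31)
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' items; 1 for identical partitions, ~0 for independent ones.  Used to
#' score recovery of the true regions by the bioregionalization.
#'
#' @param a,b vectors of cluster labels (any type), equal length.
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# standardize matrix columns to mean 0, sd 1; constant columns -> 0
zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu), 2, s, "/")
}

# env tibble (cell_id + predictors) -> plain numeric matrix
env_values <- function(env) {
  stopifnot("cell_id" %in% names(env))
  m <- as.matrix(env[setdiff(names(env), "cell_id")])
  rownames(m) <- as.character(env$cell_id)
  m
}
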