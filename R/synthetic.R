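#' Generate smooth synthetic environmental predictor surfaces
#'
#' Builds a rectangular grid and a set of spatially autocorrelated
#' predictor fields emulating climate- and soil-like layers: each field is
#' Gaussian-smoothed white noise (correlation length `smoothness`, in
#' cells), the first predictor additionally carries a monotone latitudinal
#' gradient ("temperature-like") and the second a monotone longitudinal
#' gradient ("precipitation-like").  Optionally appends predictors highly
#' rank-correlated with existing ones to exercise collinearity pruning.
#'
#' @param n_lon,n_lat lattice dimensions (each >= 4).
#' @param n_predictors number of base predictors (>= 2).
#' @param smoothness Gaussian correlation length in cells (> 0).
#' @param n_correlated number of extra near-duplicate predictors to append.
#' @param rho target correlation of each near-duplicate with its parent.
#' @param resolution cell size in arc-minutes.
#' @param lon0,lat0 lower-left corner, decimal degrees.
#' @param seed RNG seed (the same seed reproduces the world exactly).
#' @return list with `grid` (a [make_grid()] domain) and `env` (tibble
#'   `cell_id` + one standardized column per predictor).
#' @export
make_environment <- function(n_lon, n_lat, n_predictors = 8, smoothness = 5,
                             n_correlated = 0, rho = 0.9,
                             resolution = 10, lon0 = 100, lat0 = 20,
                             seed = NULL) {
  if (n_lon < 4 || n_lat < 4) abort("grid must be at least 4 x 4")
  if (n_predictors < 2) abort("need at least 2 predictors")
  if (smoothness <= 0) abort("`smoothness` must be positive")
  grid <- make_grid(n_lon, n_lat, resolution = resolution,
                    lon0 = lon0, lat0 = lat0)
  with_seed(seed, {
    fields <- purrr::map(seq_len(n_predictors), function(i) {
      f <- gaussian_field(n_lat, n_lon, smoothness)
      f <- (f - mean(f)) / sd(f)
      if (i == 1) {  # temperature-like: warm south, cold north
        grad <- -(row(f) - (n_lat + 1) / 2) / (n_lat / 2)
        f <- 1.5 * grad + 0.75 * f
      } else if (i == 2) {  # precipitation-like: wet east, dry west
        grad <- (col(f) - (n_lon + 1) / 2) / (n_lon / 2)
        f <- 1.5 * grad + 0.75 * f
      }
      f
    })
    nm <- c("temp_mean", "precip",
            if (n_predictors > 2) paste0("env", seq(3, n_predictors)))
    if (n_correlated > 0) {
      parents <- rep_len(seq_len(n_predictors), n_correlated)
      for (k in seq_len(n_correlated)) {
        p <- fields[[parents[k]]]
        p <- (p - mean(p)) / sd(p)
        noise <- gaussian_field(n_lat, n_lon, smoothness)
        noise <- (noise - mean(noise)) / sd(noise)
        fields[[n_predictors + k]] <- rho * p + sqrt(1 - rho^2) * noise
        nm <- c(nm, paste0(nm[parents[k]], "_dup", k))
      }
    }
    vals <- vapply(fields, function(f) f[cbind(grid$row, grid$col)],
                   numeric(nrow(grid)))
    vals <- zscore_cols(vals)
    colnames(vals) <- nm
    env <- dplyr::bind_cols(tibble(cell_id = grid$cell_id), as_tibble(vals))
    list(grid = grid, env = env)
  })
}

# Gaussian-smoothed white noise on an n_lat x n_lon lattice.
# Smoothing by row/column kernel matrices with edge renormalization.
gaussian_field <- function(n_lat, n_lon, sigma) {
  smoother <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  noise <- matrix(rnorm(n_lat * n_lon), n_lat, n_lon)
  smoother(n_lat) %*% noise %*% t(smoother(n_lon))
}

#' Generate virtual species with Gaussian niches
#'
#' Each species responds to 1-3 randomly chosen predictors with a Gaussian
#' (bell-shaped) suitability centered on the environment of a randomly
#' chosen cell, rescaled to a maximum of 1.  Niche breadth is tuned per
#' species (bounded bisection) so that realized prevalence — the fraction
#' of cells with suitability > 0.5 — falls inside `prevalence_range`.
#'
#' @param env predictor tibble from [make_environment()] (or any
#'   `cell_id` + predictors tibble).
#' @param n_species number of species to generate.
#' @param niche_breadth initial niche standard deviation in predictor
#'   z-score units.
#' @param prevalence_range length-2 numeric, admissible prevalence interval.
#' @param n_niche_dims candidate numbers of active niche axes (sampled per
#'   species).
#' @param seed RNG seed.
#' @return an `n_species x n_cells` suitability matrix in \[0, 1\] with
#'   species in rows (named `sp001`, ...), plus a `niche` attribute
#'   describing each species' active predictors.
#' @export
make_species <- function(env, n_species, niche_breadth = 1,
                         prevalence_range = c(0.05, 0.3),
                         n_niche_dims = 1:3, seed = NULL) {
  if (n_species < 1) abort("`n_species` must be >= 1")
  z <- zscore_cols(env_values(env))
  n_cells <- nrow(z)
  with_seed(seed, {
    suit <- matrix(0, n_species, n_cells,
                   dimnames = list(sprintf("sp%03d", seq_len(n_species)),
                                   rownames(z)))
    niche <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      d <- if (length(n_niche_dims) == 1) n_niche_dims else sample(n_niche_dims, 1)
      preds <- sample(ncol(z), min(d, ncol(z)))
      mu <- z[sample(n_cells, 1), preds]
      sq <- rowSums(sweep(z[, preds, drop = FALSE], 2, mu)^2)
      prev_at <- function(b) {
        s <- exp(-sq / (2 * b^2))
        s <- s / max(s)
        mean(s > 0.5)
      }
      b <- tune_breadth(prev_at, niche_breadth, prevalence_range)
      s <- exp(-sq / (2 * b^2))
      suit[i, ] <- s / max(s)
      niche[[i]] <- list(predictors = colnames(z)[preds], center = mu,
                         breadth = b)
    }
    attr(suit, "niche") <- niche
    suit
  })
}

# bisection on log-breadth; prevalence > 0.5 threshold is monotone in b
tune_breadth <- function(prev_at, b0, range, max_iter = 60) {
  p <- prev_at(b0)
  if (p >= range[1] && p <= range[2]) return(b0)
  lo <- 1e-3; hi <- 1e3
  target <- mean(range)
  for (k in seq_len(max_iter)) {
    b <- sqrt(lo * hi)
    p <- prev_at(b)
    if (p >= range[1] && p <= range[2]) return(b)
    if (p < target) lo <- b else hi <- b
  }
  abort(sprintf("prevalence range (%g, %g) unattainable for this niche",
                range[1], range[2]))
}

#' Partition a grid into contiguous blocks
#'
#' Voronoi cells of a seeded k-means on the cell coordinates; used as the
#' ground-truth region layout of synthetic worlds.
#'
#' @param grid a [make_grid()] domain.
#' @param k number of blocks (>= 2).
#' @param seed RNG seed.
#' @return integer label vector ordered by `cell_id`.
#' @export
partition_domain <- function(grid, k, seed = NULL) {
  if (k < 2) abort("`k` must be >= 2")
  if (k > nrow(grid)) abort("`k` exceeds the number of cells")
  with_seed(seed, {
    stats::kmeans(cbind(grid$col, grid$row), centers = k, nstart = 5,
                  iter.max = 50)$cluster
  })
}

#' Shift predictor baselines by region
#'
#' Adds a region-specific offset (drawn from N(0, `contrast`^2) per region
#' and predictor) to every predictor and re-standardizes, emulating the
#' environmental distinctness of real biogeographical regions (regions
#' differ in climate and soil baselines, not only in species pools).
#'
#' @param env tibble `cell_id` + predictors.
#' @param labels region label per cell (ordered by `cell_id`).
#' @param contrast offset standard deviation in predictor SD units.
#' @param seed RNG seed.
#' @return the shifted, re-standardized `env` tibble.
#' @export
region_shifted_env <- function(env, labels, contrast = 1, seed = NULL) {
  if (contrast == 0) return(env)
  vals <- env_values(env)
  with_seed(seed, {
    offsets <- matrix(rnorm(length(unique(labels)) * ncol(vals),
                            sd = contrast),
                      nrow = length(unique(labels)))
    lev <- sort(unique(labels))
    vals <- vals + offsets[match(labels, lev), ]
    vals <- zscore_cols(vals)
    dplyr::bind_cols(tibble(cell_id = env$cell_id), as_tibble(vals))
  })
}

#' Partition the domain into true regions with region-structured pools
#'
#' Splits the grid into `k_true` contiguous blocks (Voronoi cells of
#' k-means on the cell coordinates) and assigns each species to one
#' block's pool (plus an optional globally shared pool).  Suitabilities
#' are masked to the species' block with soft exponential edges: outside
#' its block a species' suitability decays as
#' `exp(-turnover_sharpness * d)` with `d` the distance (in cells) to the
#' block.  `pool_overlap` controls compositional overlap between blocks:
#' with disjoint pools the between-block beta-sim turnover is 1, with
#' fully shared pools it is 0.
#'
#' @param grid a [make_grid()] domain.
#' @param suitability species x cells matrix from [make_species()].
#' @param k_true number of regions (>= 2, <= n_cells).
#' @param turnover_sharpness edge decay rate per cell; large values give
#'   hard region boundaries.
#' @param pool_overlap fraction of species shared across all regions.
#' @param labels optional precomputed partition from [partition_domain()]
#'   (drawn internally when `NULL`).
#' @param seed RNG seed.
#' @return list with `regions` (tibble `cell_id`, `region`),
#'   `suitability` (masked matrix) and `pools` (tibble `species`, `pool`;
#'   pool 0 = shared).
#' @export
make_regions <- function(grid, suitability, k_true, turnover_sharpness = 2,
                         pool_overlap = 0, labels = NULL, seed = NULL) {
  if (k_true < 2) abort("`k_true` must be >= 2")
  if (k_true > nrow(grid)) abort("`k_true` exceeds the number of cells")
  n_sp <- nrow(suitability)
  with_seed(seed, {
    xy <- cbind(grid$col, grid$row)
    if (is.null(labels)) {
      labels <- stats::kmeans(xy, centers = k_true, nstart = 5,
                              iter.max = 50)$cluster
    }
    n_shared <- round(pool_overlap * n_sp)
    pool <- c(rep(0L, n_shared),
              rep_len(seq_len(k_true), n_sp - n_shared))
    pool <- sample(pool)  # shuffle species-pool assignment
    # distance (in cells) from every cell to the nearest cell of each region
    dist_to_region <- vapply(seq_len(k_true), function(k) {
      member <- xy[labels == k, , drop = FALSE]
      apply(xy, 1, function(p) {
        sqrt(min((member[, 1] - p[1])^2 + (member[, 2] - p[2])^2))
      })
    }, numeric(nrow(grid)))
    masked <- suitability
    for (i in seq_len(n_sp)) {
      if (pool[i] == 0L) next
      w <- exp(-turnover_sharpness * dist_to_region[, pool[i]])
      masked[i, ] <- suitability[i, ] * w
    }
    list(regions = tibble(cell_id = grid$cell_id, region = labels),
         suitability = masked,
         pools = tibble(species = rownames(suitability), pool = pool))
  })
}

#' Build an accessibility-bias sampling layer
#'
#' Collection effort in herbarium data concentrates near roads and other
#' accessible sites.  The layer is built from a few random straight "road"
#' corridors across the domain; sampling weight decays with squared
#' distance to the nearest corridor, plus a small background floor, and is
#' normalized to sum to one.
#'
#' @param grid a [make_grid()] domain.
#' @param n_roads number of corridors.
#' @param width corridor half-width in cells.
#' @param floor background weight far from any corridor.
#' @param seed RNG seed.
#' @return numeric vector of sampling weights (sums to 1), ordered by
#'   `cell_id`.
#' @export
make_bias_weights <- function(grid, n_roads = 3, width = 2, floor = 0.05,
                              seed = NULL) {
  with_seed(seed, {
    xy <- cbind(grid$col, grid$row)
    d_min <- rep(Inf, nrow(grid))
    for (r in seq_len(n_roads)) {
      p0 <- c(runif(1, min(xy[, 1]), max(xy[, 1])),
              runif(1, min(xy[, 2]), max(xy[, 2])))
      theta <- runif(1, 0, pi)
      u <- c(cos(theta), sin(theta))
      # distance from each cell center to the infinite line through p0
      rel <- sweep(xy, 2, p0)
      d <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
      d_min <- pmin(d_min, d)
    }
    w <- floor + exp(-(d_min / width)^2)
    w / sum(w)
  })
}

#' Assemble a complete synthetic world
#'
#' Bundles [make_environment()], [make_species()], optionally
#' [make_regions()], and [make_bias_weights()] into one reproducible
#' object carrying the full ground truth for every downstream stage.
#'
#' @param n_lon,n_lat lattice dimensions (defaults give a 40 x 30,
#'   1200-cell desk-scale domain).
#' @param n_predictors,smoothness,n_correlated,rho passed to
#'   [make_environment()].
#' @param n_species,niche_breadth,prevalence_range passed to
#'   [make_species()].
#' @param k_regions if not `NULL`, partition into this many true regions.
#' @param turnover_sharpness,pool_overlap passed to [make_regions()].
#' @param region_env_contrast region-specific predictor baseline shift
#'   (SD units, see [region_shifted_env()]); only used with `k_regions`.
#' @param seed master RNG seed; all component seeds derive from it.
#' @return a `synthetic_world` list: `grid`, `env`, `suitability`
#'   (species x cells, in \[0,1\]), `true_regions` (tibble or `NULL`),
#'   `pools`, `bias_weights`, `seed`.
#' @export
simulate_world <- function(n_lon = 40, n_lat = 30, n_predictors = 8,
                           smoothness = 5, n_correlated = 0, rho = 0.9,
                           n_species = 200, niche_breadth = 1,
                           prevalence_range = c(0.05, 0.3),
                           k_regions = NULL, turnover_sharpness = 2,
                           pool_overlap = 0, region_env_contrast = 1,
                           seed = 1) {
  seeds <- child_seeds(seed, 6)
  ge <- make_environment(n_lon, n_lat, n_predictors, smoothness,
                         n_correlated = n_correlated, rho = rho,
                         seed = seeds[[1]])
  env <- ge$env
  regions <- NULL; pools <- NULL; labels <- NULL
  if (!is.null(k_regions)) {
    labels <- partition_domain(ge$grid, k_regions, seed = seeds[[2]])
    env <- region_shifted_env(env, labels, contrast = region_env_contrast,
                              seed = seeds[[3]])
  }
  suit <- make_species(env, n_species, niche_breadth, prevalence_range,
                       seed = seeds[[4]])
  if (!is.null(k_regions)) {
    reg <- make_regions(ge$grid, suit, k_regions, turnover_sharpness,
                        pool_overlap, labels = labels, seed = seeds[[5]])
    suit <- reg$suitability
    regions <- reg$regions
    pools <- reg$pools
  }
  bias <- make_bias_weights(ge$grid, seed = seeds[[6]])
  structure(list(grid = ge$grid, env = env, suitability = suit,
                 true_regions = regions, pools = pools,
                 bias_weights = bias, seed = seed),
            class = "synthetic_world")
}

#' Simulate biased collecting from a synthetic world
#'
#' Draws `effort` independent collecting events.  Each event picks a cell
#' with probability proportional to `bias_weights ^ bias_strength`
#' (`bias_strength = 0` gives spatially uniform collecting), picks a
#' candidate species uniformly, and records a presence with probability
#' equal to the species' true suitability in that cell (detection equals
#' suitability; no false presences).  Duplicate species records within a
#' cell collapse to one presence.
#'
#' @param world a [simulate_world()] object.
#' @param effort number of collecting events.
#' @param bias_strength exponent on the accessibility layer (>= 0).
#' @param seed RNG seed.
#' @return an `occurrence_set` (no rarity filter applied; see
#'   [occurrences_from_records()]), with attribute `localities` = sorted
#'   cell ids holding at least one record.
#' @export
collect_records <- function(world, effort, bias_strength = 0, seed = NULL) {
  if (effort <= 0) abort("`effort` must be positive")
  with_seed(seed, {
    w <- world$bias_weights ^ bias_strength
    w <- w / sum(w)
    cells <- sample(world$grid$cell_id, effort, replace = TRUE, prob = w)
    sp <- sample(rownames(world$suitability), effort, replace = TRUE)
    p_keep <- world$suitability[cbind(sp, as.character(cells))]
    keep <- runif(effort) < p_keep
    if (!any(keep)) abort("no records retained; increase `effort`")
    occ <- occurrences_from_records(
      tibble(species = sp[keep], cell_id = cells[keep]),
      world$grid, min_cells = 1)
    attr(occ, "localities") <- sort(unique(cells[keep]))
    occ
  })
}

#' Write a synthetic world to plain-text artifacts
#'
#' Emits the environmental layers as ASCII-grid rasters, the true
#' suitability and region/bias truth tables as CSV, and a YAML manifest
#' recording the seed.
#'
#' @param world a [simulate_world()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- env_values(world$env)
  for (nm in colnames(ev)) {
    grid_to_ascii(world$grid, ev[, nm], file.path(dir, paste0(nm, ".asc")))
  }
  write_matrix(world$suitability, file.path(dir, "true_suitability.csv"))
  write.csv(tibble(cell_id = world$grid$cell_id,
                   bias_weight = world$bias_weights),
            file.path(dir, "bias_weights.csv"), row.names = FALSE)
  if (!is.null(world$true_regions)) {
    write.csv(world$true_regions, file.path(dir, "true_regions.csv"),
              row.names = FALSE)
  }
  yaml::write_yaml(list(seed = world$seed,
                        n_cells = nrow(world$grid),
                        n_species = nrow(world$suitability)),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}
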