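test_that("generated environments are smooth, gradient-bearing and reproducible", {
  ge <- make_environment(20, 16, n_predictors = 4, smoothness = 5, seed = 7)
  expect_equal(nrow(ge$env), 320)

  # lag-1 spatial autocorrelation of every field is high at smoothness 5
  for (p in setdiff(names(ge$env), "cell_id")) {
    v <- matrix(ge$env[[p]], 16, 20)[cbind(ge$grid$row, ge$grid$col)]
    m <- matrix(NA_real_, 16, 20)
    m[cbind(ge$grid$row, ge$grid$col)] <- ge$env[[p]]
    lag1 <- cor(as.vector(m[, -1]), as.vector(m[, -20]))
    expect_gt(lag1, 0.5)
  }

  # monotone latitudinal / longitudinal gradients in the first two fields
  expect_lt(cor(ge$env$temp_mean, ge$grid$lat), -0.5)
  expect_gt(cor(ge$env$precip, ge$grid$lon), 0.5)

  # determinism
  ge2 <- make_environment(20, 16, n_predictors = 4, smoothness = 5, seed = 7)
  expect_identical(ge$env, ge2$env)

  expect_error(make_environment(20, 16, smoothness = 0), "smoothness")
})

test_that("requested near-duplicate predictors exceed the pruning threshold", {
  ge <- make_environment(20, 16, n_predictors = 4, smoothness = 5,
                         n_correlated = 2, rho = 0.9, seed = 3)
  expect_equal(ncol(ge$env) - 1, 6)
  r1 <- cor(ge$env$temp_mean, ge$env$temp_mean_dup1, method = "spearman")
  expect_gte(abs(r1), 0.75)
})

test_that("virtual species have in-range prevalence and niche-shaped suitability", {
  ge <- desk_env()
  suit <- make_species(ge$env, 12, prevalence_range = c(0.05, 0.2),
                       n_niche_dims = 1, seed = 5)
  expect_true(all(suit >= 0 & suit <= 1))
  prev <- apply(suit, 1, function(s) mean(s > 0.5))
  expect_true(all(prev >= 0.05 & prev <= 0.2))

  # suitability is maximal at the cells closest to the niche center
  niche <- attr(suit, "niche")[[1]]
  z <- scale(ge$env[[niche$predictors]])
  best <- which.max(suit[1, ])
  expect_lt(abs(z[best] - niche$center),
            quantile(abs(z - niche$center), 0.05))

  # very broad niche approaches constant suitability
  wide <- make_species(ge$env, 1, niche_breadth = 1e6,
                       prevalence_range = c(0, 1), n_niche_dims = 1, seed = 5)
  expect_lt(diff(range(wide)), 0.01)
})

test_that("biased and unbiased collecting behave as the bias test expects", {
  world <- small_world()

  # unbiased collecting with large effort: almost all predictors unbiased
  set.seed(10)
  flagged <- replicate(20, {
    occ <- collect_records(world, effort = 20000, bias_strength = 0)
    b <- bias_test(world$env, collection_localities(occ))
    mean(b$biased, na.rm = TRUE)
  })
  expect_lte(mean(flagged), 0.05)

  # bias concentrated in ~10% of cells: most predictors flagged biased
  wb <- world
  hot <- order(world$grid$col + world$grid$row)[1:30]  # one corner, 10% of cells
  wb$bias_weights <- ifelse(seq_len(nrow(world$grid)) %in% hot, 1, 1e-6)
  wb$bias_weights <- wb$bias_weights / sum(wb$bias_weights)
  occ <- collect_records(wb, effort = 5000, bias_strength = 1, seed = 2)
  b <- bias_test(world$env, collection_localities(occ))
  expect_gte(mean(b$biased, na.rm = TRUE), 0.8)

  # conservation: no species can have more presences than retained records
  occ_small <- collect_records(world, effort = 50, seed = 3)
  expect_lte(max(species_records(occ_small)$n_records), nrow(occ_small))

  # determinism
  o1 <- collect_records(world, effort = 500, bias_strength = 1, seed = 9)
  o2 <- collect_records(world, effort = 500, bias_strength = 1, seed = 9)
  expect_equal(tibble::as_tibble(o1), tibble::as_tibble(o2))
})

test_that("region pools hit the beta-sim endpoints and worlds are deterministic", {
  ge <- make_environment(16, 12, n_predictors = 4, seed = 8)
  suit <- make_species(ge$env, 20, seed = 9)

  reg <- make_regions(ge$grid, suit, k_true = 2, turnover_sharpness = 50,
                      pool_overlap = 0, seed = 10)
  pools <- split(reg$pools$species, reg$pools$pool)
  # disjoint pools: between-block beta-sim is 1
  expect_equal(beta_sim(pools[["1"]], pools[["2"]]), 1)
  # identical pools: beta-sim 0
  expect_equal(beta_sim(pools[["1"]], pools[["1"]]), 0)

  w1 <- simulate_world(n_lon = 12, n_lat = 10, n_species = 15,
                       k_regions = 3, seed = 4)
  w2 <- simulate_world(n_lon = 12, n_lat = 10, n_species = 15,
                       k_regions = 3, seed = 4)
  expect_identical(w1$suitability, w2$suitability)
  expect_identical(w1$env, w2$env)
  expect_equal(sum(w1$bias_weights), 1)
  expect_error(make_regions(ge$grid, suit, k_true = 1000), "exceeds")
})

test_that("world artifacts round-trip to plain text", {
  world <- simulate_world(n_lon = 8, n_lat = 6, n_species = 5,
                          k_regions = 2, seed = 12)
  dir <- withr::local_tempdir()
  write_world(world, dir)
  expect_true(file.exists(file.path(dir, "temp_mean.asc")))
  suit <- read_matrix(file.path(dir, "true_suitability.csv"))
  expect_equal(unname(suit), unname(world$suitability), tolerance = 1e-12,
               ignore_attr = TRUE)
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  expect_equal(man$seed, 12)
})
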