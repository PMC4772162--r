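test_that("the trend surface has nine centered cubic terms with the right parity", {
  g <- make_grid(12, 9, resolution = 10)
  ts <- trend_surface_terms(g)
  expect_equal(setdiff(names(ts), "cell_id"),
               c("LON", "LAT", "LON2", "LONxLAT", "LAT2",
                 "LON3", "LON2xLAT", "LONxLAT2", "LAT3"))
  expect_equal(mean(ts$LON), 0, tolerance = 1e-12)
  expect_equal(mean(ts$LAT), 0, tolerance = 1e-12)

  # reflecting longitude negates exactly the odd-in-LON columns
  g2 <- g
  g2$lon <- -g2$lon
  ts2 <- trend_surface_terms(g2)
  for (odd in c("LON", "LONxLAT", "LON3", "LONxLAT2")) {
    expect_equal(ts2[[odd]], -ts[[odd]], tolerance = 1e-12)
  }
  for (even in c("LAT", "LON2", "LAT2", "LON2xLAT", "LAT3")) {
    expect_equal(ts2[[even]], ts[[even]], tolerance = 1e-12)
  }

  g1 <- make_grid(1, 5)
  expect_error(trend_surface_terms(g1), "distinct")
})

test_that("variation partitioning satisfies the algebraic identity and recovers drivers", {
  ge <- desk_env()
  ts <- trend_surface_terms(ge$grid)
  set.seed(81)

  # identity: the four fractions sum to one, by construction, on any data
  y_any <- rnorm(nrow(ge$env))
  p <- variation_partition(y_any, ge$env, ts)
  expect_equal(p$pure_env + p$pure_space + p$shared + p$unexplained, 1,
               tolerance = 1e-8)
  expect_equal(p$pure_env + p$pure_space + p$shared, p$adj_r2_combined,
               tolerance = 1e-8)

  # richness driven by one smooth predictor: environment dominates
  y_env <- 3 * ge$env$env3 + rnorm(nrow(ge$env), sd = 0.5)
  pe <- variation_partition(y_env, ge$env, ts)
  expect_gt(pe$pure_env, pe$pure_space)
  expect_gt((pe$pure_env + pe$shared) / pe$adj_r2_combined, 0.8)

  # richness a pure function of latitude: space captures it fully, and the
  # environmental share is absorbed as shared variance (env has a
  # latitudinal temperature gradient), leaving almost no pure environment
  y_lat <- scale(ge$grid$lat) + rnorm(nrow(ge$env), sd = 0.05)
  pl <- variation_partition(as.numeric(y_lat), ge$env, ts)
  expect_lt(pl$pure_env, 0.05)
  expect_gt(pl$adj_r2_space, 0.95)
})

test_that("regression fits match the normal-equations oracle", {
  set.seed(82)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5) + rnorm(n)
  env <- tibble::tibble(cell_id = 0:(n - 1), a = X[, 1], b = X[, 2],
                        c = X[, 3])
  ts <- tibble::tibble(cell_id = 0:(n - 1), s1 = rnorm(n))
  p <- variation_partition(as.numeric(y), env, ts)
  # oracle: adjusted R^2 from explicit normal equations
  oracle_adj_r2 <- function(y, X) {
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    res <- y - Xi %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    1 - (1 - r2) * (length(y) - 1) / (length(y) - ncol(X) - 1)
  }
  expect_equal(p$adj_r2_env, oracle_adj_r2(y, X), tolerance = 1e-8)
})

test_that("forward stepwise selection recovers a planted signal", {
  ge <- desk_env()
  set.seed(83)
  y <- 2 * scale(ge$env$precip) + rnorm(nrow(ge$env), sd = 0.4)
  m <- stepwise_regression(as.numeric(y), ge$env)
  expect_equal(m$steps$term[1], "precip")
  expect_gt(m$coefficients$beta[m$coefficients$term == "precip"], 0.5)
  # cumulative adjusted R^2 is non-decreasing over entry steps
  expect_true(all(diff(m$steps$adj_r2_cum) >= -1e-10))
  # betas are invariant to affine rescaling of the raw predictors
  env_scaled <- dplyr::mutate(ge$env, precip = 100 * .data$precip + 3)
  m2 <- stepwise_regression(as.numeric(y), env_scaled)
  expect_equal(m2$coefficients$beta, m$coefficients$beta, tolerance = 1e-10)
})

test_that("noise enters spuriously at about the entry alpha", {
  set.seed(84)
  n <- 150
  entered <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    env <- tibble::tibble(cell_id = 0:(n - 1), u = rnorm(n), v = rnorm(n))
    m <- suppressWarnings(stepwise_regression(rnorm(n), env))
    entered <- entered + nrow(m$steps)
  }
  rate <- entered / (n_rep * 2)   # per-candidate entry rate
  expect_lt(abs(rate - 0.05), 0.04)
})

test_that("a duplicated predictor is never entered twice", {
  set.seed(85)
  n <- 200
  x <- rnorm(n)
  env <- tibble::tibble(cell_id = 0:(n - 1), x1 = x, x2 = x)
  y <- 2 * x + rnorm(n, sd = 0.3)
  m <- stepwise_regression(y, env)
  expect_equal(nrow(m$steps), 1)
})

test_that("Moran's I matches the brute-force formula and behaves on patterns", {
  g <- make_grid(4, 4)
  w <- rook_weights(g)

  # perfect checkerboard under rook weights: strong negative autocorrelation
  chk <- (-1)^(g$row + g$col)
  mi <- morans_i(chk, g)
  expect_lt(mi$i, 0)
  expect_equal(mi$i, naive_morans_i(chk, w), tolerance = 1e-8)
  expect_equal(mi$expected, -1 / (nrow(g) - 1))

  # smooth gradient: positive and significant
  gg <- make_grid(10, 8)
  grad <- gg$lon + gg$lat
  mg <- morans_i(grad, gg)
  expect_gt(mg$i, 0.5)
  expect_lt(mg$p_value, 1e-6)
  expect_equal(mg$i, naive_morans_i(grad, rook_weights(gg)), tolerance = 1e-8)

  # i.i.d. noise: near the -1/(n-1) expectation on average
  set.seed(86)
  ii <- replicate(30, morans_i(rnorm(nrow(gg)), gg)$i)
  expect_lt(abs(mean(ii) - (-1 / (nrow(gg) - 1))), 3 * sd(ii) / sqrt(30))

  expect_error(morans_i(rep(1, nrow(g)), g), "constant")
})
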