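# expensive fixtures built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 1200-cell desk world without regions, 8 predictors
desk_env <- function() {
  fixture("desk_env", function() {
    make_environment(40, 30, n_predictors = 8, smoothness = 5, seed = 11)
  })
}

# small world with species and bias layer
small_world <- function() {
  fixture("small_world", function() {
    simulate_world(n_lon = 20, n_lat = 15, n_species = 60, seed = 42)
  })
}

# naive average-linkage agglomeration: independent UPGMA oracle
naive_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  avg_dist <- function(a, b) mean(d[a, b])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        dd <- avg_dist(clusters[[i]], clusters[[j]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    active[best[2]] <- FALSE
  }
  coph
}

# direct-formula Moran's I oracle
naive_morans_i <- function(x, w) {
  n <- length(x)
  xc <- x - mean(x)
  s0 <- sum(w)
  (n / s0) * sum(w * outer(xc, xc)) / sum(xc^2)
}

# direct-formula Gi* oracle
naive_gi_star <- function(x, region) {
  n <- length(x); nr <- length(region)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  (sum(x[region]) - nr * xbar) / (s * sqrt((n * nr - nr^2) / (n - 1)))
}
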