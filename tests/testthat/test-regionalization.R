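test_that("beta-sim hits its endpoints and closed-form values", {
  expect_equal(beta_sim(letters[1:5], letters[1:5]), 0)
  expect_equal(beta_sim(letters[1:3], letters[4:7]), 1)
  # a = 2 shared, b = 1, c = 3 unique: min(1,3) / (1 + 2)
  expect_equal(beta_sim(c("s1", "s2", "s3"), c("s1", "s2", "s4", "s5", "s6")),
               1 / 3)
  expect_error(beta_sim(character(), character()), "empty")
})

test_that("beta-sim agrees with a set-operation oracle on random pairs", {
  set.seed(91)
  pool <- paste0("sp", 1:40)
  for (r in 1:1000) {
    si <- sample(pool, sample(1:20, 1))
    sj <- sample(pool, sample(1:20, 1))
    a <- length(intersect(si, sj))
    b <- length(setdiff(si, sj))
    cc <- length(setdiff(sj, si))
    oracle <- if (min(b, cc) + a == 0) NaN else min(b, cc) / (min(b, cc) + a)
    expect_identical(beta_sim(si, sj), oracle)
  }
})

test_that("the dissimilarity matrix is symmetric, zero-diagonal, and matches vegan", {
  set.seed(92)
  m <- matrix(rbinom(20 * 15, 1, 0.4), 20, 15,
              dimnames = list(0:19, paste0("sp", 1:15)))
  m["1", ] <- m["2", ]             # two identical assemblages
  m["3", ] <- 0                    # one empty cell
  expect_message(d <- dissimilarity_matrix(m), "1 empty cells")
  dm <- unclass(d)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, nrow(dm)))
  expect_equal(dm["1", "2"], 0)
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(attr(d, "excluded_cells"), "3")

  # independent route: vegan's beta-sim on the same assemblages
  veg <- as.matrix(vegan::betadiver(m[rowSums(m) > 0, ], "sim"))
  expect_equal(unname(dm), unname(veg), tolerance = 1e-12,
               ignore_attr = TRUE)

  # per-pair component counts
  comp <- beta_sim_components(m, 0, 4)
  expect_equal(comp$a + comp$b, sum(m["0", ]))
  expect_equal(comp$a + comp$c, sum(m["4", ]))
})

test_that("genus aggregation can only lower turnover when genera are shared", {
  # 3 cells, 4 congeneric species in 2 genera: cells share genera but not
  # all species
  pa <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 1, 0, 0))
  dimnames(pa) <- list(0:2, c("A_x", "A_y", "B_x", "B_y"))
  gmap <- tibble::tibble(species = colnames(pa),
                         genus = c("A", "A", "B", "B"))
  ds <- dissimilarity_matrix(pa)
  dg <- dissimilarity_matrix(pa, level = "genus", genus_map = gmap)
  expect_true(all(unclass(dg) <= unclass(ds) + 1e-12))
  # cells 0 and 1 share no species but both genera
  expect_equal(unclass(ds)["0", "1"], 1)
  expect_equal(unclass(dg)["0", "1"], 0)
  expect_error(dissimilarity_matrix(pa, level = "genus"), "genus_map")
})

test_that("UPGMA reproduces hand-computed and ultrametric structures", {
  # 3 items: first merge (A,B) at 0.1, then C at 0.5
  d <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.5,
                0.5, 0.5, 0), 3, 3, dimnames = list(LETTERS[1:3],
                                                    LETTERS[1:3]))
  hc <- upgma(d)
  expect_equal(sort(hc$height), c(0.1, 0.5))
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))

  # an ultrametric input is reproduced exactly
  set.seed(93)
  base <- hclust(dist(matrix(rnorm(30), 15, 2)), method = "average")
  ultra <- stats::cophenetic(base)
  hc2 <- upgma(as.matrix(ultra))
  expect_equal(as.matrix(stats::cophenetic(hc2)), as.matrix(ultra),
               tolerance = 1e-10)

  expect_error(upgma(matrix(0, 1, 1)), "at least two")
})

test_that("UPGMA matches the naive agglomeration oracle", {
  set.seed(94)
  for (r in 1:5) {
    n <- sample(8:20, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    dimnames(d) <- list(seq_len(n), seq_len(n))
    hc <- upgma(d)
    coph <- as.matrix(stats::cophenetic(hc))
    ord <- as.character(seq_len(n))
    expect_equal(unname(coph[ord, ord]), naive_upgma_cophenetic(d),
                 tolerance = 1e-8)
  }
})

test_that("dendrograms are invariant to input order and export to Newick", {
  set.seed(95)
  d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  dimnames(d) <- list(paste0("c", 1:12), paste0("c", 1:12))
  hc1 <- upgma(d)
  perm <- sample(12)
  hc2 <- upgma(d[perm, perm])
  expect_equal(as.matrix(stats::cophenetic(hc1))[rownames(d), rownames(d)],
               as.matrix(stats::cophenetic(hc2))[rownames(d), rownames(d)],
               tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc1, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(d))
})

test_that("indicator values take their closed-form values on archetypes", {
  # 12 cells in 3 equal clusters
  labels <- rep(1:3, each = 4)
  perfect <- as.integer(labels == 2)        # all of cluster 2, nothing else
  everywhere <- rep(1L, 12)
  rare <- c(1L, rep(0L, 11))
  pa <- cbind(perfect = perfect, everywhere = everywhere, rare = rare)
  rownames(pa) <- 0:11
  iv <- indval(pa, labels, n_perm = 99, seed = 96)
  expect_equal(iv$indval[iv$species == "perfect"], 100)
  expect_equal(iv$cluster[iv$species == "perfect"], 2)
  expect_equal(iv$indval[iv$species == "everywhere"], 100 / 3)
  expect_lt(iv$p_value[iv$species == "perfect"], 0.05)

  # relabeling clusters leaves the species-level maxima unchanged
  relab <- c(3L, 1L, 2L)[labels]
  iv2 <- indval(pa, relab, n_perm = 99, seed = 96)
  expect_equal(iv2$indval, iv$indval)

  expect_error(indval(pa, rep(1, 12)), "two clusters")
})

test_that("the summed-p curve is complete, deterministic, and minimized at k", {
  set.seed(97)
  world <- simulate_world(n_lon = 16, n_lat = 12, n_species = 60,
                          k_regions = 3, turnover_sharpness = 4, seed = 98)
  pa_true <- t(world$suitability > 0.5) + 0L
  rownames(pa_true) <- world$grid$cell_id
  r1 <- suppressMessages(optimal_k(pa_true, k_range = 2:6,
                                   subsample_size = 120, n_repeats = 2,
                                   n_perm = 49, seed = 99))
  r2 <- suppressMessages(optimal_k(pa_true, k_range = 2:6,
                                   subsample_size = 120, n_repeats = 2,
                                   n_perm = 49, seed = 99))
  expect_equal(r1$mean_curve, r2$mean_curve)
  expect_equal(r1$k, r2$k)
  expect_setequal(r1$mean_curve$k, 2:6)
  expect_equal(nrow(r1$curve), 2 * 5)
  # labels partition all retained cells into exactly k non-empty groups
  expect_equal(dplyr::n_distinct(r1$labels$region), r1$k)
  # dendrogram heights are non-decreasing (UPGMA ultrametricity)
  expect_true(all(diff(r1$dendrogram$height) >= -1e-12))
  expect_error(optimal_k(pa_true, k_range = 2:200, subsample_size = 100),
               "subsample")
})
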