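test_that("grid cells are contiguous, unique, and half-open in assignment", {
  mask <- matrix(TRUE, 6, 8); mask[1, 1] <- FALSE
  g <- make_grid(8, 6, resolution = 10, mask = mask)
  expect_identical(g$cell_id, seq_len(nrow(g)) - 1L)
  expect_equal(nrow(g), 47)

  # a point on a shared edge belongs to exactly one cell
  step <- 10 / 60
  edge_lon <- step  # boundary between col 1 and col 2
  id <- cells_from_points(g, edge_lon, step * 0.5)
  expect_length(id, 1)
  expect_false(is.na(id))
  expect_equal(g$col[g$cell_id == id], 2L)  # half-open: belongs to the right cell

  # all in-domain points are assigned; masked cell gives NA
  expect_true(is.na(cells_from_points(g, step * 0.5, step * 0.5)))
  ids <- cells_from_points(g, g$lon, g$lat)
  expect_identical(ids, g$cell_id)
})

test_that("occurrence loading snaps, deduplicates, and filters rare species", {
  g <- make_grid(10, 10, resolution = 60)  # 1-degree cells at origin
  recs <- tibble::tibble(
    species = c(rep("rare4", 7),            # 7 records in 4 distinct cells
                rep("dup", 2),              # 2 records, same cell
                rep("a", 5), rep("b", 5), rep("c", 6)),
    lon = c(0.1, 0.2, 1.1, 2.1, 3.1, 3.2, 3.3,
            5.5, 5.6,
            0:4 + 0.5, 0:4 + 0.5, 0:5 + 0.5),
    lat = c(rep(0.5, 7), 5.5, 5.5, rep(1.5, 5), rep(2.5, 5), rep(3.5, 6)))
  occ <- occurrences_from_records(recs, g, min_cells = 5)
  counts <- species_records(occ)
  expect_setequal(counts$species, c("a", "b", "c"))   # rare4 dropped at min_cells = 5
  expect_equal(sort(counts$n_records), c(5, 5, 6))
  expect_true("rare4" %in% attr(occ, "dropped")$species)
  expect_true("dup" %in% attr(occ, "dropped")$species)
  expect_equal(attr(occ, "dropped")$n_cells[
    attr(occ, "dropped")$species == "dup"], 1L)        # deduplicated to one cell

  # loading the dump of an occurrence set reproduces it (idempotence)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, g, path)
  occ2 <- load_occurrences(path, g, min_cells = 5)
  expect_equal(tibble::as_tibble(occ2), tibble::as_tibble(occ),
               ignore_attr = TRUE)
})

test_that("occurrence loading reports skipped rows and errors on empty result", {
  g <- make_grid(4, 4, resolution = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat", "sp1,0.5,0.5", "sp1,not_a_number,1",
               "sp1,99,99"), path)
  expect_message(expect_message(
    expect_error(load_occurrences(path, g, min_cells = 5), "no species"),
    "unparseable"), "outside")
})

test_that("raster resampling aggregates continuous and preserves categorical", {
  g <- make_grid(4, 3, resolution = 10)
  step <- 10 / 60
  # constant raster at grid resolution -> constant column
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(matrix(7, 3, 4), path, 0, 0, step)
  out <- load_env_rasters(c(const = path), g)
  expect_equal(out$env$const, rep(7, 12))
  expect_equal(out$n_excluded, 0)

  # 5 arc-min raster onto the 10 arc-min grid: mean of the 4 sub-cells
  fine <- matrix(seq_len(6 * 8), 6, 8, byrow = TRUE)
  pathf <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(fine, pathf, 0, 0, step / 2)
  outf <- load_env_rasters(c(v = pathf), g)$env$v
  south_up <- fine[6:1, ]  # oracle: brute-force block means, south-up order
  oracle <- numeric(0)
  for (r in 1:3) for (cc in 1:4) {
    oracle <- c(oracle,
                mean(south_up[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc)]))
  }
  expect_equal(outf, oracle)

  # categorical: nearest-neighbour keeps the exact class values
  classes <- matrix(sample(c(1, 3, 9), 6 * 8, replace = TRUE), 6, 8)
  pathc <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(classes, pathc, 0, 0, step / 2)
  outc <- load_env_rasters(c(drain = pathc), g, methods = "nearest")$env$drain
  expect_true(all(outc %in% c(1, 3, 9)))
})

test_that("ASCII grid and per-cell raster round trips are exact", {
  g <- make_grid(5, 4, resolution = 10)
  vals <- rnorm(nrow(g))
  path <- withr::local_tempfile(fileext = ".asc")
  grid_to_ascii(g, vals, path)
  r <- read_ascii_grid(path)
  back <- load_env_rasters(c(v = path), g)$env$v
  expect_equal(back, vals, tolerance = 1e-6)
})

test_that("matrix IO round-trips densely and sparsely and the codecs agree", {
  m <- matrix(rbinom(30, 1, 0.4), 6, 5,
              dimnames = list(paste0("c", 1:6), paste0("s", 1:5)))
  pd <- withr::local_tempfile(fileext = ".csv")
  ps <- withr::local_tempfile(fileext = ".txt")
  write_matrix(m, pd, "dense")
  write_matrix(m, ps, "sparse")
  expect_equal(read_matrix(pd), m + 0)
  expect_equal(read_matrix(ps), m + 0)

  # all-zero matrix: header-only sparse file reads back as zeros
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  pz <- withr::local_tempfile(fileext = ".txt")
  write_matrix(z, pz, "sparse")
  expect_equal(read_matrix(pz), z)

  # 3x3 numeric round trip
  a <- matrix(rnorm(9), 3, 3, dimnames = list(1:3, c("x", "y", "z")))
  pa <- withr::local_tempfile(fileext = ".csv")
  write_matrix(a, pa)
  expect_equal(read_matrix(pa), a)
})

test_that("grid coarsening maps every fine cell to one coarse block", {
  g <- make_grid(7, 5, resolution = 10)
  co <- coarsen_grid(g, 2)
  expect_equal(nrow(co$mapping), nrow(g))
  expect_true(all(co$mapping$coarse_cell_id %in% co$grid$cell_id))
  expect_equal(attr(co$grid, "resolution"), 20)
  # factor 1 is the identity
  expect_identical(coarsen_grid(g, 1)$grid, g)
})
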