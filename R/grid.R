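#' Build a rectangular analysis grid
#'
#' Defines the cell lattice on which every stage of the pipeline is indexed:
#' occurrence snapping, environmental matrices, richness maps, dissimilarity
#' and regionalization.  Cells are half-open intervals
#' `[lon0, lon0 + step) x [lat0, lat0 + step)` (step = `resolution / 60`
#' decimal degrees, WGS84) with the origin at the lower-left corner of the
#' domain, so every point maps to exactly one cell.  Cells excluded by the
#' mask (e.g. sea) are dropped; the remaining "inside" cells receive
#' contiguous ids `0 .. n_cells - 1`.
#'
#' @param n_lon,n_lat number of columns (west-east) and rows (south-north)
#'   of the lattice.
#' @param resolution cell size in arc-minutes (default 10).
#' @param lon0,lat0 longitude/latitude of the domain's lower-left corner in
#'   decimal degrees.
#' @param mask optional logical matrix with `n_lat` rows and `n_lon` columns
#'   (row 1 = southernmost), `TRUE` for cells inside the study domain.
#'   `NULL` keeps every cell.
#'
#' @return A tibble of class `grid_domain` with one row per inside cell:
#'   `cell_id` (0-based integer), `lon`, `lat` (cell centers), and the
#'   lattice indices `row` (1 = south) and `col` (1 = west).  Lattice
#'   geometry is stored in attributes `resolution`, `lon0`, `lat0`,
#'   `n_lon`, `n_lat`.
#' @export
#' @examples
#' g <- make_grid(8, 6, resolution = 10)
#' nrow(g)  # 48 cells
make_grid <- function(n_lon, n_lat, resolution = 10, lon0 = 0, lat0 = 0,
                      mask = NULL) {
  if (n_lon < 1 || n_lat < 1) abort("grid must have at least one cell")
  if (resolution <= 0) abort("`resolution` must be positive (arc-minutes)")
  if (!is.null(mask)) {
    if (!is.matrix(mask) || nrow(mask) != n_lat || ncol(mask) != n_lon) {
      abort("`mask` must be a logical n_lat x n_lon matrix")
    }
    if (!any(mask)) abort("mask excludes every cell")
  }
  step <- resolution / 60
  cells <- tidyr::expand_grid(row = seq_len(n_lat), col = seq_len(n_lon))
  if (!is.null(mask)) {
    keep <- mask[cbind(cells$row, cells$col)]
    cells <- cells[keep, , drop = FALSE]
  }
  g <- tibble(
    cell_id = seq_len(nrow(cells)) - 1L,
    lon = lon0 + (cells$col - 0.5) * step,
    lat = lat0 + (cells$row - 0.5) * step,
    row = cells$row,
    col = cells$col
  )
  structure(g,
    class = c("grid_domain", class(tibble())),
    resolution = resolution, lon0 = lon0, lat0 = lat0,
    n_lon = as.integer(n_lon), n_lat = as.integer(n_lat)
  )
}

grid_meta <- function(grid) {
  m <- attributes(grid)[c("resolution", "lon0", "lat0", "n_lon", "n_lat")]
  if (any(vapply(m, is.null, logical(1)))) {
    abort("not a grid_domain (lattice attributes missing); build with make_grid()")
  }
  m$step <- m$resolution / 60
  m
}

# lattice (row, col) -> cell_id matrix; NA for masked cells
grid_lookup <- function(grid) {
  m <- grid_meta(grid)
  lk <- matrix(NA_integer_, nrow = m$n_lat, ncol = m$n_lon)
  lk[cbind(grid$row, grid$col)] <- grid$cell_id
  lk
}

#' Map points to grid cells
#'
#' Assigns longitude/latitude points to cells using the half-open cell
#' convention, so a point on a shared edge belongs to exactly one cell.
#'
#' @param grid a [make_grid()] domain.
#' @param lon,lat numeric vectors of equal length, decimal degrees.
#' @return integer vector of cell ids; `NA` for points outside the lattice
#'   or in masked cells.
#' @export
cells_from_points <- function(grid, lon, lat) {
  m <- grid_meta(grid)
  col <- floor((lon - m$lon0) / m$step) + 1
  row <- floor((lat - m$lat0) / m$step) + 1
  ok <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= m$n_lon & row >= 1 & row <= m$n_lat
  out <- rep(NA_integer_, length(lon))
  lk <- grid_lookup(grid)
  out[ok] <- lk[cbind(row[ok], col[ok])]
  out
}

#' Row-standardized rook-contiguity spatial weights
#'
#' Builds the neighbour weight matrix used for Moran's I: cells sharing an
#' edge on the lattice are neighbours (rook scheme); rows are standardized
#' to sum to one (cells without neighbours keep a zero row).
#'
#' @param grid a [make_grid()] domain.
#' @param row_standardize divide each row by its neighbour count?
#' @return an `n_cells x n_cells` numeric matrix ordered by `cell_id`.
#' @export
rook_weights <- function(grid, row_standardize = TRUE) {
  n <- nrow(grid)
  lk <- grid_lookup(grid)
  m <- grid_meta(grid)
  w <- matrix(0, n, n)
  shift <- function(dr, dc) {
    r2 <- grid$row + dr
    c2 <- grid$col + dc
    ok <- r2 >= 1 & r2 <= m$n_lat & c2 >= 1 & c2 <= m$n_lon
    nb <- rep(NA_integer_, n)
    nb[ok] <- lk[cbind(r2[ok], c2[ok])]
    has <- !is.na(nb)
    w[cbind(grid$cell_id[has] + 1L, nb[has] + 1L)] <<- 1
    invisible(NULL)
  }
  shift(1, 0); shift(-1, 0); shift(0, 1); shift(0, -1)
  if (row_standardize) {
    rs <- rowSums(w)
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  }
  w
}

#' Coarsen a grid by an integer factor
#'
#' Aggregates `factor x factor` blocks of fine cells into coarse cells
#' (e.g. 10 arc-minute cells into 20 arc-minute cells with `factor = 2`).
#' A coarse cell is inside the domain if it contains at least one inside
#' fine cell.
#'
#' @param grid a [make_grid()] domain.
#' @param factor positive integer block size.
#' @return a list with `grid` (the coarse `grid_domain`) and `mapping`, a
#'   tibble `fine_cell_id`, `coarse_cell_id`.
#' @export
coarsen_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  if (factor < 1) abort("`factor` must be >= 1")
  m <- grid_meta(grid)
  if (factor == 1L) {
    return(list(grid = grid,
                mapping = tibble(fine_cell_id = grid$cell_id,
                                 coarse_cell_id = grid$cell_id)))
  }
  crow <- (grid$row - 1L) %/% factor + 1L
  ccol <- (grid$col - 1L) %/% factor + 1L
  n_lon_c <- ceiling(m$n_lon / factor)
  n_lat_c <- ceiling(m$n_lat / factor)
  mask <- matrix(FALSE, n_lat_c, n_lon_c)
  mask[cbind(crow, ccol)] <- TRUE
  cg <- make_grid(n_lon_c, n_lat_c, resolution = m$resolution * factor,
                  lon0 = m$lon0, lat0 = m$lat0, mask = mask)
  lk <- grid_lookup(cg)
  list(grid = cg,
       mapping = tibble(fine_cell_id = grid$cell_id,
                        coarse_cell_id = lk[cbind(crow, ccol)]))
}

#' @export
print.grid_domain <- function(x, ...) {
  m <- grid_meta(x)
  cat(sprintf("<grid_domain> %d x %d lattice at %g arc-min, %d inside cells\n",
              m$n_lon, m$n_lat, m$resolution, nrow(x)))
  NextMethod()
}
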