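#' Read an ESRI ASCII grid
#'
#' @param path path to an `.asc` file.
#' @return list with `values` (numeric matrix, row 1 = northernmost row),
#'   `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata`
#'   (nodata cells are returned as `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) abort(sprintf("ASCII grid header missing %s", k))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(sprintf("ASCII grid %s: expected %d values, found %d",
                  path, hdr$ncols * hdr$nrows, length(vals)))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr[["nodata_value"]] %||% NA_real_
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  list(values = m, ncols = hdr$ncols, nrows = hdr$nrows,
       xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` written as
#'   the nodata value.
#' @param path output path.
#' @param xllcorner,yllcorner,cellsize grid geometry in decimal degrees.
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, xllcorner, yllcorner, cellsize,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10g", xllcorner),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  v <- values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, function(r) paste(format(r, trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}

#' Write per-cell values as an ASCII grid raster
#'
#' @param grid a [make_grid()] domain.
#' @param values numeric vector ordered by `cell_id`.
#' @param path output path.
#' @param nodata nodata sentinel for masked cells.
#' @return `path`, invisibly.
#' @export
grid_to_ascii <- function(grid, values, path, nodata = -9999) {
  m <- grid_meta(grid)
  v <- matrix(NA_real_, m$n_lat, m$n_lon)
  v[cbind(grid$row, grid$col)] <- values
  # ASCII grids are north-up; our rows count from the south
  write_ascii_grid(v[m$n_lat:1, , drop = FALSE], path,
                   xllcorner = m$lon0, yllcorner = m$lat0,
                   cellsize = m$step, nodata = nodata)
}

#' Load environmental raster layers onto a grid
#'
#' Resamples each layer to the analysis grid: continuous layers by mean
#' aggregation of the raster cell centers falling inside each grid cell,
#' categorical layers by nearest-neighbour sampling at the grid cell
#' center (values preserved exactly, never averaged).  Grid cells left
#' without a value by some layer are excluded from the domain (the grid is
#' rebuilt with those cells masked) with an informative count.
#'
#' @param paths character vector of ASCII-grid paths; names become
#'   predictor names (file basenames by default).
#' @param grid a [make_grid()] domain.
#' @param methods `"mean"` or `"nearest"`, recycled or named per layer.
#' @return list with `env` (tibble `cell_id` + one column per layer),
#'   `grid` (possibly reduced domain) and `n_excluded`.
#' @export
load_env_rasters <- function(paths, grid, methods = "mean") {
  nm <- names(paths)
  if (is.null(nm)) nm <- sub("\\.[^.]*$", "", basename(paths))
  methods <- rep_len(methods, length(paths))
  cols <- purrr::map2(paths, methods, function(p, method) {
    r <- read_ascii_grid(p)
    resample_to_grid(r, grid, method, layer = p)
  })
  names(cols) <- nm
  env <- dplyr::bind_cols(tibble(cell_id = grid$cell_id), cols)
  miss <- !complete.cases(env)
  n_excluded <- sum(miss)
  if (n_excluded > 0) {
    inform(sprintf(
      "%d cells with missing environmental values excluded from the domain",
      n_excluded))
    m <- grid_meta(grid)
    mask <- matrix(FALSE, m$n_lat, m$n_lon)
    keep <- !miss
    mask[cbind(grid$row[keep], grid$col[keep])] <- TRUE
    grid <- make_grid(m$n_lon, m$n_lat, resolution = m$resolution,
                      lon0 = m$lon0, lat0 = m$lat0, mask = mask)
    env <- env[keep, , drop = FALSE]
    env$cell_id <- grid$cell_id
  }
  list(env = env, grid = grid, n_excluded = n_excluded)
}

resample_to_grid <- function(r, grid, method = c("mean", "nearest"), layer = "") {
  method <- match.arg(method)
  m <- grid_meta(grid)
  if (method == "nearest") {
    # sample the raster at grid-cell centers
    jj <- floor((grid$lon - r$xllcorner) / r$cellsize) + 1
    ii_s <- floor((grid$lat - r$yllcorner) / r$cellsize) + 1  # from south
    inside <- jj >= 1 & jj <= r$ncols & ii_s >= 1 & ii_s <= r$nrows
    if (!all(inside)) {
      abort(sprintf("raster %s does not cover the domain", layer))
    }
    out <- r$values[cbind(r$nrows - ii_s + 1, jj)]
  } else {
    # centers of raster cells, assigned to grid cells
    xs <- r$xllcorner + (seq_len(r$ncols) - 0.5) * r$cellsize
    ys <- r$yllcorner + (seq_len(r$nrows) - 0.5) * r$cellsize
    pts <- expand.grid(j = seq_len(r$ncols), i_s = seq_len(r$nrows))
    val <- r$values[cbind(r$nrows - pts$i_s + 1, pts$j)]
    cid <- cells_from_points(grid, xs[pts$j], ys[pts$i_s])
    keep <- !is.na(cid) & !is.na(val)
    sums <- tapply(val[keep], cid[keep], mean)
    out <- rep(NA_real_, nrow(grid))
    out[as.integer(names(sums)) + 1L] <- as.numeric(sums)
    if (all(is.na(out))) abort(sprintf("raster %s is all missing over the domain", layer))
    if (anyNA(out)) {
      # cells with no raster center inside: fall back to nearest sampling
      fill <- is.na(out)
      jj <- pmin(pmax(floor((grid$lon - r$xllcorner) / r$cellsize) + 1, 1), r$ncols)
      ii_s <- pmin(pmax(floor((grid$lat - r$yllcorner) / r$cellsize) + 1, 1), r$nrows)
      covered <- grid$lon >= r$xllcorner &
        grid$lon <= r$xllcorner + r$ncols * r$cellsize &
        grid$lat >= r$yllcorner &
        grid$lat <= r$yllcorner + r$nrows * r$cellsize
      if (!all(covered)) abort(sprintf("raster %s does not cover the domain", layer))
      out[fill] <- r$values[cbind(r$nrows - ii_s + 1, jj)][fill]
    }
  }
  out
}
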