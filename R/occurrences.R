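#' Load occurrence records onto a grid
#'
#' Reads a delimited file with columns `species`, `lon`, `lat` (extra
#' columns ignored), snaps coordinates to grid cells, deduplicates species
#' records within cells (a species is either present or absent in a cell),
#' and drops species occupying fewer than `min_cells` distinct cells — the
#' standard rarity filter for presence-only modeling.
#'
#' @param path path to a CSV file with header `species,lon,lat`.
#' @param grid a [make_grid()] domain.
#' @param min_cells minimum number of distinct presence cells a species
#'   needs to be retained (default 5).
#' @return An `occurrence_set`: a tibble with columns `species`, `cell_id`
#'   (one row per species-cell presence) and attributes `dropped` (tibble
#'   of removed species with their cell counts), `n_unparseable` and
#'   `n_outside` (skipped record counts).
#' @export
load_occurrences <- function(path, grid, min_cells = 5) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(raw))) {
    abort("occurrence file must have columns species, lon, lat")
  }
  raw <- as_tibble(raw[need])
  raw$lon <- suppressWarnings(as.numeric(raw$lon))
  raw$lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(raw$lon) | is.na(raw$lat) | is.na(raw$species) |
    !nzchar(raw$species)
  n_unparseable <- sum(bad)
  if (n_unparseable > 0) {
    inform(sprintf("skipped %d unparseable occurrence rows", n_unparseable))
  }
  raw <- raw[!bad, , drop = FALSE]
  occurrences_from_records(raw, grid, min_cells = min_cells,
                           n_unparseable = n_unparseable)
}

#' Build an occurrence set from in-memory records
#'
#' Same contract as [load_occurrences()] but starting from a data frame of
#' records (columns `species`, `lon`, `lat`), or from already-snapped
#' records (columns `species`, `cell_id`).
#'
#' @param records a data frame of records.
#' @param grid a [make_grid()] domain.
#' @param min_cells minimum distinct presence cells per retained species.
#' @param n_unparseable internal: count of rows dropped before snapping.
#' @return an `occurrence_set` (see [load_occurrences()]).
#' @export
occurrences_from_records <- function(records, grid, min_cells = 5,
                                     n_unparseable = 0L) {
  if (min_cells < 1) abort("`min_cells` must be >= 1")
  records <- as_tibble(records)
  if (!"cell_id" %in% names(records)) {
    records$cell_id <- cells_from_points(grid, records$lon, records$lat)
  }
  n_outside <- sum(is.na(records$cell_id))
  if (n_outside > 0) {
    inform(sprintf("skipped %d records outside the domain", n_outside))
  }
  occ <- records |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::distinct(.data$species, .data$cell_id) |>
    dplyr::arrange(.data$species, .data$cell_id)
  counts <- dplyr::count(occ, .data$species, name = "n_cells")
  dropped <- dplyr::filter(counts, .data$n_cells < min_cells)
  occ <- dplyr::semi_join(occ,
                          dplyr::filter(counts, .data$n_cells >= min_cells),
                          by = "species")
  if (nrow(occ) == 0) {
    abort(sprintf("no species retained at min_cells = %d", min_cells))
  }
  new_occurrence_set(occ, dropped = dropped,
                     n_unparseable = as.integer(n_unparseable),
                     n_outside = as.integer(n_outside))
}

new_occurrence_set <- function(occ, dropped = tibble(species = character(),
                                                     n_cells = integer()),
                               n_unparseable = 0L, n_outside = 0L) {
  structure(occ,
    class = c("occurrence_set", class(tibble())),
    dropped = dropped, n_unparseable = n_unparseable, n_outside = n_outside)
}

#' Per-species record counts
#'
#' @param occ an `occurrence_set`.
#' @return tibble `species`, `n_records` (distinct presence cells).
#' @export
species_records <- function(occ) {
  dplyr::count(as_tibble(occ), .data$species, name = "n_records")
}

#' Presence cells of one species
#' @param occ an `occurrence_set`.
#' @param species species id.
#' @return integer vector of cell ids.
#' @export
presence_cells <- function(occ, species) {
  sort(occ$cell_id[occ$species == species])
}

#' Distinct collection localities
#'
#' The set of cells holding at least one record of any species — the
#' "collection localities" against which environmental bias is diagnosed
#' and from which null-model subsamples are drawn.
#'
#' @param occ an `occurrence_set`.
#' @return sorted integer vector of cell ids.
#' @export
collection_localities <- function(occ) sort(unique(occ$cell_id))

#' Write occurrences back to CSV
#'
#' Dumps one row per species-cell presence with the cell-center
#' coordinates, so that reloading the file reproduces the same
#' `occurrence_set` (loading is idempotent).
#'
#' @param occ an `occurrence_set`.
#' @param grid the grid the occurrences are indexed on.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, grid, path) {
  d <- dplyr::left_join(as_tibble(occ),
                        as_tibble(grid)[c("cell_id", "lon", "lat")],
                        by = "cell_id")
  write.csv(d[c("species", "lon", "lat")], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.occurrence_set <- function(x, ...) {
  nd <- nrow(attr(x, "dropped"))
  cat(sprintf("<occurrence_set> %d species, %d presences (%d species dropped)\n",
              dplyr::n_distinct(x$species), nrow(x), nd))
  NextMethod()
}
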