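#' Write a named matrix to text
#'
#' Dense matrices go to CSV with a leading `row` column of row names.
#' `format = "sparse"` writes a coordinate-format triplet file (one line
#' per non-zero entry) with the dimnames stored in comment headers — the
#' natural codec for large presence/absence matrices.  Both codecs
#' round-trip exactly through [read_matrix()].
#'
#' @param m a matrix with row and column names.
#' @param path output path.
#' @param format `"dense"` (CSV) or `"sparse"` (triplet text).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)) - 1L)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (format == "dense") {
    d <- data.frame(row = rownames(m), m, check.names = FALSE)
    write.csv(d, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#sparse",
                 paste0("#rows\t", paste(rownames(m), collapse = "\t")),
                 paste0("#cols\t", paste(colnames(m), collapse = "\t")),
                 "row\tcol\tvalue"), con)
    nz <- which(m != 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      writeLines(sprintf("%d\t%d\t%.15g", nz[, 1], nz[, 2],
                         m[nz]), con)
    }
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path path to a dense CSV or sparse triplet file (auto-detected).
#' @return a named numeric matrix.
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1)
  if (identical(first, "#sparse")) {
    lines <- readLines(path)
    rn <- strsplit(lines[2], "\t")[[1]][-1]
    cn <- strsplit(lines[3], "\t")[[1]][-1]
    m <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
    if (length(lines) > 4) {
      trip <- read.delim(text = lines[4:length(lines)], sep = "\t")
      m[cbind(trip$row, trip$col)] <- trip$value
    }
    m
  } else {
    d <- read.csv(path, check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    m
  }
}
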