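#' Aligned stack of gridded environmental layers
#'
#' A `layer_stack` bundles the continuous and categorical rasters used by
#' every stage of the pipeline, together with a validity mask (cells that are
#' part of the study region) and a sampling mask (cells with observer effort,
#' used for presence-bias correction).  Rasters are plain numeric matrices in
#' row-major map orientation; coordinates are projected kilometres, with the
#' centre of cell `(r, c)` at `((c - 0.5) * cell_km, (r - 0.5) * cell_km)`.
#'
#' @param continuous named list of numeric matrices (e.g. `rainfall` mm/yr,
#'   `altitude` m, `dem` m, `agb` Mg/ha, `footprint` dimensionless index
#'   >= 0).
#' @param categorical named list of integer-class matrices (e.g.
#'   `vegetation`, `biogeo`, `geology`), with a `classes` attribute or the
#'   observed set of finite values as the declared classes.
#' @param valid logical matrix; `TRUE` where the cell belongs to the study
#'   region.
#' @param sampling logical matrix; `TRUE` where observers were active.  Must
#'   be a subset of `valid`.  Defaults to `valid`.
#' @param cell_km cell edge length in kilometres (default 0.5, the sighting
#'   grid unit).
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(continuous, categorical = list(), valid = NULL,
                        sampling = NULL, cell_km = 0.5) {
  stopifnot(is.list(continuous), length(continuous) >= 1)
  dims <- dim(continuous[[1]])
  all_layers <- c(continuous, categorical)
  for (nm in names(all_layers)) {
    if (!identical(dim(all_layers[[nm]]), dims))
      stop("layer '", nm, "' does not share the stack dimensions")
  }
  if (is.null(valid)) valid <- matrix(TRUE, dims[1], dims[2])
  if (is.null(sampling)) sampling <- valid
  stopifnot(identical(dim(valid), dims), identical(dim(sampling), dims))
  if (any(sampling & !valid))
    stop("sampling mask must be a subset of the validity mask")
  if (!is.null(continuous$footprint) &&
      any(continuous$footprint[valid] < 0, na.rm = TRUE))
    stop("footprint must be >= 0 on valid cells")
  for (nm in names(categorical)) {
    cl <- attr(categorical[[nm]], "classes") %||%
      sort(unique(categorical[[nm]][valid & is.finite(categorical[[nm]])]))
    bad <- categorical[[nm]][valid]
    if (any(!bad %in% cl & is.finite(bad)))
      stop("categorical layer '", nm, "' takes values outside declared classes")
    attr(categorical[[nm]], "classes") <- cl
  }
  structure(list(continuous = continuous, categorical = categorical,
                 valid = valid, sampling = sampling,
                 dims = dims, cell_km = cell_km),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("layer_stack:", x$dims[1], "x", x$dims[2], "cells of",
      x$cell_km, "km\n")
  cat("  continuous :", paste(names(x$continuous), collapse = ", "), "\n")
  cat("  categorical:", paste(names(x$categorical), collapse = ", "), "\n")
  cat("  valid cells:", sum(x$valid), " sampling cells:", sum(x$sampling), "\n")
  invisible(x)
}

#' Linear cell index helpers
#'
#' Cells are indexed 1..rows*cols in column-major (R matrix) order; these
#' helpers convert between linear indices, (row, col) pairs and projected-km
#' centre coordinates.
#'
#' @param stack a [layer_stack()].
#' @param cells integer vector of linear cell indices.
#' @return `cell_coords()` returns a data.frame with `cell`, `row`, `col`,
#'   `x_km`, `y_km`.
#' @export
cell_coords <- function(stack, cells) {
  r <- ((cells - 1L) %% stack$dims[1]) + 1L
  c <- ((cells - 1L) %/% stack$dims[1]) + 1L
  data.frame(cell = cells, row = r, col = c,
             x_km = (c - 0.5) * stack$cell_km,
             y_km = (r - 0.5) * stack$cell_km)
}

#' @rdname cell_coords
#' @export
valid_cells <- function(stack) which(stack$valid)

#' @rdname cell_coords
#' @export
sampling_cells <- function(stack) which(stack$sampling)

#' Read and write single-layer rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' whitespace-separated values, top row first.  Coordinates here are
#' projected kilometres.
#'
#' @param mat numeric matrix (row 1 = southernmost row internally; written
#'   north-up as the format requires).
#' @param path file path.
#' @param cell_km cell size in km.
#' @param nodata value standing in for `NA`.
#' @return `read_asc()` returns a list with `mat` and `cell_km`.
#' @export
write_asc <- function(mat, path, cell_km = 0.5, nodata = -9999) {
  m <- mat
  m[!is.finite(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           "xllcorner 0", "yllcorner 0",
           paste("cellsize", cell_km), paste("NODATA_value", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # ASCII grids store the top (northern) row first
  for (r in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[r, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   vapply(hdr, `[`, "", 1))
  body <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-up
  m[m == vals[["nodata_value"]]] <- NA
  list(mat = m, cell_km = vals[["cellsize"]])
}

#' Write every layer of a stack as ASCII grids in a directory
#'
#' @param stack a [layer_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (nm in names(stack$continuous))
    out <- c(out, write_asc(stack$continuous[[nm]],
                            file.path(dir, paste0(nm, ".asc")), stack$cell_km))
  for (nm in names(stack$categorical))
    out <- c(out, write_asc(stack$categorical[[nm]],
                            file.path(dir, paste0(nm, ".asc")), stack$cell_km))
  out <- c(out, write_asc(stack$valid * 1, file.path(dir, "valid.asc"),
                          stack$cell_km))
  out <- c(out, write_asc(stack$sampling * 1, file.path(dir, "sampling.asc"),
                          stack$cell_km))
  invisible(out)
}
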