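#' Single-band raster on a regular projected grid
#'
#' The raster container used throughout the pipeline: a numeric matrix whose
#' rows run north to south (row 1 is the top of the grid), with square cells
#' of side `res` metres, top-left corner at (`xmin`, `ymax`) and cells
#' half-open (a cell covers `[x, x+res) x (y-res, y]`). `NA` is the nodata
#' value.
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin,ymax coordinates of the grid's top-left corner (metres).
#' @param res cell size in metres (square cells).
#' @param crs a projected [bc_crs()].
#' @param name optional layer name.
#' @return a `baci_raster` object.
#' @export
bc_raster <- function(values, xmin, ymax, res, crs, name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  xmin <- unname(as.numeric(xmin)); ymax <- unname(as.numeric(ymax))
  res <- unname(as.numeric(res))
  stopifnot(res > 0, inherits(crs, "baci_crs"))
  if (!is_projected(crs)) stop("raster CRS must be projected (metre units)")
  structure(list(values = values, xmin = xmin, ymax = ymax, res = res,
                 crs = crs, name = name),
            class = "baci_raster")
}

#' @export
print.baci_raster <- function(x, ...) {
  cat("<baci_raster> '", x$name, "': ", nrow(x$values), " x ", ncol(x$values),
      " cells @ ", x$res, " m, origin (", format(x$xmin), ", ",
      format(x$ymax), "), EPSG:", x$crs$epsg, "\n", sep = "")
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat("values: [", format(min(v)), ", ", format(max(v)), "], ",
                     sum(is.na(x$values)), " NA\n", sep = "")
  invisible(x)
}

#' @export
dim.baci_raster <- function(x) dim(x$values)

raster_template <- function(r, values = NA_real_, name = r$name) {
  bc_raster(matrix(values, nrow(r$values), ncol(r$values)),
            r$xmin, r$ymax, r$res, r$crs, name)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$res - b$res) < tol && crs_equal(a$crs, b$crs)
}

#' Cell-centre coordinates of every cell, row-major from the top-left
#'
#' @param r a `baci_raster`.
#' @return a matrix with columns `x`, `y`; row `k` is cell `k` in row-major
#'   order (`cell = (row-1)*ncol + col`).
#' @export
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), times = nr)
  row <- rep(seq_len(nr), each = nc)
  cbind(x = r$xmin + (col - 0.5) * r$res,
        y = r$ymax - (row - 0.5) * r$res)
}

# row-major cell index <-> matrix subscripts
cell_to_rowcol <- function(r, cell) {
  nc <- ncol(r$values)
  cbind(row = (cell - 1L) %/% nc + 1L, col = (cell - 1L) %% nc + 1L)
}

cell_values <- function(r, cell) r$values[cell_to_rowcol(r, cell)]

`cell_values<-` <- function(r, cell, value) {
  r$values[cell_to_rowcol(r, cell)] <- value
  r
}

# value at arbitrary coordinates: nearest (cell containing the point, cells
# half-open) or bilinear interpolation between cell centres
raster_extract <- function(r, xy, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  xy <- as_coord_matrix(xy)
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (method == "nearest") {
    col <- floor((xy[, 1] - r$xmin) / r$res) + 1
    row <- floor((r$ymax - xy[, 2]) / r$res) + 1
    ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
    out <- rep(NA_real_, nrow(xy))
    out[ok] <- r$values[cbind(row[ok], col[ok])]
    return(out)
  }
  # bilinear on cell-centre lattice, clamped at edges
  fx <- (xy[, 1] - (r$xmin + 0.5 * r$res)) / r$res
  fy <- ((r$ymax - 0.5 * r$res) - xy[, 2]) / r$res
  c0 <- pmin(pmax(floor(fx), 0), nc - 1); r0 <- pmin(pmax(floor(fy), 0), nr - 1)
  c1 <- pmin(c0 + 1, nc - 1); r1 <- pmin(r0 + 1, nr - 1)
  wx <- pmin(pmax(fx - c0, 0), 1); wy <- pmin(pmax(fy - r0, 0), 1)
  v00 <- r$values[cbind(r0 + 1, c0 + 1)]; v01 <- r$values[cbind(r0 + 1, c1 + 1)]
  v10 <- r$values[cbind(r1 + 1, c0 + 1)]; v11 <- r$values[cbind(r1 + 1, c1 + 1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' The pipeline's raster interchange format is the plain-text ESRI ASCII
#' grid (`.asc`), readable by standard GIS tooling, with the CRS stored in a
#' `.prj` sidecar file (`EPSG:<code>`). Values are written at full double
#' precision so a write/read round trip is exact.
#'
#' @param r a `baci_raster`.
#' @param path output path (`.asc`); the sidecar is `path` with `.prj`
#'   substituted.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `baci_raster`.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "baci_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  nr <- nrow(r$values); nc <- ncol(r$values)
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.10f", r$xmin)),
    paste("yllcorner", sprintf("%.10f", r$ymax - nr * r$res)),
    paste("cellsize", sprintf("%.10f", r$res)),
    "NODATA_value -9999"
  ), con)
  v <- r$values
  v[is.na(v)] <- -9999
  for (i in seq_len(nr))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  writeLines(paste0("EPSG:", r$crs$epsg), sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' @rdname write_raster
#' @param name layer name for the raster read back.
#' @export
read_raster <- function(path, name = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  prj <- sub("\\.asc$", ".prj", path)
  epsg <- if (file.exists(prj)) {
    as.integer(sub("^EPSG:", "", readLines(prj, n = 1)))
  } else stop("missing .prj sidecar for ", path, "; CRS unknown")
  bc_raster(m, hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
            hdr$cellsize, bc_crs(epsg), name)
}
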