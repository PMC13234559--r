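#' Scene stacks and yearly value stacks
#'
#' Two containers feed the time-series summarisation step. A *scene stack*
#' (`baci_imagestack`) holds individual acquisitions: per scene a date,
#' reflectance band matrices, a logical quality mask (`TRUE` = valid pixel,
#' i.e. not cloud/shadow) and a scene-level cloud percentage. A *yearly
#' stack* (`baci_yearly`) holds one composited value matrix per year.
#' Both share the geometry of the unit grid.
#'
#' @param scenes list of scenes, each a list with `date` (a `Date`),
#'   `bands` (named list of matrices), `mask` (logical matrix or `NULL` for
#'   all-valid), `cloud_pct` (scalar, 0-100; default 0).
#' @param grid a `baci_raster` providing the geometry.
#' @return a `baci_imagestack`.
#' @export
image_stack <- function(scenes, grid) {
  stopifnot(inherits(grid, "baci_raster"))
  dm <- dim(grid$values)
  for (s in scenes) {
    stopifnot(inherits(s$date, "Date"), is.list(s$bands))
    for (b in s$bands) stopifnot(all(dim(b) == dm))
    if (!is.null(s$mask)) stopifnot(all(dim(s$mask) == dm))
  }
  structure(list(scenes = scenes, grid = grid), class = "baci_imagestack")
}

#' @rdname image_stack
#' @param values 3-d array (rows, cols, years) of yearly composite values.
#' @param years integer vector of calendar years, one per array slice.
#' @export
yearly_stack <- function(values, years, grid) {
  stopifnot(inherits(grid, "baci_raster"),
            length(dim(values)) == 3, dim(values)[3] == length(years),
            all(dim(values)[1:2] == dim(grid$values)))
  structure(list(values = values, years = as.integer(years), grid = grid),
            class = "baci_yearly")
}

#' Read a scene stack from a manifest
#'
#' Loads scenes listed in a CSV manifest with columns `date` (ISO),
#' `cloud_pct`, and one path column per band (e.g. `nir`, `red`), plus an
#' optional `mask` column (raster of 1 = valid / 0 = invalid). All rasters
#' are ESRI ASCII grids on the unit grid.
#'
#' @param manifest path to the manifest CSV; relative band paths are
#'   resolved against its directory.
#' @param grid the unit grid the scenes must share.
#' @return a `baci_imagestack`.
#' @export
read_image_stack <- function(manifest, grid) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot("date" %in% names(mf))
  base <- dirname(manifest)
  bandcols <- setdiff(names(mf), c("date", "cloud_pct", "mask"))
  ctr <- cell_centres(grid)
  dm <- dim(grid$values)
  # scenes covering a larger window are cropped/aligned to the unit grid by
  # nearest-cell extraction at the grid's cell centres
  to_grid <- function(r, p) {
    if (same_grid(r, grid)) return(r$values)
    if (!crs_equal(r$crs, grid$crs))
      stop("scene raster CRS differs from the unit grid: ", p)
    matrix(raster_extract(r, ctr, "nearest"), dm[1], dm[2], byrow = TRUE)
  }
  scenes <- lapply(seq_len(nrow(mf)), function(i) {
    bands <- lapply(mf[i, bandcols, drop = FALSE], function(p)
      to_grid(read_raster(file.path(base, p)), p))
    names(bands) <- bandcols
    mask <- NULL
    if ("mask" %in% names(mf) && nzchar(mf$mask[i]))
      mask <- {
        m <- to_grid(read_raster(file.path(base, mf$mask[i])), mf$mask[i])
        !is.na(m) & m == 1  # cells outside the scene's coverage are invalid
      }
    list(date = as.Date(mf$date[i]), bands = bands, mask = mask,
         cloud_pct = if ("cloud_pct" %in% names(mf)) mf$cloud_pct[i] else 0)
  })
  image_stack(scenes, grid)
}

#' Vegetation index from reflectance bands
#'
#' Currently implements NDVI = (NIR - red) / (NIR + red); zero denominator
#' yields `NA` and the result is clipped to [-1, 1].
#'
#' @param bands named list of band matrices.
#' @param index index name (only `"NDVI"`).
#' @return a matrix of index values.
#' @export
vegetation_index <- function(bands, index = "NDVI") {
  index <- match.arg(index, "NDVI")
  for (b in c("nir", "red"))
    if (is.null(bands[[b]])) stop("missing band '", b, "' required for NDVI")
  nir <- bands$nir; red <- bands$red
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA
  out[] <- pmin(1, pmax(-1, out))  # clip in place to keep matrix dims
  out
}

#' Yearly median composite of a vegetation index
#'
#' Per-pixel median of the index over all scenes acquired in the given year
#' and months, using only pixels flagged valid by the quality mask. Scenes
#' whose scene-level cloud percentage exceeds `max_cloud` are excluded
#' entirely. An even number of valid observations yields the mean of the
#' two middle values; a pixel with no valid observation is `NA`.
#'
#' @param stack a `baci_imagestack`.
#' @param year calendar year.
#' @param months integer months to include (default 1:12).
#' @param index vegetation index name.
#' @param max_cloud optional scene-level cloud-cover ceiling in percent.
#' @return a matrix of composite values, or all-`NA` with a warning when no
#'   scene passes the filters.
#' @export
yearly_composite <- function(stack, year, months = 1:12, index = "NDVI",
                             max_cloud = NULL) {
  stopifnot(inherits(stack, "baci_imagestack"))
  keep <- vapply(stack$scenes, function(s) {
    as.integer(format(s$date, "%Y")) == year &&
      as.integer(format(s$date, "%m")) %in% months &&
      (is.null(max_cloud) || s$cloud_pct <= max_cloud)
  }, TRUE)
  dm <- dim(stack$grid$values)
  if (!any(keep)) {
    warning("no scenes for year ", year, " after date/cloud filters")
    return(matrix(NA_real_, dm[1], dm[2]))
  }
  scenes <- stack$scenes[keep]
  vals <- vapply(scenes, function(s) {
    v <- vegetation_index(s$bands, index)
    if (!is.null(s$mask)) v[!s$mask] <- NA
    v
  }, matrix(0, dm[1], dm[2]))
  apply(vals, c(1, 2), stats::median, na.rm = TRUE) |>
    (\(m) { m[is.nan(m)] <- NA; m })()
}

#' Build a yearly stack from a scene stack
#'
#' Applies [yearly_composite()] over a sequence of years.
#'
#' @param stack a `baci_imagestack`.
#' @param years integer years.
#' @inheritParams yearly_composite
#' @return a `baci_yearly`.
#' @export
composite_years <- function(stack, years, months = 1:12, index = "NDVI",
                            max_cloud = NULL) {
  dm <- dim(stack$grid$values)
  arr <- array(NA_real_, c(dm[1], dm[2], length(years)))
  for (k in seq_along(years))
    arr[, , k] <- yearly_composite(stack, years[k], months, index, max_cloud)
  yearly_stack(arr, years, stack$grid)
}

#' Per-pixel time-series metrics
#'
#' Summarises a yearly stack into a temporal mean and an ordinary
#' least-squares trend (slope of value on calendar year, missing years
#' omitted, regressor centred), and optionally the fitted value at the
#' earliest or latest year of the period. The mean needs at least one
#' non-missing year per pixel; the trend at least `min_years`.
#'
#' @param stack a `baci_yearly`.
#' @param intercept_at `"none"`, `"min"` or `"max"`: return the fitted line
#'   evaluated at the first/last year of the period.
#' @param min_years minimum non-missing years required for a trend
#'   (default 3).
#' @return a `baci_tsmetrics`: list of `baci_raster` layers `mean`, `trend`
#'   (units per year), optionally `intercept`, plus `n_years`.
#' @examples
#' crs <- bc_crs(32735)
#' g <- bc_raster(matrix(0, 1, 1), 0, 60, 60, crs)
#' ys <- yearly_stack(array(c(0.1, 0.2, 0.3), c(1, 1, 3)), 2001:2003, g)
#' m <- calc_ts_metrics(ys, intercept_at = "min")
#' c(m$mean$values, m$trend$values, m$intercept$values)  # 0.2, 0.1, 0.1
#' @export
calc_ts_metrics <- function(stack, intercept_at = c("none", "min", "max"),
                            min_years = 3) {
  stopifnot(inherits(stack, "baci_yearly"))
  intercept_at <- match.arg(intercept_at)
  v <- stack$values
  yrs <- stack$years
  tc <- yrs - mean(yrs)
  dm <- dim(v)

  n <- apply(!is.na(v), c(1, 2), sum)
  mu <- apply(v, c(1, 2), mean, na.rm = TRUE)
  mu[n == 0] <- NA

  # OLS slope with per-pixel missingness: loop over distinct missing
  # patterns is overkill at these sizes; direct per-pixel computation
  slope <- matrix(NA_real_, dm[1], dm[2])
  icpt <- matrix(NA_real_, dm[1], dm[2])
  t_eval <- if (intercept_at == "min") min(yrs) else max(yrs)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    ok <- !is.na(v[i, j, ])
    if (sum(ok) < max(2, min_years)) next
    tt <- tc[ok]; vv <- v[i, j, ok]
    st <- sum((tt - mean(tt))^2)
    if (st == 0) next
    b <- sum((tt - mean(tt)) * (vv - mean(vv))) / st
    a <- mean(vv) - b * mean(tt)
    slope[i, j] <- b
    icpt[i, j] <- a + b * (t_eval - mean(yrs))
  }

  lay <- function(m, nm) bc_raster(m, stack$grid$xmin, stack$grid$ymax,
                                   stack$grid$res, stack$grid$crs, nm)
  out <- list(mean = lay(mu, "mean"), trend = lay(slope, "trend"),
              n_years = lay(n, "n_years"))
  if (intercept_at != "none") out$intercept <- lay(icpt, "intercept")
  structure(out, class = "baci_tsmetrics",
            intercept_at = intercept_at, years = yrs)
}
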