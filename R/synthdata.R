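#' Synthetic landscape with confounded intervention placement
#'
#' Generates a fully synthetic study area with known ground truth so the
#' whole pipeline runs offline: a smooth random elevation field (sum of
#' seeded 2-d cosine basis functions), a categorical land-cover raster
#' (thresholded second smooth field), a few random road polylines, and
#' intervention polygons placed with configurable confounding — seed cells
#' are drawn with probability `plogis(b0 + b_elev * z(elev) +
#' b_road * z(dist_road))` and grown into small rectangular sites, so
#' non-zero coefficients reproduce the real-world pattern that restoration
#' sites sit on systematically different terrain than the candidate
#' controls around them.
#'
#' @param seed integer seed; the landscape is reproducible from it.
#' @param size grid size in cells (`c(nrow, ncol)` or a scalar; >= 20).
#' @param res cell size in metres (default 60, a Landsat-class analysis
#'   resolution).
#' @param n_classes number of land-cover classes (default 3).
#' @param n_sites number of intervention polygons (default 4).
#' @param site_cells approximate side of each site, in cells (default 5).
#' @param confounding named numeric vector of placement coefficients on the
#'   standardised covariates, e.g. `c(elev = 1.5, road = 0)`; `c(elev = 0,
#'   road = 0)` gives unconfounded (random) placement.
#' @param crs projected CRS of the landscape (default UTM 35S, a southern-
#'   hemisphere restoration setting).
#' @return a `baci_landscape`: `dem`, `lulc` (land-cover raster with
#'   scheme), `roads` (`baci_geoms` lines), `impact_polygons`,
#'   `control_exclude` (empty polygon set placeholder), and `truth`
#'   recording every generator parameter.
#' @export
make_landscape <- function(seed, size = c(50, 50), res = 60, n_classes = 3,
                           n_sites = 4, site_cells = 5,
                           confounding = c(elev = 0, road = 0),
                           crs = bc_crs(32735)) {
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 20)) stop("landscape must be at least 20x20 cells")
  nr <- size[1]; nc <- size[2]
  set.seed(seed)

  x0 <- 500000; y1 <- 6300000  # plausible UTM coordinates
  grid <- bc_raster(matrix(NA_real_, nr, nc), x0, y1, res, crs, "landscape")

  dem_field <- smooth_field(nr, nc, k = 6, scale = 150) + 800
  dem <- bc_raster(dem_field, x0, y1, res, crs, "elevation")

  lc_field <- smooth_field(nr, nc, k = 5, scale = 1)
  q <- stats::quantile(lc_field, probs = seq_len(n_classes - 1) / n_classes)
  lulc_vals <- matrix(findInterval(lc_field, q) + 1, nr, nc)
  scheme <- stats::setNames(paste0("class", seq_len(n_classes)),
                            as.character(seq_len(n_classes)))
  lulc <- encode_landcover(bc_raster(lulc_vals, x0, y1, res, crs, "landcover"),
                           scheme)

  # two random roads crossing the extent
  xmax <- x0 + nc * res; ymin <- y1 - nr * res
  roads <- bc_lines(list(
    wiggly_line(c(x0, stats::runif(1, ymin, y1)),
                c(xmax, stats::runif(1, ymin, y1)), 8, res * 4),
    wiggly_line(c(stats::runif(1, x0, xmax), y1),
                c(stats::runif(1, x0, xmax), ymin), 8, res * 4)),
    attrs = data.frame(class = c("track", "secondary")), crs = crs)

  # confounded site placement: seed-cell probability from standardised
  # elevation and distance-to-road
  ctr <- cell_centres(grid)
  elev_v <- as.vector(t(dem$values))
  road_v <- dist_points_geoms(ctr, roads)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  b_elev <- if ("elev" %in% names(confounding)) confounding[["elev"]] else 0
  b_road <- if ("road" %in% names(confounding)) confounding[["road"]] else 0
  lin <- b_elev * zs(elev_v) + b_road * zs(road_v)

  half <- floor(site_cells / 2)
  inner <- which(ctr[, 1] > x0 + (half + 1) * res &
                 ctr[, 1] < xmax - (half + 1) * res &
                 ctr[, 2] > ymin + (half + 1) * res &
                 ctr[, 2] < y1 - (half + 1) * res)
  prob <- exp(lin[inner] - max(lin[inner]))
  seeds <- sample(inner, n_sites, prob = prob)
  polys <- lapply(seeds, function(cell) {
    cx <- ctr[cell, 1]; cy <- ctr[cell, 2]
    w <- (half + 0.5) * res
    h <- (half + sample(0:1, 1) + 0.5) * res
    rect_ring(cx - w, cy - h, cx + w, cy + h)
  })
  impact_polygons <- bc_polygons(
    polys, attrs = data.frame(Planting_date = rep(2012L, n_sites),
                              Lifestock_exclusion = rep(0L, n_sites)),
    crs = crs)

  structure(list(dem = dem, lulc = lulc, roads = roads,
                 impact_polygons = impact_polygons, grid = grid,
                 truth = list(seed = seed, size = size, res = res,
                              n_classes = n_classes, n_sites = n_sites,
                              site_cells = site_cells,
                              confounding = c(elev = b_elev, road = b_road))),
            class = "baci_landscape")
}

# smooth random field: sum of k random 2-d cosine waves, standardised then
# scaled; low frequencies give terrain-like spatial autocorrelation
smooth_field <- function(nr, nc, k = 6, scale = 1) {
  ry <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
  rx <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  f <- matrix(0, nr, nc)
  for (i in seq_len(k)) {
    fr <- stats::runif(2, 0.5, 3)
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(1, 0.3, 1)
    f <- f + amp * cos(2 * pi * fr[1] * rx + ph[1]) *
               cos(2 * pi * fr[2] * ry + ph[2])
  }
  (f - mean(f)) / stats::sd(f) * scale
}

wiggly_line <- function(a, b, n_seg, jitter) {
  t <- seq(0, 1, length.out = n_seg + 1)
  px <- a[1] + t * (b[1] - a[1]); py <- a[2] + t * (b[2] - a[2])
  mid <- seq(2, n_seg)
  px[mid] <- px[mid] + stats::rnorm(length(mid), 0, jitter)
  py[mid] <- py[mid] + stats::rnorm(length(mid), 0, jitter)
  cbind(x = px, y = py)
}

#' Synthetic before/after outcome series with injected treatment effect
#'
#' Builds yearly outcome stacks on the landscape grid following
#' `v(p, t) = base + trend * (t - t0) + field(p) + trend_conf * z(elev_p) *
#' (t - t0) + noise + delta * [p impact and t after]`: a static spatial
#' fertility field (cancelled exactly by the difference-in-difference), an
#' optional elevation-dependent trend (`trend_confounding`) that biases
#' naive estimators when placement is elevation-confounded, i.i.d. Gaussian
#' observation noise, and an additive treatment effect `delta` on impact
#' pixels in the after period only. With `as_scenes = TRUE`, each year is
#' expanded into NIR/red reflectance scene pairs whose NDVI equals the
#' outcome value, with random cloud masks, to exercise the compositing
#' path.
#'
#' @param landscape a `baci_landscape`.
#' @param years_before,years_after integer year vectors (e.g. 2002:2011 and
#'   2013:2022 around a 2012 intervention).
#' @param base baseline outcome level (default 0.3, a typical semi-arid
#'   NDVI).
#' @param trend common linear trend per year (default 0).
#' @param delta additive treatment effect on after-period impact pixels.
#' @param sigma i.i.d. noise standard deviation per pixel-year.
#' @param trend_confounding slope of the elevation-dependent trend term
#'   (outcome units per year per SD of elevation; default 0).
#' @param field_sd standard deviation of the static spatial field
#'   (default 0.05).
#' @param missing_frac fraction of pixel-years masked missing (default 0).
#' @param scenes_per_year scenes per year when `as_scenes = TRUE`.
#' @param as_scenes return `baci_imagestack`s instead of yearly stacks.
#' @param seed integer seed.
#' @return list with `before`, `after` (each `baci_yearly` or
#'   `baci_imagestack`), `impact_mask` (logical matrix), and `truth`.
#' @export
make_outcome_series <- function(landscape, years_before, years_after,
                                base = 0.3, trend = 0, delta = 0.1,
                                sigma = 0.02, trend_confounding = 0,
                                field_sd = 0.05, missing_frac = 0,
                                scenes_per_year = 3, as_scenes = FALSE,
                                seed = 1L) {
  stopifnot(inherits(landscape, "baci_landscape"),
            length(years_before) >= 1, length(years_after) >= 1,
            is.finite(delta), is.finite(sigma))
  set.seed(seed)
  grid <- landscape$grid
  nr <- nrow(grid$values); nc <- ncol(grid$values)

  impact_mask_v <- points_in_geoms(cell_centres(grid), landscape$impact_polygons)
  impact_mask <- matrix(impact_mask_v, nr, nc, byrow = TRUE)

  field <- smooth_field(nr, nc, k = 6, scale = field_sd)
  elev_z <- (landscape$dem$values - mean(landscape$dem$values)) /
    stats::sd(landscape$dem$values)
  t0 <- max(years_before) + 1  # intervention year

  build <- function(years, treated) {
    arr <- array(NA_real_, c(nr, nc, length(years)))
    for (k in seq_along(years)) {
      t <- years[k]
      v <- base + trend * (t - t0) + field +
        trend_confounding * elev_z * (t - t0) +
        matrix(stats::rnorm(nr * nc, 0, sigma), nr, nc)
      if (treated) v <- v + delta * impact_mask
      if (missing_frac > 0)
        v[matrix(stats::runif(nr * nc) < missing_frac, nr, nc)] <- NA
      arr[, , k] <- v
    }
    yearly_stack(arr, years, grid)
  }
  before <- build(years_before, treated = FALSE)
  after <- build(years_after, treated = TRUE)

  if (as_scenes) {
    before <- yearly_to_scenes(before, scenes_per_year, sigma / 2, missing_frac)
    after <- yearly_to_scenes(after, scenes_per_year, sigma / 2, missing_frac)
  }
  list(before = before, after = after, impact_mask = impact_mask,
       truth = list(delta = delta, sigma = sigma, base = base, trend = trend,
                    trend_confounding = trend_confounding,
                    field_sd = field_sd, missing_frac = missing_frac,
                    seed = seed, intervention_year = t0))
}

# expand a yearly stack into scene pairs whose NDVI reproduces the yearly
# value plus scene-level noise; red fixed at 0.1, nir solved from the NDVI
# formula
yearly_to_scenes <- function(ystack, scenes_per_year, scene_sigma,
                             missing_frac) {
  grid <- ystack$grid
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  scenes <- list()
  for (k in seq_along(ystack$years)) {
    yv <- ystack$values[, , k]
    for (s in seq_len(scenes_per_year)) {
      ndvi <- pmin(0.99, pmax(-0.99,
        yv + matrix(stats::rnorm(nr * nc, 0, scene_sigma), nr, nc)))
      red <- matrix(0.1, nr, nc)
      nir <- red * (1 + ndvi) / (1 - ndvi)
      mask <- matrix(stats::runif(nr * nc) >= missing_frac, nr, nc)
      nir[is.na(nir)] <- 0; red[is.na(ndvi)] <- 0
      mask[is.na(ndvi)] <- FALSE
      scenes[[length(scenes) + 1L]] <- list(
        date = as.Date(sprintf("%d-%02d-15", ystack$years[k], 2 + s)),
        bands = list(nir = nir, red = red), mask = mask,
        cloud_pct = stats::runif(1, 0, 50))
    }
  }
  image_stack(scenes, grid)
}
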