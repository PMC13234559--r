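#' Coordinate reference systems
#'
#' Lightweight CRS descriptors for the two cases the pipeline needs:
#' geographic WGS84 longitude/latitude, and projected UTM zones (metres).
#' All raster and matching geometry lives in a projected CRS; geographic
#' input polygons are projected to the UTM zone of their centroid.
#'
#' @param epsg integer EPSG code. Recognised: 4326 (geographic WGS84),
#'   326xx / 327xx (UTM zone xx north / south, WGS84 datum).
#' @return an object of class `baci_crs` with fields `epsg`, `kind`
#'   (`"geographic"` or `"projected"`), and for UTM `zone` and `south`.
#' @examples
#' bc_crs(32735)  # UTM zone 35 South
#' @export
bc_crs <- function(epsg) {
  epsg <- as.integer(epsg)
  if (epsg == 4326L) {
    out <- list(epsg = epsg, kind = "geographic", units = "degrees")
  } else if (epsg >= 32601L && epsg <= 32660L) {
    out <- list(epsg = epsg, kind = "projected", units = "m",
                zone = epsg - 32600L, south = FALSE)
  } else if (epsg >= 32701L && epsg <= 32760L) {
    out <- list(epsg = epsg, kind = "projected", units = "m",
                zone = epsg - 32700L, south = TRUE)
  } else {
    # any other positive code is accepted as an opaque projected CRS in metres
    out <- list(epsg = epsg, kind = "projected", units = "m")
  }
  structure(out, class = "baci_crs")
}

#' @export
print.baci_crs <- function(x, ...) {
  cat("<baci_crs> EPSG:", x$epsg, " (", x$kind, ", ", x$units, ")\n", sep = "")
  invisible(x)
}

is_projected <- function(crs) {
  inherits(crs, "baci_crs") && identical(crs$kind, "projected")
}

crs_equal <- function(a, b) {
  inherits(a, "baci_crs") && inherits(b, "baci_crs") && a$epsg == b$epsg
}

#' UTM zone CRS from the centroid of a polygon set
#'
#' Determines the Universal Transverse Mercator zone containing the centroid
#' of a geographic polygon set: zone `floor((lon + 180)/6) + 1`, hemisphere
#' from the centroid latitude. This is the default projected CRS for the
#' analysis grid when intervention polygons are supplied in longitude/latitude.
#'
#' @param polygons a `baci_geoms` polygon set in a geographic CRS.
#' @return a `baci_crs` for the matching UTM zone (EPSG 326xx north / 327xx
#'   south).
#' @examples
#' sq <- bc_polygons(list(rect_ring(24, -34, 25, -33.2)), crs = bc_crs(4326))
#' utm_crs_from_centroid(sq)  # EPSG:32735
#' @export
utm_crs_from_centroid <- function(polygons) {
  stopifnot(inherits(polygons, "baci_geoms"))
  if (length(polygons$geoms) == 0L) stop("polygon set is empty")
  if (is_projected(polygons$crs))
    stop("utm_crs_from_centroid() expects polygons in a geographic CRS; ",
         "input is already projected (EPSG:", polygons$crs$epsg, ")")
  ct <- geom_centroid(polygons)
  lon <- ct[1]; lat <- ct[2]
  if (!is.finite(lon) || !is.finite(lat)) stop("centroid is not finite")
  if (lat < -80 || lat > 84)
    stop("centroid latitude ", format(lat), " outside [-80, 84]: UTM undefined")
  zone <- floor((lon + 180) / 6) + 1
  zone <- max(1L, min(60L, as.integer(zone)))
  bc_crs(if (lat >= 0) 32600L + zone else 32700L + zone)
}

# Forward transverse Mercator projection (WGS84 ellipsoid, standard UTM
# parameters: k0 = 0.9996, false easting 500 km, false northing 10000 km in
# the southern hemisphere). Series accurate to well under a metre, which is
# ample for unit definition at tens-of-metres resolution.
project_to_utm <- function(lonlat, crs) {
  stopifnot(is_projected(crs), !is.null(crs$zone))
  lon <- lonlat[, 1] * pi / 180
  lat <- lonlat[, 2] * pi / 180
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (-183 + 6 * crs$zone) * pi / 180

  N <- a / sqrt(1 - e2 * sin(lat)^2)
  T <- tan(lat)^2
  C <- ep2 * cos(lat)^2
  A <- (lon - lon0) * cos(lat)

  # meridional arc
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * lat -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * lat) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * lat) -
    (35 * e2^3 / 3072) * sin(6 * lat))

  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
    (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(lat) * (A^2 / 2 +
    (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (isTRUE(crs$south)) y <- y + 1e7
  cbind(x = x, y = y)
}
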