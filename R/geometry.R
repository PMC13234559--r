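#' Vector geometry sets
#'
#' A minimal feature collection for the pipeline: a list of coordinate
#' matrices (columns x, y) in one CRS, with an attribute table. Polygon
#' features may contain several rings separated by an `NA` row (even-odd
#' rule: additional rings are holes or disjoint parts); line features are
#' open polylines, point features single coordinates.
#'
#' @param geoms list of numeric matrices with columns x, y. Polygon rings
#'   need not be explicitly closed; they are closed on construction.
#' @param attrs optional data.frame of per-feature attributes (one row per
#'   element of `geoms`).
#' @param crs a [bc_crs()] object.
#' @return a `baci_geoms` object with fields `type`, `geoms`, `attrs`, `crs`.
#' @export
bc_polygons <- function(geoms, attrs = NULL, crs) {
  new_geoms("polygon", lapply(geoms, close_rings), attrs, crs)
}

#' @rdname bc_polygons
#' @export
bc_lines <- function(geoms, attrs = NULL, crs) {
  new_geoms("line", lapply(geoms, as_coord_matrix), attrs, crs)
}

#' @rdname bc_polygons
#' @export
bc_points <- function(geoms, attrs = NULL, crs) {
  if (is.matrix(geoms)) geoms <- lapply(seq_len(nrow(geoms)), function(i) geoms[i, , drop = FALSE])
  new_geoms("point", lapply(geoms, as_coord_matrix), attrs, crs)
}

new_geoms <- function(type, geoms, attrs, crs) {
  stopifnot(inherits(crs, "baci_crs"))
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(geoms))
  if (nrow(attrs) != length(geoms))
    stop("attrs must have one row per feature")
  structure(list(type = type, geoms = geoms, attrs = attrs, crs = crs),
            class = "baci_geoms")
}

as_coord_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 2)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

# close every NA-separated ring of a polygon coordinate matrix
close_rings <- function(m) {
  m <- as_coord_matrix(m)
  rings <- split_rings(m)
  rings <- lapply(rings, function(r) {
    if (nrow(r) < 3) stop("polygon ring with fewer than 3 vertices")
    if (!isTRUE(all.equal(r[1, ], r[nrow(r), ], check.attributes = FALSE)))
      r <- rbind(r, r[1, ])
    r
  })
  join_rings(rings)
}

split_rings <- function(m) {
  na_row <- is.na(m[, 1]) | is.na(m[, 2])
  grp <- cumsum(na_row)
  keep <- !na_row
  unname(lapply(split(seq_len(nrow(m))[keep], grp[keep]),
                function(i) m[i, , drop = FALSE]))
}

join_rings <- function(rings) {
  if (length(rings) == 1) return(rings[[1]])
  out <- rings[[1]]
  for (r in rings[-1]) out <- rbind(out, c(NA, NA), r)
  out
}

#' @export
print.baci_geoms <- function(x, ...) {
  cat("<baci_geoms> ", length(x$geoms), " ", x$type, " feature(s), EPSG:",
      x$crs$epsg, "\n", sep = "")
  if (ncol(x$attrs)) {
    cat("attributes:\n")
    print(utils::head(x$attrs))
  }
  invisible(x)
}

#' @export
`[.baci_geoms` <- function(x, i) {
  new_geoms(x$type, x$geoms[i], x$attrs[i, , drop = FALSE], x$crs)
}

#' @export
length.baci_geoms <- function(x) length(x$geoms)

#' Axis-aligned rectangle ring
#'
#' Convenience constructor for a closed rectangular polygon ring.
#' @param xmin,ymin,xmax,ymax rectangle corners.
#' @return a 5x2 coordinate matrix (closed ring).
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}

geom_bbox <- function(g) {
  xs <- unlist(lapply(g$geoms, function(m) m[, 1]))
  ys <- unlist(lapply(g$geoms, function(m) m[, 2]))
  c(xmin = min(xs, na.rm = TRUE), ymin = min(ys, na.rm = TRUE),
    xmax = max(xs, na.rm = TRUE), ymax = max(ys, na.rm = TRUE))
}

# Area-weighted centroid of a polygon set (shoelace formula per ring; holes
# carry negative signed area so they subtract correctly). For points/lines,
# the vertex mean.
geom_centroid <- function(g) {
  if (g$type != "polygon") {
    xs <- unlist(lapply(g$geoms, function(m) m[, 1]))
    ys <- unlist(lapply(g$geoms, function(m) m[, 2]))
    return(c(x = mean(xs, na.rm = TRUE), y = mean(ys, na.rm = TRUE)))
  }
  A_tot <- 0; cx <- 0; cy <- 0
  for (m in g$geoms) for (r in split_rings(m)) {
    x <- r[, 1]; y <- r[, 2]; n <- nrow(r)
    i <- seq_len(n - 1)
    cross <- x[i] * y[i + 1] - x[i + 1] * y[i]
    A <- sum(cross) / 2
    if (abs(A) < .Machine$double.eps) next
    cx <- cx + sum((x[i] + x[i + 1]) * cross) / 6
    cy <- cy + sum((y[i] + y[i + 1]) * cross) / 6
    A_tot <- A_tot + A
  }
  if (A_tot == 0) stop("degenerate polygon set: zero total area")
  c(x = cx / A_tot, y = cy / A_tot)
}

# Even-odd point-in-polygon test over the whole feature set: TRUE where the
# point falls inside any feature (holes excluded per feature).
points_in_geoms <- function(pts, g) {
  stopifnot(g$type == "polygon")
  pts <- as_coord_matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  for (m in g$geoms) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- mgcv::in.out(m, pts[todo, , drop = FALSE])
  }
  inside
}

# Minimum Euclidean distance from each point to a feature set. For polygons
# the distance is 0 for points inside; otherwise distance to the nearest
# ring segment. Vectorised over points per segment.
dist_points_geoms <- function(pts, g) {
  pts <- as_coord_matrix(pts)
  n <- nrow(pts)
  d <- rep(Inf, n)
  for (m in g$geoms) {
    if (g$type == "point") {
      for (i in seq_len(nrow(m)))
        d <- pmin(d, sqrt((pts[, 1] - m[i, 1])^2 + (pts[, 2] - m[i, 2])^2))
      next
    }
    for (r in split_rings(m)) {
      nr <- nrow(r)
      if (nr == 1) {
        d <- pmin(d, sqrt((pts[, 1] - r[1, 1])^2 + (pts[, 2] - r[1, 2])^2))
        next
      }
      for (i in seq_len(nr - 1))
        d <- pmin(d, dist_points_segment(pts, r[i, ], r[i + 1, ]))
    }
  }
  if (g$type == "polygon") d[points_in_geoms(pts, g)] <- 0
  d
}

dist_points_segment <- function(pts, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * vx + (pts[, 2] - a[2]) * vy) / L2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * vx; py <- a[2] + t * vy
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Project a geographic geometry set to a UTM CRS (no-op if already there).
geoms_to_crs <- function(g, crs) {
  if (crs_equal(g$crs, crs)) return(g)
  if (is_projected(g$crs))
    stop("cannot reproject between projected CRSs (EPSG:", g$crs$epsg,
         " -> EPSG:", crs$epsg, ")")
  geoms <- lapply(g$geoms, function(m) {
    ok <- !is.na(m[, 1])
    out <- m
    out[ok, ] <- project_to_utm(m[ok, , drop = FALSE], crs)
    out
  })
  new_geoms(g$type, geoms, g$attrs, crs)
}
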