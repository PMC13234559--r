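#' Specification of impact and control unit construction
#'
#' Collects the parameters that turn intervention polygons into a labelled
#' analysis grid: the grid resolution, where candidate control pixels may
#' come from (a neighbourhood buffer around the impact polygons and/or an
#' explicit control polygon), exclusion zones, a spillover exclusion buffer
#' around impact sites, optional seeded subsampling of either class, and
#' grid-origin rounding.
#'
#' @param resolution cell size in metres (> 0).
#' @param control_from_buffer neighbourhood radius in metres around the
#'   impact polygons from which control pixels are drawn, or `NULL`.
#' @param control_from_polygon a `baci_geoms` polygon set delimiting the
#'   control area, or `NULL`. At least one of the two control sources must
#'   be given; when both are given their union is used.
#' @param control_exclude polygon set whose interior is excluded from the
#'   control pool (e.g. other intervention sites), or `NULL`.
#' @param exclude_impact_buffer controls closer than this many metres to any
#'   impact polygon are excluded, to limit spillover/leakage and
#'   misregistration effects. Applies to control eligibility only.
#' @param impact_inner_buffer optional erosion of the impact class: impact
#'   pixels whose centre is within this many metres of the polygon boundary
#'   are dropped. Default off.
#' @param sample_impact,sample_control fraction in (0, 1] of the final
#'   impact/control pixel pool to retain (seeded uniform subsample), or
#'   `NULL` to keep all.
#' @param round_coords integer decimal exponent for grid-origin rounding:
#'   `-2` snaps the origin to the nearest 100 m (half away from zero), `NULL`
#'   keeps the exact bounding-box corner.
#' @param seed integer seed for the subsampling PRNG.
#' @return a validated `baci_unit_spec` list.
#' @export
unit_spec <- function(resolution,
                      control_from_buffer = NULL,
                      control_from_polygon = NULL,
                      control_exclude = NULL,
                      exclude_impact_buffer = NULL,
                      impact_inner_buffer = NULL,
                      sample_impact = NULL,
                      sample_control = NULL,
                      round_coords = NULL,
                      seed = 1L) {
  stopifnot(is.numeric(resolution), length(resolution) == 1, resolution > 0)
  if (is.null(control_from_buffer) && is.null(control_from_polygon))
    stop("at least one of control_from_buffer / control_from_polygon is required")
  for (b in list(control_from_buffer, exclude_impact_buffer, impact_inner_buffer))
    if (!is.null(b) && (!is.numeric(b) || b < 0)) stop("buffers must be non-negative")
  for (f in list(sample_impact, sample_control))
    if (!is.null(f) && (f <= 0 || f > 1)) stop("sampling fractions must be in (0, 1]")
  if (!is.null(round_coords)) stopifnot(round_coords == as.integer(round_coords))
  structure(list(resolution = resolution,
                 control_from_buffer = control_from_buffer,
                 control_from_polygon = control_from_polygon,
                 control_exclude = control_exclude,
                 exclude_impact_buffer = exclude_impact_buffer,
                 impact_inner_buffer = impact_inner_buffer,
                 sample_impact = sample_impact,
                 sample_control = sample_control,
                 round_coords = round_coords,
                 seed = as.integer(seed)),
            class = "baci_unit_spec")
}

# round half away from zero to a multiple of m
round_half_away <- function(x, m) sign(x) * floor(abs(x) / m + 0.5) * m

#' Build the empty analysis grid for a polygon set
#'
#' Computes the grid geometry (origin, dimensions) covering the impact
#' polygons plus the largest requested buffer, in a projected CRS. When the
#' polygons are geographic the UTM zone of their centroid is used; an
#' already-projected input keeps its CRS.
#'
#' @param polygons impact polygons (`baci_geoms`).
#' @param spec a [unit_spec()].
#' @param crs optional projected [bc_crs()] override.
#' @return an all-`NA` `baci_raster` with the grid geometry.
#' @export
build_grid <- function(polygons, spec, crs = NULL) {
  stopifnot(inherits(polygons, "baci_geoms"), inherits(spec, "baci_unit_spec"))
  if (length(polygons) == 0) stop("polygon set is empty")
  if (is.null(crs)) {
    crs <- if (is_projected(polygons$crs)) polygons$crs
           else utm_crs_from_centroid(polygons)
  }
  if (!is_projected(crs)) stop("grid CRS must be projected")
  polygons <- geoms_to_crs(polygons, crs)
  pad <- max(0, spec$control_from_buffer, spec$exclude_impact_buffer)
  bb <- geom_bbox(polygons) + c(-pad, -pad, pad, pad)
  if (!is.null(spec$control_from_polygon)) {
    bb2 <- geom_bbox(geoms_to_crs(spec$control_from_polygon, crs))
    bb <- c(pmin(bb[1:2], bb2[1:2]), pmax(bb[3:4], bb2[3:4]))
  }
  x0 <- bb[1]; y1 <- bb[4]
  if (!is.null(spec$round_coords)) {
    m <- 10^(-spec$round_coords)
    x0 <- round_half_away(x0, m)
    y1 <- round_half_away(y1, m)
  }
  nc <- max(1L, ceiling((bb[3] - x0) / spec$resolution - 1e-9))
  nr <- max(1L, ceiling((y1 - bb[2]) / spec$resolution - 1e-9))
  bc_raster(matrix(NA_real_, nr, nc), x0, y1, spec$resolution, crs, "units")
}

#' Label impact and candidate-control pixels
#'
#' The core unit-definition step: every grid cell whose centre falls inside
#' an impact polygon is an impact unit (value 1); cells whose centre lies in
#' the control region — within `control_from_buffer` metres of an impact
#' polygon and/or inside `control_from_polygon` — and survives all
#' exclusions (not inside an impact polygon, not inside `control_exclude`,
#' not within `exclude_impact_buffer` metres of an impact polygon) is a
#' candidate control (value 0). All remaining cells are nodata. Optional
#' seeded subsampling retains a fraction of each class, applied after all
#' exclusions; the retained count is `round(f * n)` (round half to even),
#' drawn uniformly in row-major cell order.
#'
#' @param impact_polygons intervention-site polygons (`baci_geoms`).
#' @param spec a [unit_spec()].
#' @param crs optional projected CRS override (see [build_grid()]).
#' @return a `baci_labelgrid`: a [bc_raster()] of 1 (impact) / 0 (candidate
#'   control) / `NA` (excluded), with the spec attached as attribute `spec`.
#' @examples
#' crs <- bc_crs(32735)
#' sq <- bc_polygons(list(rect_ring(0, 0, 300, 300)), crs = crs)
#' sp <- unit_spec(resolution = 60, control_from_buffer = 120, seed = 1)
#' lg <- create_control_candidates(sq, sp)
#' table(lg$values)
#' @export
create_control_candidates <- function(impact_polygons, spec, crs = NULL) {
  stopifnot(inherits(impact_polygons, "baci_geoms"),
            inherits(spec, "baci_unit_spec"))
  grid <- build_grid(impact_polygons, spec, crs)
  impact_polygons <- geoms_to_crs(impact_polygons, grid$crs)
  ctr <- cell_centres(grid)

  in_impact <- points_in_geoms(ctr, impact_polygons)
  if (!any(in_impact))
    stop("no impact pixels: no cell centre falls inside an impact polygon ",
         "(polygons smaller than one pixel?)")
  d_impact <- dist_points_geoms(ctr, impact_polygons)

  impact <- in_impact
  if (!is.null(spec$impact_inner_buffer) && spec$impact_inner_buffer > 0) {
    # distance to the polygon boundary for interior points
    d_bound <- dist_boundary(ctr, impact_polygons)
    impact <- impact & d_bound >= spec$impact_inner_buffer
    if (!any(impact)) stop("no impact pixels left after impact_inner_buffer erosion")
  }

  control <- rep(FALSE, nrow(ctr))
  if (!is.null(spec$control_from_buffer))
    control <- control | (d_impact <= spec$control_from_buffer)
  if (!is.null(spec$control_from_polygon)) {
    cfp <- geoms_to_crs(spec$control_from_polygon, grid$crs)
    control <- control | points_in_geoms(ctr, cfp)
  }
  control <- control & !in_impact
  if (!any(control)) stop("no control pixels inside the control region")
  if (!is.null(spec$control_exclude) && length(spec$control_exclude)) {
    ce <- geoms_to_crs(spec$control_exclude, grid$crs)
    control <- control & !points_in_geoms(ctr, ce)
    if (!any(control)) stop("no control pixels left after control_exclude filter")
  }
  if (!is.null(spec$exclude_impact_buffer)) {
    control <- control & d_impact >= spec$exclude_impact_buffer
    if (!any(control)) stop("no control pixels left after exclude_impact_buffer filter")
  }

  set.seed(spec$seed)
  impact <- subsample_class(impact, spec$sample_impact)
  control <- subsample_class(control, spec$sample_control)
  if (!any(impact)) stop("no impact pixels left after sample_impact subsampling")
  if (!any(control)) stop("no control pixels left after sample_control subsampling")

  lab <- rep(NA_real_, nrow(ctr))
  lab[control] <- 0
  lab[impact] <- 1
  grid$values <- matrix(lab, nrow(grid$values), ncol(grid$values), byrow = TRUE)
  structure(grid, class = c("baci_labelgrid", class(grid)), spec = spec)
}

# retain round-half-even(f * n) elements of a logical mask, uniformly at
# random; relies on the caller having seeded the RNG
subsample_class <- function(mask, f) {
  if (is.null(f) || f >= 1) return(mask)
  idx <- which(mask)
  k <- round(f * length(idx))
  keep <- sort(sample(idx, k))
  out <- rep(FALSE, length(mask))
  out[keep] <- TRUE
  out
}

# distance from points to the nearest polygon boundary segment (ignores
# inside/outside)
dist_boundary <- function(pts, g) {
  d <- rep(Inf, nrow(pts))
  for (m in g$geoms) for (r in split_rings(m)) {
    for (i in seq_len(nrow(r) - 1))
      d <- pmin(d, dist_points_segment(pts, r[i, ], r[i + 1, ]))
  }
  d
}

#' @export
print.baci_labelgrid <- function(x, ...) {
  NextMethod()
  cat("impact: ", sum(x$values == 1, na.rm = TRUE),
      "  candidate control: ", sum(x$values == 0, na.rm = TRUE),
      "  excluded: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

# row-major cell indices of labelled pixels
labelled_cells <- function(grid) {
  lab <- as.vector(t(grid$values))
  which(!is.na(lab))
}
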