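#' Terrain derivatives from a digital elevation model
#'
#' Computes slope and aspect with Horn's 3x3 finite-difference kernel, and
#' transforms the circular aspect into northness and eastness components
#' (cosine and sine of aspect), which are suitable for environmental
#' distance calculations where the raw angle is not. Edge rows/columns use
#' nearest-edge padding. Flat cells (zero gradient) get slope 0 and
#' northness = eastness = 0.
#'
#' @param dem a `baci_raster` of elevations (metres), at least 3x3 cells.
#' @param which subset of `c("slope", "aspect", "northness", "eastness")`.
#' @param grid optional `baci_labelgrid`; if given the DEM must share its
#'   geometry.
#' @return named list of `baci_raster` layers. Slope in degrees; aspect in
#'   degrees clockwise from north (direction of steepest descent), `NA` on
#'   flat cells.
#' @export
terrain_derivatives <- function(dem, which = c("slope", "northness", "eastness"),
                                grid = NULL) {
  stopifnot(inherits(dem, "baci_raster"))
  which <- match.arg(which, c("slope", "aspect", "northness", "eastness"),
                     several.ok = TRUE)
  if (!is.null(grid) && !same_grid(dem, grid))
    stop("DEM is not on the unit grid (dimensions/origin/resolution differ)")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3x3 cells")

  # nearest-edge padded shifts; p[r, c] neighbourhoods via index clamping
  up <- c(1, seq_len(nr - 1)); dn <- c(seq_len(nr - 1) + 1, nr)
  lf <- c(1, seq_len(nc - 1)); rt <- c(seq_len(nc - 1) + 1, nc)
  z1 <- z[up, lf]; z2 <- z[up, ]; z3 <- z[up, rt]
  z4 <- z[, lf];                  z6 <- z[, rt]
  z7 <- z[dn, lf]; z8 <- z[dn, ]; z9 <- z[dn, rt]

  res <- dem$res
  gx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * res)  # d z / d east
  gy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * res)  # d z / d north
  grad <- sqrt(gx^2 + gy^2)

  out <- list()
  lay <- function(v, nm) { r <- raster_template(dem, name = nm); r$values <- v; r }
  if ("slope" %in% which)
    out$slope <- lay(atan(grad) * 180 / pi, "slope")
  flat <- grad == 0
  # azimuth of steepest descent, clockwise from north
  asp <- (atan2(-gx, -gy) * 180 / pi) %% 360
  if ("aspect" %in% which) {
    a <- asp; a[flat] <- NA
    out$aspect <- lay(a, "aspect")
  }
  if ("northness" %in% which) {
    v <- cos(asp * pi / 180); v[flat] <- 0
    out$northness <- lay(v, "northness")
  }
  if ("eastness" %in% which) {
    v <- sin(asp * pi / 180); v[flat] <- 0
    out$eastness <- lay(v, "eastness")
  }
  out
}

#' Distance from each grid cell to the nearest feature
#'
#' Euclidean distance (metres, grid CRS) from every cell centre to the
#' nearest retained line/point geometry — the standard
#' distance-to-roads/settlements matching covariate. Features can be
#' filtered by an attribute class column against an ordered class
#' hierarchy: `class_filter = "track+"` keeps `"track"` and every class
#' ranked above it in `hierarchy`.
#'
#' @param grid a `baci_raster` / `baci_labelgrid` defining the cells.
#' @param features `baci_geoms` lines or points.
#' @param class_filter optional class name, with `"+"` suffix meaning "this
#'   class and above".
#' @param class_column attribute column holding the class.
#' @param hierarchy character vector of classes ordered from lowest to
#'   highest rank.
#' @return a `baci_raster` of distances at every cell (computed for the full
#'   grid; mask with the label grid as needed).
#' @export
distance_to_features <- function(grid, features, class_filter = NULL,
                                 class_column = "class",
                                 hierarchy = c("path", "track", "unclassified",
                                               "tertiary", "secondary",
                                               "primary", "trunk", "motorway")) {
  stopifnot(inherits(grid, "baci_raster"), inherits(features, "baci_geoms"))
  if (!crs_equal(grid$crs, features$crs))
    features <- geoms_to_crs(features, grid$crs)
  if (!is.null(class_filter)) {
    plus <- grepl("\\+$", class_filter)
    base <- sub("\\+$", "", class_filter)
    if (!base %in% hierarchy)
      stop("unknown feature class '", base, "' (hierarchy: ",
           paste(hierarchy, collapse = ", "), ")")
    keep_classes <- if (plus) hierarchy[seq(match(base, hierarchy), length(hierarchy))]
                    else base
    if (!class_column %in% names(features$attrs))
      stop("features have no '", class_column, "' attribute")
    features <- features[features$attrs[[class_column]] %in% keep_classes]
  }
  if (length(features) == 0)
    stop("no features left",
         if (!is.null(class_filter)) paste0(" after class filter '", class_filter, "'"))
  d <- dist_points_geoms(cell_centres(grid), features)
  r <- raster_template(grid, name = "distance")
  r$values <- matrix(d, nrow(grid$values), ncol(grid$values), byrow = TRUE)
  r
}

#' Land-cover class covariate
#'
#' Validates an integer class raster against a labelling scheme and marks it
#' as categorical. At model time the covariate is expanded to K-1 indicator
#' columns with the most frequent class as the reference level.
#'
#' @param lulc integer-valued `baci_raster` of land-cover classes.
#' @param scheme named character vector mapping class codes to labels, e.g.
#'   `c("1" = "trees", "2" = "shrub", "3" = "bare")`.
#' @return the raster with attribute `categorical = TRUE` and the scheme
#'   attached.
#' @export
encode_landcover <- function(lulc, scheme) {
  stopifnot(inherits(lulc, "baci_raster"))
  v <- lulc$values[!is.na(lulc$values)]
  if (any(v != round(v))) stop("land-cover raster must be integer-coded")
  present <- sort(unique(v))
  unknown <- setdiff(present, as.numeric(names(scheme)))
  if (length(unknown))
    stop("land-cover classes absent from scheme: ", paste(unknown, collapse = ", "))
  structure(lulc, categorical = TRUE, scheme = scheme)
}

is_categorical <- function(layer) isTRUE(attr(layer, "categorical"))

#' Collate matching covariates into a unit table
#'
#' Extracts every covariate layer at the labelled pixels of the unit grid
#' and assembles the table consumed by the matching step: one row per unit
#' with its id (row-major cell index), centre coordinates, treatment flag
#' (1 = impact, 0 = control) and one column per covariate. Layers on a
#' different grid are resampled on the fly (nearest neighbour for
#' categorical layers, bilinear for continuous). Units with any missing
#' covariate are dropped with a warning giving the count.
#'
#' @param grid a `baci_labelgrid` from [create_control_candidates()].
#' @param layers named list of `baci_raster` covariate layers (names become
#'   column names; unnamed layers use their `name` field).
#' @return a `baci_covariates` data.frame with columns `unit_id`, `x`, `y`,
#'   `treatment`, then covariates; categorical columns are factors. The
#'   names of categorical covariates are kept in attribute `categorical`.
#' @export
collate_matching_layers <- function(grid, layers) {
  stopifnot(inherits(grid, "baci_labelgrid"))
  nms <- names(layers)
  if (is.null(nms)) nms <- rep("", length(layers))
  nms[nms == ""] <- vapply(layers[nms == ""], function(l) l$name, "")
  if (anyDuplicated(nms)) stop("duplicated covariate names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))

  cells <- labelled_cells(grid)
  ctr <- cell_centres(grid)[cells, , drop = FALSE]
  lab <- as.vector(t(grid$values))[cells]
  tab <- data.frame(unit_id = cells, x = ctr[, 1], y = ctr[, 2], treatment = lab)

  cat_names <- character()
  for (k in seq_along(layers)) {
    l <- layers[[k]]
    stopifnot(inherits(l, "baci_raster"))
    if (!crs_equal(l$crs, grid$crs))
      stop("covariate '", nms[k], "' is in EPSG:", l$crs$epsg,
           " but the grid is EPSG:", grid$crs$epsg)
    if (same_grid(l, grid)) {
      v <- cell_values(l, cells)
    } else {
      v <- raster_extract(l, ctr, if (is_categorical(l)) "nearest" else "bilinear")
    }
    if (is_categorical(l)) {
      scheme <- attr(l, "scheme")
      v <- factor(as.character(v), levels = names(scheme), labels = scheme)
      cat_names <- c(cat_names, nms[k])
    }
    tab[[nms[k]]] <- v
  }

  miss <- !stats::complete.cases(tab)
  if (any(miss)) {
    warning(sum(miss), " unit(s) dropped due to missing covariate values")
    tab <- tab[!miss, , drop = FALSE]
  }
  if (!nrow(tab)) stop("all units dropped: no complete covariate rows")
  if (!all(c(0, 1) %in% tab$treatment))
    stop("both impact and control units are required after collation")
  rownames(tab) <- NULL
  structure(tab, categorical = cat_names,
            class = c("baci_covariates", "data.frame"))
}

covariate_names <- function(table) {
  setdiff(names(table), c("unit_id", "x", "y", "treatment"))
}

# model matrix of covariates only (no intercept column): continuous columns
# as-is, factors expanded to K-1 indicators against the modal reference level
covariate_matrix <- function(table, vars = covariate_names(table)) {
  cols <- list()
  for (v in vars) {
    x <- table[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- droplevels(factor(x))
      if (nlevels(x) < 2) {
        warning("covariate '", v, "' has a single level and was dropped")
        next
      }
      ref <- names(which.max(table(x)))
      x <- stats::relevel(x, ref = ref)
      mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, "_", sub("^x", "", colnames(mm)))
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  if (!length(cols)) stop("no usable covariate columns")
  do.call(cbind, cols)
}

# maps each column of covariate_matrix() back to its parent covariate
indicator_parent <- function(table, vars = covariate_names(table)) {
  X <- covariate_matrix(table, vars)
  parent <- vapply(colnames(X), function(cn) {
    hit <- vars[vapply(vars, function(v) cn == v || startsWith(cn, paste0(v, "_")), TRUE)]
    hit[which.max(nchar(hit))]
  }, "")
  parent
}

#' Variance inflation factors
#'
#' For each covariate column (categorical covariates expanded to indicator
#' columns), the VIF is `1 / (1 - R^2)` of the ordinary least-squares
#' regression of that column on all other columns plus an intercept.
#' Perfectly collinear columns get `Inf`.
#'
#' @param table a `baci_covariates` table.
#' @param threshold columns with VIF above this are flagged (default 5).
#' @return a `baci_vif` list with `vif` (named vector), `flagged`, and the
#'   threshold.
#' @examples
#' \donttest{
#' set.seed(1)
#' tb <- data.frame(unit_id = 1:50, x = 0, y = 0,
#'                  treatment = rep(0:1, 25),
#'                  a = rnorm(50), b = rnorm(50))
#' class(tb) <- c("baci_covariates", "data.frame")
#' vif(tb)$vif  # both near 1
#' }
#' @export
vif <- function(table, threshold = 5) {
  X <- covariate_matrix(table)
  if (ncol(X) < 2) stop("VIF needs at least 2 covariate columns")
  if (nrow(X) <= ncol(X) + 1) stop("need more rows than covariates + 1")
  v <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(v) <- colnames(X)
  structure(list(vif = v, flagged = names(v)[v > threshold],
                 threshold = threshold),
            class = "baci_vif")
}

#' @export
print.baci_vif <- function(x, ...) {
  cat("Variance inflation factors (threshold ", x$threshold, "):\n", sep = "")
  print(round(x$vif, 3))
  if (length(x$flagged)) cat("flagged: ", paste(x$flagged, collapse = ", "), "\n")
  if (length(x$dropped)) cat("dropped: ", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Screen covariates for multicollinearity
#'
#' Computes VIFs and, under the `"auto-drop-worst"` policy, iteratively
#' removes the covariate owning the highest-VIF column and recomputes until
#' every VIF is at or below the threshold. `"report-only"` leaves the table
#' untouched. A Pearson correlation matrix of the continuous covariates is
#' attached for inspection/plotting.
#'
#' @param table a `baci_covariates` table.
#' @param threshold VIF threshold (default 5, the conventional cut-off).
#' @param policy `"auto-drop-worst"` or `"report-only"`.
#' @return list with `table` (possibly reduced), `report` (a `baci_vif` with
#'   `dropped` recorded), and `correlation` matrix.
#' @export
test_multicollinearity <- function(table, threshold = 5,
                                   policy = c("auto-drop-worst", "report-only")) {
  policy <- match.arg(policy)
  vars <- covariate_names(table)
  dropped <- character()
  repeat {
    rep_ <- vif(table, threshold)
    if (policy == "report-only" || all(rep_$vif <= threshold)) break
    worst_col <- names(which.max(rep_$vif))
    parent <- indicator_parent(table)[[worst_col]]
    if (length(covariate_names(table)) <= 1 ||
        length(setdiff(covariate_names(table), parent)) < 1)
      stop("dropping '", parent, "' would leave no covariates")
    dropped <- c(dropped, parent)
    table[[parent]] <- NULL
    if (length(covariate_names(table)) < 2) { rep_ <- NULL; break }
  }
  if (is.null(rep_)) {
    v <- stats::setNames(1, covariate_names(table))
    rep_ <- structure(list(vif = v, flagged = character(), threshold = threshold),
                      class = "baci_vif")
  }
  rep_$dropped <- dropped
  num <- vapply(covariate_names(table), function(v) is.numeric(table[[v]]), TRUE)
  corr <- if (sum(num) >= 2)
    stats::cor(table[covariate_names(table)[num]]) else NULL
  list(table = table, report = rep_, correlation = corr)
}
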