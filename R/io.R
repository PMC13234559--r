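#' Read a vector layer from GeoJSON
#'
#' Reads Polygon/MultiPolygon/LineString/MultiLineString/Point features
#' with their properties. Standard GeoJSON is in geographic WGS84
#' coordinates; a top-level `"crs"` member of the form
#' `"urn:ogc:def:crs:EPSG::<code>"` or `"EPSG:<code>"` overrides this,
#' which is how projected layers written by [write_vector()] round-trip.
#' An optional attribute filter is evaluated over the property columns
#' (e.g. `"Planting_date == 2012 & Lifestock_exclusion == 0"`).
#'
#' @param path GeoJSON file.
#' @param filter optional filter expression string over attribute columns.
#' @return a `baci_geoms`.
#' @export
read_vector <- function(path, filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  epsg <- 4326L
  if (!is.null(gj$crs)) {
    nm <- gj$crs$properties$name %||% gj$crs
    code <- regmatches(nm, regexpr("[0-9]+$", nm))
    if (length(code)) epsg <- as.integer(code)
  }
  crs <- bc_crs(epsg)

  feats <- gj$features
  if (!length(feats)) stop("empty FeatureCollection")
  geoms <- list(); props <- list(); type <- NULL
  for (f in feats) {
    g <- f$geometry
    gt <- g$type
    this_type <- switch(gt,
      Polygon = , MultiPolygon = "polygon",
      LineString = , MultiLineString = "line",
      Point = "point",
      stop("unsupported geometry type: ", gt))
    if (is.null(type)) type <- this_type
    if (!identical(type, this_type)) stop("mixed geometry types in layer")
    coords <- switch(gt,
      Polygon = rings_to_matrix(g$coordinates),
      MultiPolygon = {
        parts <- lapply(g$coordinates, rings_to_matrix)
        join_rings(lapply(parts, split_rings) |> unlist(recursive = FALSE))
      },
      LineString = coords_to_matrix(g$coordinates),
      MultiLineString = join_rings(lapply(g$coordinates, coords_to_matrix)),
      Point = matrix(unlist(g$coordinates), 1, 2))
    geoms[[length(geoms) + 1L]] <- coords
    props[[length(props) + 1L]] <- lapply(f$properties, function(p)
      if (is.null(p)) NA else p)
  }
  attrs <- if (any(lengths(props) > 0)) {
    cols <- unique(unlist(lapply(props, names)))
    as.data.frame(lapply(stats::setNames(cols, cols), function(cn)
      unlist(lapply(props, function(p) p[[cn]] %||% NA))),
      stringsAsFactors = FALSE)
  } else data.frame(row.names = seq_along(geoms))

  out <- switch(type,
    polygon = bc_polygons(geoms, attrs, crs),
    line = bc_lines(geoms, attrs, crs),
    point = bc_points(geoms, attrs, crs))
  if (!is.null(filter)) out <- filter_features(out, filter)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coords_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("x", "y")
  m
}

rings_to_matrix <- function(rings) {
  join_rings(lapply(rings, coords_to_matrix))
}

#' Filter features by an attribute expression
#'
#' @param g a `baci_geoms`.
#' @param filter expression string over attribute columns; only attribute
#'   names, literals, comparison and logical operators are allowed.
#' @return the filtered `baci_geoms`; errors if the expression references
#'   an unknown column or matches nothing.
#' @export
filter_features <- function(g, filter) {
  expr <- str2lang(filter)
  vars <- all.vars(expr)
  unknown <- setdiff(vars, names(g$attrs))
  if (length(unknown))
    stop("unknown column(s) in filter: ", paste(unknown, collapse = ", "))
  allowed <- c("==", "!=", "<", ">", "<=", ">=", "&", "|", "&&", "||", "!",
               "(", "c", "%in%", "+", "-", "*", "/", "is.na")
  check <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% allowed) stop("disallowed function in filter: ", fn)
      for (a in as.list(e)[-1]) check(a)
    }
  }
  check(expr)
  keep <- eval(expr, g$attrs, baseenv())
  keep <- !is.na(keep) & keep
  if (!any(keep)) stop("filter '", filter, "' matched no features")
  g[keep]
}

#' Write a vector layer to GeoJSON
#'
#' Polygons/lines/points with attributes; a projected CRS is recorded in a
#' top-level `"crs"` member so [read_vector()] round-trips it.
#'
#' @param g a `baci_geoms`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_vector <- function(g, path) {
  stopifnot(inherits(g, "baci_geoms"))
  feat <- lapply(seq_along(g$geoms), function(i) {
    m <- g$geoms[[i]]
    geometry <- switch(g$type,
      polygon = list(type = "Polygon",
                     coordinates = lapply(split_rings(m), matrix_to_coords)),
      line = list(type = "LineString", coordinates = matrix_to_coords(m)),
      point = list(type = "Point", coordinates = as.numeric(m[1, ])))
    props <- as.list(g$attrs[i, , drop = FALSE])
    list(type = "Feature", properties = props, geometry = geometry)
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name", properties = list(
                name = paste0("urn:ogc:def:crs:EPSG::", g$crs$epsg))),
              features = feat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

matrix_to_coords <- function(m) {
  lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
}

#' Write/read the covariate table as CSV
#'
#' @param table a `baci_covariates`.
#' @param path CSV path.
#' @return `write_covariates` returns `path`; `read_covariates` a
#'   `baci_covariates` (categorical columns restored from a header comment).
#' @export
write_covariates <- function(table, path) {
  cats <- attr(table, "categorical")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# categorical: ", paste(cats, collapse = ",")), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  first <- readLines(path, n = 1)
  cats <- character()
  if (startsWith(first, "# categorical:")) {
    spec <- trimws(sub("# categorical:", "", first))
    if (nzchar(spec)) cats <- strsplit(spec, ",")[[1]]
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (cn in cats) tab[[cn]] <- factor(tab[[cn]])
  structure(tab, categorical = cats,
            class = c("baci_covariates", "data.frame"))
}
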