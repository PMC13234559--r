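crs35s <- bc_crs(32735)

plane_dem <- function(nr, nc, res, gx = 0, gy = 0, base = 100) {
  # z = base + gx * easting + gy * northing
  xs <- (seq_len(nc) - 0.5) * res
  ys <- ((nr:1) - 0.5) * res  # row 1 is the top (largest northing)
  z <- outer(rev(ys), xs, function(y, x) base + gx * x + gy * y)[nr:1, , drop = FALSE]
  bc_raster(z, 0, nr * res, res, crs35s, "elevation")
}

test_that("terrain derivatives recover an inclined plane's slope and aspect", {
  # north-up plane z = 0.1 * northing: slope atan(0.1), south-facing
  dem <- plane_dem(9, 9, 60, gx = 0, gy = 0.1)
  td <- terrain_derivatives(dem, c("slope", "aspect", "northness", "eastness"))
  interior <- function(m) m[2:8, 2:8]
  expect_equal(interior(td$slope$values),
               matrix(atan(0.1) * 180 / pi, 7, 7), tolerance = 1e-10)
  expect_equal(interior(td$aspect$values), matrix(180, 7, 7), tolerance = 1e-10)
  expect_equal(interior(td$northness$values), matrix(-1, 7, 7), tolerance = 1e-10)
  expect_equal(interior(td$eastness$values), matrix(0, 7, 7), tolerance = 1e-10)

  # east-up plane: aspect 270 (west-facing descent), eastness -1
  dem2 <- plane_dem(9, 9, 60, gx = 0.05, gy = 0)
  td2 <- terrain_derivatives(dem2, c("aspect", "northness", "eastness"))
  expect_equal(interior(td2$aspect$values), matrix(270, 7, 7), tolerance = 1e-10)
  expect_equal(interior(td2$eastness$values), matrix(-1, 7, 7), tolerance = 1e-10)
  expect_equal(interior(td2$northness$values), matrix(0, 7, 7), tolerance = 1e-8)
})

test_that("flat terrain yields zero slope and zero direction components", {
  dem <- plane_dem(5, 5, 60, 0, 0)
  td <- terrain_derivatives(dem, c("slope", "aspect", "northness", "eastness"))
  expect_true(all(td$slope$values == 0))
  expect_true(all(is.na(td$aspect$values)))
  expect_true(all(td$northness$values == 0))
  expect_true(all(td$eastness$values == 0))
})

test_that("northness^2 + eastness^2 is 1 on slopes, 0 on flats", {
  set.seed(21)
  z <- matrix(cumsum(rnorm(100)), 10, 10)
  dem <- bc_raster(z, 0, 600, 60, crs35s)
  td <- terrain_derivatives(dem, c("slope", "northness", "eastness"))
  n2e2 <- td$northness$values^2 + td$eastness$values^2
  sl <- td$slope$values
  expect_true(all(abs(n2e2[sl > 0] - 1) < 1e-10))
  expect_true(all(n2e2[sl == 0] == 0))
})

test_that("distance-to-features raster is exact and translation invariant", {
  g <- bc_raster(matrix(0, 5, 5), 0, 300, 60, crs35s)
  vline <- bc_lines(list(cbind(c(0, 0), c(-1e4, 1e4))),
                    attrs = data.frame(class = "track"), crs = crs35s)
  d <- distance_to_features(g, vline)
  # column j centres sit at x = (j - 0.5) * 60
  expect_equal(d$values[1, ], (seq_len(5) - 0.5) * 60)

  shift <- 12345
  g2 <- bc_raster(matrix(0, 5, 5), shift, 300 + shift, 60, crs35s)
  vline2 <- bc_lines(list(cbind(c(shift, shift), c(-1e4 + shift, 1e4 + shift))),
                     attrs = data.frame(class = "track"), crs = crs35s)
  d2 <- distance_to_features(g2, vline2)
  expect_equal(d2$values, d$values, tolerance = 1e-9)
})

test_that("road-class hierarchy filter implements 'class+' semantics", {
  g <- bc_raster(matrix(0, 3, 3), 0, 180, 60, crs35s)
  roads <- bc_lines(list(cbind(c(0, 0), c(0, 180)),
                         cbind(c(180, 180), c(0, 180)),
                         cbind(c(90, 90), c(0, 180))),
                    attrs = data.frame(class = c("path", "track", "primary")),
                    crs = crs35s)
  d_all <- distance_to_features(g, roads)
  d_trk <- distance_to_features(g, roads, class_filter = "track+")
  d_pri <- distance_to_features(g, roads, class_filter = "primary")
  # column 1 centres sit at x = 30
  expect_equal(d_all$values[, 1], rep(30, 3))   # path at x=0 still present
  expect_equal(d_trk$values[, 1], rep(60, 3))   # track+ drops it; primary at x=90
  expect_equal(d_pri$values[, 2], rep(0, 3))    # only x=90 remains; column 2 on it
  expect_equal(d_pri$values[, 1], rep(60, 3))
  expect_error(distance_to_features(g, roads, class_filter = "runway+"),
               "unknown feature class")
  expect_error(distance_to_features(g, roads[0]), "no features left")
})

test_that("land-cover encoding validates the scheme and sets the mode as reference", {
  sq <- bc_polygons(list(rect_ring(120, 120, 360, 360)), crs = crs35s)
  lg <- create_control_candidates(sq, unit_spec(resolution = 60,
                                                control_from_buffer = 180))
  nr <- nrow(lg$values); nc <- ncol(lg$values)
  m <- matrix(c(rep(1, 10), rep(3, 5), rep(2, nr * nc - 15)), nr, nc)
  lulc <- bc_raster(m, lg$xmin, lg$ymax, 60, crs35s, "landcover")
  enc <- encode_landcover(lulc, c("1" = "forest", "2" = "shrub", "3" = "bare"))
  expect_true(baciR:::is_categorical(enc))
  expect_error(encode_landcover(lulc, c("1" = "forest", "2" = "shrub")),
               "absent from scheme")

  # through collate + covariate_matrix: reference = modal class (shrub)
  tab <- collate_matching_layers(lg, list(landcover = enc))
  X <- baciR:::covariate_matrix(tab)
  expect_setequal(colnames(X), c("landcover_forest", "landcover_bare"))
})

test_that("collation shape, missing-value dropping, and resampling", {
  sq <- bc_polygons(list(rect_ring(120, 120, 360, 360)), crs = crs35s)
  lg <- create_control_candidates(sq, unit_spec(resolution = 60,
                                                control_from_buffer = 180))
  n_lab <- sum(!is.na(lg$values))
  dem <- plane_dem(nrow(lg$values), ncol(lg$values), 60, gy = 0.1)
  dem$xmin <- lg$xmin; dem$ymax <- lg$ymax
  tab <- collate_matching_layers(lg, list(elevation = dem))
  expect_equal(nrow(tab), n_lab)
  expect_named(tab, c("unit_id", "x", "y", "treatment", "elevation"))
  expect_true(all(tab$treatment %in% c(0, 1)))
  expect_false(any(duplicated(tab$unit_id)))

  # poke NA into two labelled cells -> 2 rows dropped with a warning
  dem2 <- dem
  rc <- baciR:::cell_to_rowcol(lg, tab$unit_id[1:2])
  dem2$values[rc] <- NA
  expect_warning(tab2 <- collate_matching_layers(lg, list(elevation = dem2)),
                 "2 unit")
  expect_equal(nrow(tab2), n_lab - 2)

  # constant layer at 2x resolution resamples to the same constant
  coarse <- bc_raster(matrix(7, ceiling(nrow(lg$values) / 2),
                             ceiling(ncol(lg$values) / 2)),
                      lg$xmin, lg$ymax, 120, crs35s, "const")
  tab3 <- collate_matching_layers(lg, list(const = coarse, elevation = dem))
  expect_true(all(tab3$const == 7))
  expect_equal(nrow(tab3), n_lab)

  expect_error(collate_matching_layers(lg, list(a = dem, a = dem)),
               "duplicated covariate names")
})

test_that("VIF equals 1/(1 - R^2) from an independent least-squares oracle", {
  for (seed in 1:5) {
    n <- sample(30:200, 1)
    p <- sample(2:8, 1)
    tab <- make_table(n, p, seed = 400 + seed)
    v <- vif(tab)$vif
    X <- baciR:::covariate_matrix(tab)
    want <- vapply(seq_len(ncol(X)), function(j)
      1 / (1 - oracle_r2(X[, j], X[, -j, drop = FALSE])), 0)
    expect_equal(unname(v), want, tolerance = 1e-8)
  }
})

test_that("constructed collinearity gives the closed-form VIF", {
  # orthogonal-by-construction pair: VIF exactly 1
  n <- 64
  a <- rep(c(-1, 1), n / 2); b <- rep(c(-1, -1, 1, 1), n / 4)
  tab <- make_table(n, 2, seed = 1)
  tab$v1 <- a; tab$v2 <- b
  expect_equal(unname(vif(tab)$vif), c(1, 1), tolerance = 1e-12)

  # exact linear dependence: infinite VIF, flagged
  tab$v2 <- 2 * tab$v1
  v <- vif(tab)
  expect_true(all(is.infinite(v$vif)))
  expect_setequal(v$flagged, c("v1", "v2"))

  # x2 = x1 + noise scaled to sample R^2 = 0.9 -> VIF = 10
  set.seed(7)
  x1 <- rnorm(400)
  e <- rnorm(400)
  x1 <- (x1 - mean(x1)) / sd(x1)
  e <- residuals(lm(e ~ x1)); e <- e / sd(e)  # orthogonalise exactly
  x2 <- 3 * x1 + sqrt(9 * (1 - 0.9) / 0.9) * e  # R^2 = 0.9 by construction
  tab2 <- make_table(400, 2, seed = 2)
  tab2$v1 <- x1; tab2$v2 <- x2
  expect_equal(unname(vif(tab2)$vif), c(10, 10), tolerance = 1e-6)
})

test_that("multicollinearity screening drops the worst offender until clean", {
  tab <- make_table(100, 3, seed = 9)
  out <- test_multicollinearity(tab)
  expect_identical(out$table, tab)  # already clean: no-op
  expect_length(out$report$dropped, 0)

  tab$v3 <- tab$v1 + tab$v2  # three mutually collinear
  out2 <- test_multicollinearity(tab, threshold = 5)
  expect_length(out2$report$dropped, 1)
  expect_true(all(out2$report$vif <= 5))
  expect_equal(length(baciR:::covariate_names(out2$table)), 2)

  out3 <- test_multicollinearity(tab, policy = "report-only")
  expect_identical(out3$table, tab)
  expect_true(any(is.infinite(out3$report$vif)))
  expect_true(is.matrix(out3$correlation))
})
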