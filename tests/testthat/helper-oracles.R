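# Independent oracles, deliberately written without reusing package
# internals: plain ray casting for point-in-polygon, exhaustive greedy
# matching, closed-form least squares.

# even-odd ray casting over NA-separated rings
oracle_point_in_polygon <- function(px, py, rings_matrix) {
  na_row <- is.na(rings_matrix[, 1])
  grp <- cumsum(na_row)
  inside <- FALSE
  for (g in unique(grp[!na_row])) {
    r <- rings_matrix[!na_row & grp == g, , drop = FALSE]
    n <- nrow(r)
    j <- n
    for (i in seq_len(n)) {
      xi <- r[i, 1]; yi <- r[i, 2]; xj <- r[j, 1]; yj <- r[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
  }
  inside
}

oracle_in_any_polygon <- function(px, py, geoms) {
  any(vapply(geoms$geoms, function(m) oracle_point_in_polygon(px, py, m), TRUE))
}

# min distance from a point to all segments of a geometry set (plus 0 if
# inside, for polygons)
oracle_dist_to_geoms <- function(px, py, geoms) {
  best <- Inf
  for (m in geoms$geoms) {
    na_row <- is.na(m[, 1])
    grp <- cumsum(na_row)
    for (g in unique(grp[!na_row])) {
      r <- m[!na_row & grp == g, , drop = FALSE]
      n <- nrow(r)
      if (n == 1) {
        best <- min(best, sqrt((px - r[1, 1])^2 + (py - r[1, 2])^2))
        next
      }
      for (i in seq_len(n - 1)) {
        ax <- r[i, 1]; ay <- r[i, 2]; bx <- r[i + 1, 1]; by <- r[i + 1, 2]
        vx <- bx - ax; vy <- by - ay
        L2 <- vx^2 + vy^2
        t <- if (L2 == 0) 0 else
          max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2))
        best <- min(best, sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2))
      }
    }
  }
  if (geoms$type == "polygon" && oracle_in_any_polygon(px, py, geoms)) 0 else best
}

# brute-force greedy sequential nearest-neighbour matcher: impact units in
# the order given, each taking its full ratio of nearest eligible controls,
# distance ties broken by lowest control id
oracle_greedy_match <- function(impact_ids, impact_scores,
                                control_ids, control_scores,
                                ratio, replace, caliper_abs = NULL) {
  avail <- rep(TRUE, length(control_ids))
  pairs <- NULL
  for (k in seq_along(impact_ids)) {
    d <- abs(impact_scores[k] - control_scores)
    elig <- which(avail & (if (is.null(caliper_abs)) TRUE else d <= caliper_abs))
    if (!length(elig)) next
    ord <- elig[order(d[elig], control_ids[elig])]
    take <- ord[seq_len(min(ratio, length(ord)))]
    if (!replace) avail[take] <- FALSE
    pairs <- rbind(pairs, data.frame(impact_id = impact_ids[k],
                                     control_id = control_ids[take],
                                     rank = seq_along(take),
                                     distance = d[take]))
  }
  pairs
}

# closed-form OLS slope of v on t
oracle_ols_slope <- function(t, v) {
  ok <- !is.na(v)
  t <- t[ok]; v <- v[ok]
  sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
}

# R^2 of y on X via QR least squares, independent of the vif() path
oracle_r2 <- function(y, X) {
  fit <- qr.coef(qr(cbind(1, X)), y)
  res <- y - cbind(1, X) %*% fit
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# small covariate table builder
make_table <- function(n, p, seed, treat_frac = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  tab <- data.frame(unit_id = seq_len(n), x = 0, y = 0,
                    treatment = rbinom(n, 1, treat_frac))
  # guarantee both classes
  tab$treatment[1] <- 1; tab$treatment[2] <- 0
  tab <- cbind(tab, as.data.frame(X))
  structure(tab, class = c("baci_covariates", "data.frame"))
}
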