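#' BACI difference-in-difference contrast
#'
#' For each observable, computes the before-after-control-impact contrast
#' `(mu_CA - mu_CB) - (mu_IA - mu_IB)`, where `mu_IB`/`mu_IA` are an impact
#' unit's own before/after values and `mu_CB`/`mu_CA` are the
#' weighted means over its matched controls. One contrast is computed per
#' impact unit; the overall contrast is their unweighted mean and its
#' significance is a two-sided one-sample t-test of the per-impact-unit
#' contrasts against zero (df = number of matched impact units with
#' complete data minus 1). A Wilcoxon signed-rank p-value is reported
#' alongside as a distribution-free companion. Under this sign convention a
#' *gain* at impact sites relative to control appears as a *negative*
#' contrast.
#'
#' @param matches a `baci_match`.
#' @param before,after observables for the before/after periods: a
#'   `baci_tsmetrics`, a named list of `baci_raster` layers, or a single
#'   `baci_raster`. `before` and `after` must provide the same observables.
#' @param observables optional subset of observable names (default: all
#'   shared numeric layers, e.g. `mean` and `trend`).
#' @param flip_sign report impact-minus-control instead (default `FALSE`,
#'   the conventional control-minus-impact form).
#' @return a `baci_result`: data.frame `summary` (observable, contrast,
#'   t_statistic, df, p_value, p_wilcoxon, n_impact, n_excluded) and
#'   `per_impact` (impact_id x observable contrast matrix), plus the grid.
#' @examples
#' # single impact unit, one control, hand-set means
#' # before: control 0.30, impact 0.30; after: control 0.35, impact 0.50
#' # contrast = (0.35 - 0.30) - (0.50 - 0.30) = -0.15
#' @export
baci_contrast <- function(matches, before, after, observables = NULL,
                          flip_sign = FALSE) {
  stopifnot(inherits(matches, "baci_match"))
  bl <- observable_layers(before)
  al <- observable_layers(after)
  shared <- intersect(names(bl), names(al))
  if (!is.null(observables)) shared <- intersect(shared, observables)
  if (!length(shared)) stop("before and after share no observable layers")

  pairs <- matches$pairs
  if (!nrow(pairs)) stop("match result has no pairs")
  pw <- match_pair_weights(matches)
  imp_ids <- sort(unique(pairs$impact_id))

  grid <- infer_grid(bl, al, matches)
  per_impact <- matrix(NA_real_, length(imp_ids), length(shared),
                       dimnames = list(imp_ids, shared))
  summ <- list()
  for (obs in shared) {
    vb <- layer_values_by_unit(bl[[obs]], grid)
    va <- layer_values_by_unit(al[[obs]], grid)
    n_excl <- 0L
    for (k in seq_along(imp_ids)) {
      i <- imp_ids[k]
      rows <- which(pairs$impact_id == i)
      cids <- pairs$control_id[rows]
      w <- pw[rows]
      mu_IB <- vb[as.character(i)]; mu_IA <- va[as.character(i)]
      cb <- vb[as.character(cids)]; ca <- va[as.character(cids)]
      ok <- !is.na(cb) & !is.na(ca)
      if (is.na(mu_IB) || is.na(mu_IA) || !any(ok)) { n_excl <- n_excl + 1L; next }
      mu_CB <- sum(w[ok] * cb[ok]) / sum(w[ok])
      mu_CA <- sum(w[ok] * ca[ok]) / sum(w[ok])
      per_impact[k, obs] <- (mu_CA - mu_CB) - (mu_IA - mu_IB)
    }
    ci <- per_impact[, obs]
    ci <- ci[!is.na(ci)]
    if (flip_sign) { ci <- -ci; per_impact[, obs] <- -per_impact[, obs] }
    n <- length(ci)
    contrast <- mean(ci)
    if (n >= 2 && stats::sd(ci) > 0) {
      tt <- stats::t.test(ci, mu = 0)
      tstat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
      pw_ <- tryCatch(suppressWarnings(
        stats::wilcox.test(ci, mu = 0)$p.value), error = function(e) NA_real_)
    } else if (n >= 2) {
      # zero variance: degenerate t-test
      tstat <- if (contrast == 0) 0 else sign(contrast) * Inf
      df <- n - 1; p <- if (contrast == 0) 1 else 0; pw_ <- NA_real_
      warning("zero variance in per-impact contrasts for '", obs,
              "'; p-value is degenerate")
    } else {
      tstat <- NA_real_; df <- NA_real_; p <- NA_real_; pw_ <- NA_real_
      warning("fewer than 2 impact units with complete data for '", obs,
              "'; p-value not computed")
    }
    summ[[obs]] <- data.frame(observable = obs, contrast = contrast,
                              t_statistic = tstat, df = df, p_value = p,
                              p_wilcoxon = pw_, n_impact = n,
                              n_excluded = n_excl)
  }
  structure(list(summary = do.call(rbind, summ), per_impact = per_impact,
                 grid = grid, flip_sign = flip_sign),
            class = "baci_result")
}

observable_layers <- function(x) {
  if (inherits(x, "baci_tsmetrics"))
    return(Filter(function(l) l$name != "n_years",
                  x[intersect(names(x), c("mean", "trend", "intercept"))]))
  if (inherits(x, "baci_raster")) return(stats::setNames(list(x), x$name))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "baci_raster"))) return(x)
  if (is.data.frame(x)) return(x)  # unit_id-keyed table handled downstream
  stop("cannot interpret observables: expected baci_tsmetrics, baci_raster, ",
       "a named list of rasters, or a unit table")
}

infer_grid <- function(bl, al, matches) {
  for (l in c(bl, al)) if (inherits(l, "baci_raster")) return(l)
  if (inherits(matches$table, "data.frame")) return(NULL)
  NULL
}

# named vector of observable values keyed by unit id (row-major cell index)
layer_values_by_unit <- function(layer, grid) {
  if (inherits(layer, "baci_raster")) {
    v <- as.vector(t(layer$values))
    return(stats::setNames(v, seq_along(v)))
  }
  stop("observable layer must be a baci_raster")
}

#' @export
print.baci_result <- function(x, ...) {
  cat("BACI contrast (", if (x$flip_sign) "impact - control"
      else "control - impact", " convention):\n", sep = "")
  s <- x$summary
  s$contrast <- signif(s$contrast, 4)
  s$t_statistic <- signif(s$t_statistic, 4)
  s$p_value <- signif(s$p_value, 3)
  s$p_wilcoxon <- signif(s$p_wilcoxon, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Spatialise per-impact-unit contrasts
#'
#' Writes each impact unit's contrast into its grid cell (one contrast band
#' per observable, `NA` elsewhere) together with a constant band holding
#' the overall p-value of that observable, for visual inspection of spatial
#' patterns of impact.
#'
#' @param result a `baci_result`.
#' @param grid the unit grid (defaults to the grid carried by the result).
#' @return named list of `baci_raster` layers
#'   (`contrast_<obs>`, `p_value_<obs>` per observable).
#' @export
spatialise_contrast <- function(result, grid = result$grid) {
  stopifnot(inherits(result, "baci_result"))
  if (is.null(grid)) stop("no grid available to spatialise onto")
  out <- list()
  ids <- as.integer(rownames(result$per_impact))
  for (obs in colnames(result$per_impact)) {
    r <- raster_template(grid, name = paste0("contrast_", obs))
    ci <- result$per_impact[, obs]
    ok <- !is.na(ci)
    r <- `cell_values<-`(r, ids[ok], ci[ok])
    out[[r$name]] <- r
    p <- result$summary$p_value[result$summary$observable == obs]
    pr <- raster_template(grid, values = p, name = paste0("p_value_", obs))
    out[[pr$name]] <- pr
  }
  out
}
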