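#' Propensity-score distance model
#'
#' Fits a maximum-likelihood logistic regression of the treatment flag on
#' the covariates (categorical covariates as indicator columns, intercept
#' included). The matching step operates on the linear predictor (logit of
#' the propensity score), which spreads scores near 0 and 1 and is the
#' conventional scale for nearest-neighbour propensity matching.
#'
#' @param table a `baci_covariates` table.
#' @return a `baci_distance_model` with `kind = "propensity"`, the fitted
#'   `coefficients`, per-unit `propensity` (probability scale), `score`
#'   (logit scale) aligned with `table$unit_id`, and the `glm` fit.
#' @export
fit_propensity <- function(table) {
  X <- covariate_matrix(table)
  y <- table$treatment
  if (length(unique(y)) < 2) stop("both treatment classes are required")
  df <- data.frame(..y = y, X, check.names = FALSE)
  fit <- withCallingHandlers(
    stats::glm(..y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      # both glm.fit conditions are re-diagnosed below (separation /
      # non-convergence errors), so the raw warnings are redundant
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  eta <- as.numeric(fit$linear.predictors)
  p <- as.numeric(fit$fitted.values)
  if (max(p[y == 0]) < min(p[y == 1]) && max(abs(eta)) > 20)
    stop("perfect separation of treatment by covariates; review the ",
         "covariate set before matching")
  if (!fit$converged)
    stop("propensity model did not converge after ", fit$iter, " iterations")
  structure(list(kind = "propensity", coefficients = stats::coef(fit),
                 propensity = p, score = eta, unit_id = table$unit_id,
                 fit = fit),
            class = "baci_distance_model")
}

#' Mahalanobis covariate distances
#'
#' Pairwise Mahalanobis distance between every impact and every control
#' unit: `d(i, c) = sqrt((x_i - x_c)' S^-1 (x_i - x_c))` with `S` the
#' covariance of the covariates pooled over all units. Near-singular `S`
#' (condition number above 1e12) is ridge-regularised by adding
#' `1e-10 * trace(S)/p` to the diagonal.
#'
#' @param table a `baci_covariates` table.
#' @return a `baci_distance_model` with `kind = "mahalanobis"` and a
#'   `distance` matrix (rows = impact units, columns = control units,
#'   dimnames = unit ids).
#' @export
mahalanobis_distances <- function(table) {
  X <- covariate_matrix(table)
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e12)
    diag(S) <- diag(S) + 1e-10 * sum(diag(S)) / ncol(S)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("covariate covariance is singular even after regularisation"))
  ii <- which(table$treatment == 1); cc <- which(table$treatment == 0)
  D <- matrix(0, length(ii), length(cc),
              dimnames = list(table$unit_id[ii], table$unit_id[cc]))
  Xi <- X[ii, , drop = FALSE]; Xc <- X[cc, , drop = FALSE]
  for (k in seq_along(ii)) {
    dx <- sweep(Xc, 2, Xi[k, ])
    D[k, ] <- sqrt(pmax(0, rowSums((dx %*% Sinv) * dx)))
  }
  structure(list(kind = "mahalanobis", covariance = S, distance = D,
                 unit_id = table$unit_id),
            class = "baci_distance_model")
}

#' Greedy nearest-neighbour matching
#'
#' Assigns to each impact unit up to `ratio` nearest control units under the
#' distance model: absolute difference in logit propensity scores for a
#' propensity model, or the Mahalanobis matrix entry. Impact units are
#' processed sequentially; each takes its full `ratio` of nearest eligible
#' controls before the next is considered. Without replacement, assigned
#' controls leave the pool. A caliper discards pairs beyond the threshold;
#' for propensity models the caliper is expressed in standard deviations of
#' the logit scores (over all units). Ties in distance are broken by the
#' lowest control unit id.
#'
#' @param table a `baci_covariates` table.
#' @param model a `baci_distance_model`; default fits [fit_propensity()].
#' @param ratio controls per impact unit (>= 1).
#' @param replace may a control serve several impact units?
#' @param caliper optional maximum distance (see above for units), or `NULL`.
#' @param order processing order of impact units: `"extremity"` (hardest to
#'   match first: descending distance of the unit's score from the control
#'   mean; propensity models only, falls back to `"data"` otherwise),
#'   `"data"`, or `"random"` (seeded).
#' @param seed integer seed used when `order = "random"`.
#' @return a `baci_match` with `pairs` (data.frame impact_id, control_id,
#'   rank, distance, weight), `weights` (per matched control: times used),
#'   `unmatched_impact`, the `model` and the matching `spec`.
#' @export
match_nearest <- function(table, model = fit_propensity(table), ratio = 1,
                          replace = FALSE, caliper = NULL,
                          order = c("extremity", "data", "random"), seed = 1L) {
  order <- match.arg(order)
  stopifnot(ratio >= 1, ratio == round(ratio))
  ii <- which(table$treatment == 1); cc <- which(table$treatment == 0)
  impact_ids <- table$unit_id[ii]; control_ids <- table$unit_id[cc]
  if (!length(ii) || !length(cc)) stop("both impact and control units required")

  cal_abs <- NULL
  if (model$kind == "propensity") {
    s <- model$score
    si <- s[match(impact_ids, model$unit_id)]
    sc <- s[match(control_ids, model$unit_id)]
    distfun <- function(k) abs(si[k] - sc)
    if (!is.null(caliper)) cal_abs <- caliper * stats::sd(s)
    ext <- abs(si - mean(sc))
  } else {
    D <- model$distance[as.character(impact_ids), as.character(control_ids),
                        drop = FALSE]
    distfun <- function(k) D[k, ]
    if (!is.null(caliper)) cal_abs <- caliper
    ext <- NULL
  }

  if (!replace && is.null(caliper) && length(cc) < ratio * length(ii))
    stop("not enough controls for ratio=", ratio, " without replacement (",
         length(cc), " < ", ratio * length(ii), ")")

  ord <- switch(order,
    extremity = if (is.null(ext)) seq_along(ii) else base::order(-ext, impact_ids),
    data = seq_along(ii),
    random = { set.seed(seed); sample(seq_along(ii)) })

  avail <- rep(TRUE, length(cc))
  pairs <- vector("list", length(ii))
  unmatched <- integer()
  for (k in ord) {
    d <- distfun(k)
    elig <- avail & (if (is.null(cal_abs)) TRUE else d <= cal_abs)
    idx <- which(elig)
    if (!length(idx)) { unmatched <- c(unmatched, impact_ids[k]); next }
    take <- idx[base::order(d[idx], control_ids[idx])][seq_len(min(ratio, length(idx)))]
    if (!replace) avail[take] <- FALSE
    pairs[[k]] <- data.frame(impact_id = impact_ids[k],
                             control_id = control_ids[take],
                             rank = seq_along(take),
                             distance = d[take])
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    warning("caliper excluded every potential pair: no impact unit matched")
    pairs <- data.frame(impact_id = integer(), control_id = integer(),
                        rank = integer(), distance = numeric())
  }
  pairs <- pairs[base::order(pairs$impact_id, pairs$rank), , drop = FALSE]
  rownames(pairs) <- NULL
  w <- table(pairs$control_id)
  weights <- stats::setNames(as.integer(w), names(w))
  structure(list(pairs = pairs, weights = weights, model = model,
                 spec = list(ratio = ratio, replace = replace,
                             caliper = caliper,
                             caliper_scale = if (model$kind == "propensity")
                               "sd of logit propensity" else "mahalanobis",
                             order = order, seed = seed),
                 unmatched_impact = sort(unmatched),
                 table = table),
            class = "baci_match")
}

#' Exact matching on categorical covariates
#'
#' Matches each impact unit to every control unit sharing its exact
#' combination of the given covariates; the k controls of a stratum each
#' carry weight 1/k. Impact units in strata without controls are reported
#' unmatched.
#'
#' @param table a `baci_covariates` table.
#' @param vars covariate names to match on exactly.
#' @return a `baci_match` (pairs carry a `weight` column of 1/k).
#' @export
match_exact <- function(table, vars) {
  stopifnot(all(vars %in% covariate_names(table)))
  key <- interaction(table[vars], drop = TRUE)
  ii <- which(table$treatment == 1); cc <- which(table$treatment == 0)
  pairs <- list(); unmatched <- integer()
  for (k in ii) {
    mates <- cc[key[cc] == key[k]]
    if (!length(mates)) { unmatched <- c(unmatched, table$unit_id[k]); next }
    pairs[[length(pairs) + 1L]] <- data.frame(
      impact_id = table$unit_id[k],
      control_id = table$unit_id[mates],
      rank = seq_along(mates), distance = 0,
      weight = 1 / length(mates))
  }
  if (!length(pairs)) stop("no stratum contains both impact and control units")
  pairs <- do.call(rbind, pairs)
  w <- tapply(pairs$weight, pairs$control_id, sum)
  structure(list(pairs = pairs,
                 weights = stats::setNames(as.numeric(w), names(w)),
                 model = list(kind = "exact", vars = vars),
                 spec = list(ratio = NA, replace = TRUE, caliper = NULL,
                             caliper_scale = NA, order = NA, seed = NA),
                 unmatched_impact = sort(unmatched),
                 table = table),
            class = "baci_match")
}

#' @export
print.baci_match <- function(x, ...) {
  cat("<baci_match> ", length(unique(x$pairs$impact_id)), " impact unit(s), ",
      nrow(x$pairs), " pair(s), ", length(x$unmatched_impact),
      " unmatched\n", sep = "")
  invisible(x)
}

match_pair_weights <- function(match) {
  if ("weight" %in% names(match$pairs)) match$pairs$weight
  else rep(1, nrow(match$pairs))
}

#' Covariate balance before and after matching
#'
#' Standardised mean differences (SMD) of every covariate column and of the
#' distance score, before matching (impact vs all candidate controls) and
#' after (impact vs matched controls weighted by match weights). Both use
#' the same pooled pre-matching standard deviation in the denominator, so
#' before/after values are directly comparable (Love-plot convention). Also
#' reports variance ratios, the control selection-rate table (how often each
#' control was reused), and 30-bin overlap histograms of the distance score.
#'
#' @param match a `baci_match`.
#' @param table the covariate table (defaults to the one stored in the
#'   match).
#' @return a `baci_balance` with `smd` (data.frame covariate, smd_before,
#'   smd_after, var_ratio_before, var_ratio_after), `reuse`, `histograms`.
#' @export
balance_evaluation <- function(match, table = match$table) {
  if (!nrow(match$pairs)) stop("match has no pairs")
  X <- covariate_matrix(table)
  score <- if (identical(match$model$kind, "propensity"))
    match$model$score[match(table$unit_id, match$model$unit_id)] else NULL
  if (!is.null(score)) X <- cbind(`distance score` = score, X)

  ti <- table$treatment == 1
  id <- table$unit_id
  m_imp <- unique(match$pairs$impact_id)
  pw <- match_pair_weights(match)
  cw <- tapply(pw, match$pairs$control_id, sum)
  c_ids <- as.numeric(names(cw)); cwv <- as.numeric(cw)

  wmean <- function(v, w) sum(v * w) / sum(w)
  wvar <- function(v, w) {
    mu <- wmean(v, w); sum(w * (v - mu)^2) / sum(w) * length(w) / max(1, length(w) - 1)
  }
  rows <- lapply(colnames(X), function(cn) {
    v <- X[, cn]
    vi <- v[ti]; vc <- v[!ti]
    sd_pool <- sqrt((stats::var(vi) + stats::var(vc)) / 2)
    vi_m <- v[id %in% m_imp & ti]
    vc_m <- v[match(c_ids, id)]
    smd_b <- if (sd_pool == 0) NA_real_ else (mean(vi) - mean(vc)) / sd_pool
    smd_a <- if (sd_pool == 0) NA_real_ else
      (mean(vi_m) - wmean(vc_m, cwv)) / sd_pool
    vr_b <- if (stats::var(vc) == 0) NA_real_ else stats::var(vi) / stats::var(vc)
    vr_a <- wv <- wvar(vc_m, cwv)
    vr_a <- if (length(vi_m) < 2 || wv == 0) NA_real_ else stats::var(vi_m) / wv
    data.frame(covariate = cn, smd_before = smd_b, smd_after = smd_a,
               var_ratio_before = vr_b, var_ratio_after = vr_a)
  })
  smd <- do.call(rbind, rows)

  reuse <- sort(match$weights, decreasing = TRUE)
  histograms <- NULL
  if (!is.null(score)) {
    brks <- seq(min(score), max(score), length.out = 31)
    if (brks[1] == brks[31]) brks <- brks[1] + seq(-1, 1, length.out = 31) * 1e-8
    histograms <- list(
      breaks = brks,
      impact = graphics::hist(score[ti], breaks = brks, plot = FALSE)$counts,
      control = graphics::hist(score[!ti], breaks = brks, plot = FALSE)$counts)
  }
  structure(list(smd = smd, reuse = reuse, histograms = histograms,
                 n_unmatched = length(match$unmatched_impact)),
            class = "baci_balance")
}

#' @export
print.baci_balance <- function(x, ...) {
  cat("Covariate balance (standardised mean differences):\n")
  print(transform(x$smd, smd_before = round(smd_before, 3),
                  smd_after = round(smd_after, 3)),
        row.names = FALSE)
  cat(x$n_unmatched, "impact unit(s) unmatched\n")
  invisible(x)
}

#' Love plot of standardised mean differences
#'
#' @param x a `baci_balance`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.baci_balance <- function(x, ...) {
  s <- x$smd
  n <- nrow(s)
  graphics::plot(NA, xlim = range(c(s$smd_before, s$smd_after, 0), na.rm = TRUE),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Standardised mean difference", ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = s$covariate, las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, lty = 2, col = "grey")
  graphics::points(s$smd_before, seq_len(n), pch = 1)
  graphics::points(s$smd_after, seq_len(n), pch = 16)
  graphics::legend("topright", pch = c(1, 16),
                   legend = c("before matching", "after matching"), bty = "n")
  invisible(x)
}
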