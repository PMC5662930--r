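#' Residual series of a fitted segmentation
#'
#' Subtracts the piecewise linear function of `seg` from the measured cell
#' lengths. Within each segment the residual mean is zero (OLS normal
#' equations).
#'
#' @param profile the [cell_profile()] the segmentation was fitted on.
#' @param seg the fitted `segmentation`.
#' @return Numeric vector of residuals (um) at the same positions.
#' @export
residual_series <- function(profile, seg) {
  stopifnot(inherits(profile, "cell_profile"), inherits(seg, "segmentation"))
  if (seg$T != profile$T)
    stop("segmentation was fitted on a profile with a different cell count")
  res <- numeric(profile$T)
  for (f in seg$fits) {
    idx <- f$start:f$end
    res[idx] <- profile$lengths[idx] -
      (f$intercept + f$slope * profile$positions[idx])
  }
  res
}

#' Gaussian change-in-the-variance model for a residual series
#'
#' Between two successive change points the mean is constant (the global
#' mean of the series) and the variance is constant; the number of variance
#' regimes is selected by the same slope heuristic, and the optimal
#' segmentation, change-point posteriors and uncertainty intervals reuse the
#' generic dynamic-programming machinery.
#'
#' @param series numeric series (typically residuals of a piecewise linear
#'   fit).
#' @param J_max largest number of variance regimes considered (default 5).
#' @param min_len minimum regime length (cells).
#' @param positions optional axial positions (um) used to report limits on
#'   the micrometre scale; limit positions use the first cell of the
#'   shootward regime, as in the linear model.
#' @param coverage coverage of the change-point uncertainty intervals.
#' @param var_floor variance floor (um^2).
#' @return An object of class `variance_segmentation` with the global mean
#'   `alpha`, per-regime variances, change points, limit positions and
#'   uncertainty intervals, plus the `model_selection` trace in `$selection`.
#' @export
fit_variance_segmentation <- function(series, J_max = 5L, min_len = 4L,
                                      positions = NULL, coverage = 0.95,
                                      var_floor = 1e-6) {
  x <- as.numeric(series)
  if (length(x) < min_len)
    stop("series shorter than the minimum segment length")
  costs <- .variance_costs(x, min_len, var_floor, positions = positions)
  sel <- .slope_heuristic_engine(costs, as.integer(J_max), "variance")
  J <- sel$J_star
  cps <- .optimal_cps(costs, J)
  starts <- c(1L, cps)
  ends <- c(cps - 1L, length(x))
  sigma2 <- mapply(function(u, v) {
    max(mean((x[u:v] - costs$alpha)^2), var_floor)
  }, starts, ends)
  ll <- sum(mapply(function(u, v, s2) {
    rss <- sum((x[u:v] - costs$alpha)^2)
    n <- v - u + 1
    -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
  }, starts, ends, sigma2))
  eng <- .posterior_engine(costs, J)
  intervals <- lapply(seq_along(cps), function(j)
    uncertainty_interval(eng$changepoints[[j]], cps[j], coverage,
                         positions = positions))
  structure(list(J = J, change_points = cps,
                 limit_positions = if (!is.null(positions)) positions[cps],
                 alpha = costs$alpha, sigma2 = sigma2,
                 log_likelihood = ll,
                 log_evidence = eng$log_evidence,
                 changepoint_posteriors = eng$changepoints,
                 uncertainty_intervals = intervals,
                 selection = sel, T = length(x), min_len = as.integer(min_len)),
            class = "variance_segmentation")
}

#' @export
print.variance_segmentation <- function(x, ...) {
  cat("<variance_segmentation> J = ", x$J, ", alpha = ",
      format(x$alpha, digits = 3), ", sd = ",
      paste(format(sqrt(x$sigma2), digits = 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Do two uncertainty intervals co-localize?
#'
#' Closed-interval overlap test used to compare the uncertainty interval of a
#' limit under the piecewise linear model with the interval of the matching
#' change point of the change-in-variance model fitted to the residuals.
#' Touching endpoints count as overlap.
#'
#' @param interval_a,interval_b numeric length-2 vectors `c(lo, hi)` in um.
#' @return `TRUE` if the closed intervals intersect.
#' @export
colocalized <- function(interval_a, interval_b) {
  .check_interval(interval_a)
  .check_interval(interval_b)
  max(interval_a[1], interval_b[1]) <= min(interval_a[2], interval_b[2])
}

.check_interval <- function(x) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop("malformed interval: expected numeric c(lo, hi) with lo <= hi")
  invisible(x)
}

#' Residual analysis of a zoned root
#'
#' Extracts the residual series of the retained segmentation, fits the
#' change-in-variance model to it, and tests co-localization of each linear
#' limit's uncertainty interval with the nearest variance-model limit
#' interval.
#'
#' @param profile the [cell_profile()].
#' @param zoned a `zoned_root` from [select_final_segmentation()].
#' @param J_max,min_len,coverage,var_floor passed to
#'   [fit_variance_segmentation()].
#' @return A list with the `variance_segmentation` fit and a per-limit data
#'   frame (`limit_um`, variance-model interval, `colocalized`).
#' @export
residual_analysis <- function(profile, zoned, J_max = 5L, min_len = 4L,
                              coverage = 0.95, var_floor = 1e-6) {
  stopifnot(inherits(zoned, "zoned_root"))
  res <- residual_series(profile, zoned$segmentation)
  vfit <- fit_variance_segmentation(res, J_max = J_max, min_len = min_len,
                                    positions = profile$positions,
                                    coverage = coverage,
                                    var_floor = var_floor)
  lims <- zoned$limits
  if (nrow(lims) == 0L || length(vfit$change_points) == 0L) {
    tab <- data.frame(limit_um = lims$position_um,
                      variance_lo_um = NA_real_, variance_hi_um = NA_real_,
                      colocalized = NA)
  } else {
    tab <- do.call(rbind, lapply(seq_len(nrow(lims)), function(i) {
      # compare with the nearest variance-model limit
      k <- which.min(abs(vfit$limit_positions - lims$position_um[i]))
      ui <- vfit$uncertainty_intervals[[k]]
      data.frame(limit_um = lims$position_um[i],
                 variance_lo_um = ui$lo_um, variance_hi_um = ui$hi_um,
                 colocalized = colocalized(c(lims$lo_um[i], lims$hi_um[i]),
                                           c(ui$lo_um, ui$hi_um)))
    }))
  }
  list(variance_fit = vfit, colocalization = tab)
}
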