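#' Gaussian linear fit of one candidate segment
#'
#' Ordinary least squares of cell length on axial position over the cell-index
#' range `u..v`, with maximum-likelihood residual variance (RSS/n, floored at
#' `var_floor` to keep log-likelihoods finite on collinear stretches).
#'
#' @param profile a [cell_profile()].
#' @param u,v inclusive cell indices, `1 <= u <= v <= T`.
#' @param min_len minimum admissible segment length (cells). Default 4: three
#'   cells are needed for a positive residual variance and a fourth adds
#'   stability.
#' @param var_floor variance floor (um^2) applied to the ML variance.
#' @return An object of class `segment_fit` with elements `start`, `end`,
#'   `n`, `intercept` (um), `slope` (um per um; multiply by 1000 for the
#'   reported um/mm scale), `slope_per_mm`, `residual_sd` (um), `rss` (um^2),
#'   `correlation`, `slope_se`, `log_likelihood`, `x_mean`, `sxx` and
#'   `degenerate` (TRUE when RSS is 0 and the variance was floored).
#' @export
fit_segment <- function(profile, u, v, min_len = 4L, var_floor = 1e-6) {
  stopifnot(inherits(profile, "cell_profile"))
  u <- as.integer(u); v <- as.integer(v)
  T <- profile$T
  if (u < 1L || v > T || u > v) stop("invalid segment bounds")
  n <- v - u + 1L
  if (n < min_len)
    stop("infeasible segment: length ", n, " below minimum ", min_len)
  p <- profile$positions[u:v]
  x <- profile$lengths[u:v]
  sxx_p <- sum((p - mean(p))^2)
  if (sxx_p <= 1e-12)
    stop("slope undefined: positions within the segment are all equal")
  sxy <- sum((p - mean(p)) * (x - mean(x)))
  sxx_x <- sum((x - mean(x))^2)
  slope <- sxy / sxx_p
  intercept <- mean(x) - slope * mean(p)
  rss <- max(sxx_x - sxy^2 / sxx_p, 0)
  if (rss < 1e-12 * max(sxx_x, 1)) rss <- 0
  degenerate <- rss / n < var_floor
  s2 <- max(rss / n, var_floor)
  ll <- -n / 2 * log(2 * pi * s2) - rss / (2 * s2)
  corr <- if (sxx_x > 0) sxy / sqrt(sxx_p * sxx_x) else NA_real_
  slope_se <- if (n > 2) sqrt((rss / (n - 2)) / sxx_p) else NA_real_
  structure(list(start = u, end = v, n = n,
                 intercept = intercept, slope = slope,
                 slope_per_mm = slope * 1000,
                 residual_sd = sqrt(s2), rss = rss,
                 correlation = corr, slope_se = slope_se,
                 log_likelihood = ll,
                 x_mean = mean(p), sxx = sxx_p,
                 degenerate = degenerate),
            class = "segment_fit")
}

# Assemble a segmentation object for the linear family from change points
# (cps = index of the first cell of each later segment).
.build_segmentation <- function(profile, cps, min_len, var_floor,
                                log_likelihood = NULL) {
  T <- profile$T
  starts <- c(1L, cps)
  ends <- c(cps - 1L, T)
  fits <- mapply(function(u, v) fit_segment(profile, u, v, min_len, var_floor),
                 starts, ends, SIMPLIFY = FALSE)
  ll <- sum(vapply(fits, `[[`, numeric(1), "log_likelihood"))
  structure(list(J = length(starts),
                 change_points = as.integer(cps),
                 fits = fits,
                 log_likelihood = if (is.null(log_likelihood)) ll else log_likelihood,
                 limit_positions = profile$positions[cps],
                 span = range(profile$positions),
                 T = T, min_len = as.integer(min_len),
                 family = "linear", root_id = profile$root_id),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation> ", x$root_id, ": J = ", x$J, ", log-likelihood = ",
      format(x$log_likelihood, digits = 6), "\n", sep = "")
  if (x$J > 1)
    cat("  change points at cells ", paste(x$change_points, collapse = ", "),
        " (", paste(round(x$limit_positions, 1), collapse = ", "), " um)\n",
        sep = "")
  invisible(x)
}

#' Optimal segmentation into J zones by dynamic programming
#'
#' Maximizes the total heteroscedastic piecewise-linear log-likelihood over
#' all segmentations of the profile into `J` contiguous segments of at least
#' `min_len` cells. Ties are broken toward the lexicographically smallest
#' change-point vector. The change point `tau_j` is the index of the first
#' cell of the shootward segment and the reported limit position (um) is that
#' cell's position.
#'
#' @inheritParams fit_segment
#' @param J number of zones (segments).
#' @return A `segmentation` object (see [fit_segment()] for the per-segment
#'   fields).
#' @export
optimal_segmentation <- function(profile, J, min_len = 4L, var_floor = 1e-6) {
  costs <- .linear_costs(profile, min_len, var_floor)
  cps <- .optimal_cps(costs, J)
  .build_segmentation(profile, cps, min_len, var_floor)
}

#' Top-N most likely segmentations
#'
#' Enumerates the `N` feasible segmentations in `J` zones with the highest
#' total log-likelihood, in strictly decreasing order (exact ties broken by
#' the lexicographically smaller change-point vector). The first element is
#' the optimal segmentation. If fewer than `N` feasible segmentations exist,
#' all of them are returned.
#'
#' @inheritParams optimal_segmentation
#' @param N number of segmentations requested (`N >= 1`).
#' @return A list of `segmentation` objects.
#' @export
top_segmentations <- function(profile, J, N, min_len = 4L, var_floor = 1e-6) {
  if (N < 1L) stop("`N` must be at least 1")
  costs <- .linear_costs(profile, min_len, var_floor)
  st <- .topn_cps(costs, J, N)
  out <- lapply(seq_along(st$scores), function(k)
    .build_segmentation(profile, st$cps[k, ], min_len, var_floor))
  # guard: the front-reconstructed optimum defines tie-breaking for rank 1
  opt <- .optimal_cps(costs, J)
  if (length(opt) && !identical(as.integer(st$cps[1, ]), opt) &&
      isTRUE(all.equal(out[[1]]$log_likelihood,
                       .build_segmentation(profile, opt, min_len,
                                           var_floor)$log_likelihood)))
    out[[1]] <- .build_segmentation(profile, opt, min_len, var_floor)
  out
}

#' Evaluate the piecewise linear function at axial positions
#'
#' Returns `alpha_j + beta_j * position` for the zone covering each position.
#' At a zone limit, the shootward (later) segment is used. The function is
#' not assumed to be continuous at limits.
#'
#' @param seg a `segmentation`.
#' @param position numeric vector of axial positions (um) within the profile
#'   span.
#' @return Predicted cell lengths (um).
#' @export
evaluate_piecewise <- function(seg, position) {
  stopifnot(inherits(seg, "segmentation"))
  position <- as.numeric(position)
  if (any(position < seg$span[1] - 1e-9) || any(position > seg$span[2] + 1e-9))
    stop("position outside the profile span [", seg$span[1], ", ",
         seg$span[2], "] um")
  j <- vapply(position, function(p) 1L + sum(seg$limit_positions <= p),
              integer(1))
  vapply(seq_along(position), function(i) {
    f <- seg$fits[[j[i]]]
    f$intercept + f$slope * position[i]
  }, numeric(1))
}

#' Discontinuity of the piecewise linear function at a limit
#'
#' Signed jump (um) between the two linear functions evaluated at the limit
#' position: shootward prediction minus rootward prediction, so the jump is
#' negative when the shootward line starts below the rootward line.
#'
#' @param seg a `segmentation`.
#' @param j limit index, `1 <= j <= J - 1`.
#' @return Signed jump in um.
#' @export
jump_at_limit <- function(seg, j) {
  stopifnot(inherits(seg, "segmentation"))
  j <- as.integer(j)
  if (j < 1L || j > seg$J - 1L) stop("limit index out of range")
  L <- seg$limit_positions[j]
  fr <- seg$fits[[j]]
  fs <- seg$fits[[j + 1L]]
  (fs$intercept + fs$slope * L) - (fr$intercept + fr$slope * L)
}
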