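#' Number of free parameters of a J-zone model
#'
#' The piecewise linear family estimates an intercept, a slope and a residual
#' variance per zone plus the J - 1 change points (4J - 1 parameters); the
#' change-in-variance family estimates a global mean, one variance per zone
#' and the change points (2J parameters).
#'
#' @param J number of zones.
#' @param family `"linear"` or `"variance"`.
#' @return Integer parameter count.
#' @export
model_dimension <- function(J, family = c("linear", "variance")) {
  family <- match.arg(family)
  if (any(J < 1)) stop("`J` must be at least 1")
  switch(family, linear = 4 * J - 1, variance = 2 * J)
}

# Shared slope-heuristic engine working on a precomputed cost table.
.slope_heuristic_engine <- function(costs, J_max, family) {
  T <- costs$T; ml <- costs$min_len
  J_feas <- T %/% ml
  Jm <- min(J_max, J_feas)
  if (Jm < 2L) {
    warning("fewer than two feasible zone numbers; selection degenerates to J = 1")
    trace <- data.frame(J = 1L, log_likelihood = .dp_forward(costs, 1L, "max")[1, T],
                        dimension = model_dimension(1L, family),
                        criterion = NA_real_, weight = 1)
    return(structure(list(trace = trace, slope = NA_real_, J_star = 1L,
                          family = family), class = "model_selection"))
  }
  Fm <- .dp_forward(costs, Jm, "max")
  Js <- seq_len(Jm)
  ll <- Fm[cbind(Js, rep(T, Jm))]
  D <- model_dimension(Js, family)
  # penalty slope from the upper half of the J range (>= 3 points, else all
  # J >= 2), where gains in log-likelihood reflect overfitting only; the
  # largest per-parameter increment over that range is used rather than the
  # OLS slope, because the first spurious split captures the most spurious
  # likelihood and an average would under-penalize it
  fit_Js <- Js[Js >= floor(Jm / 2) + 1L]
  if (length(fit_Js) < 3L) fit_Js <- Js[Js >= 2L]
  s_hat <- if (length(fit_Js) >= 2L) {
    max(diff(ll[fit_Js]) / diff(D[fit_Js]))
  } else 0
  s_hat <- max(s_hat, 0)
  crit <- ll - 2 * s_hat * D
  w <- exp(crit - max(crit))
  w <- w / sum(w)
  J_star <- Js[which.max(crit)]     # smallest J on ties
  trace <- data.frame(J = Js, log_likelihood = ll, dimension = D,
                      criterion = crit, weight = w)
  structure(list(trace = trace, slope = s_hat, J_star = as.integer(J_star),
                 family = family), class = "model_selection")
}

#' Select the number of developmental zones by the slope heuristic
#'
#' Fits the optimal segmentation for J = 1..`J_max`, estimates the penalty
#' constant `s_hat` as the largest per-parameter log-likelihood increment
#' over the upper half of the J range (where additional zones only overfit),
#' and maximizes the penalized criterion `C(J) = l(J) - 2 * s_hat * D(J)`.
#' Model weights are the normalized exponentials of `C(J)`, so models within
#' roughly one zone of the optimum retain non-negligible weight.
#'
#' @inheritParams optimal_segmentation
#' @param J_max largest number of zones considered; truncated to the largest
#'   feasible value for the profile. Default 5, so that the penalty slope is
#'   estimated from the top half of the range (J = 3..5), beyond the zone
#'   numbers expected biologically (at most 4).
#' @param family `"linear"` fits cell lengths; `"variance"` fits a
#'   change-in-variance model, in which case `profile` may be a plain numeric
#'   series (e.g. residuals).
#' @return An object of class `model_selection`: a per-J trace
#'   (log-likelihood, dimension, criterion, weight), the estimated penalty
#'   slope and the selected `J_star`.
#' @export
slope_heuristic <- function(profile, J_max = NULL, min_len = 4L,
                            family = c("linear", "variance"),
                            var_floor = 1e-6) {
  family <- match.arg(family)
  if (is.null(J_max)) J_max <- 5L
  costs <- if (family == "linear") {
    stopifnot(inherits(profile, "cell_profile"))
    .linear_costs(profile, min_len, var_floor)
  } else {
    .variance_costs(if (inherits(profile, "cell_profile")) profile$lengths
                    else profile, min_len, var_floor)
  }
  .slope_heuristic_engine(costs, as.integer(J_max), family)
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> family = ", x$family, ", selected J = ", x$J_star,
      "\n", sep = "")
  print(format(x$trace, digits = 4), row.names = FALSE)
  invisible(x)
}
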