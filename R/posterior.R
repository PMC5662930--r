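# Posterior quantities over the whole segmentation space at fixed J.
#
# All segmentation-space sums use the profile likelihood (per-segment ML
# plug-in parameters), consistent with the dynamic-programming cost, with a
# uniform prior over feasible segmentations. Accumulation is in log-sum-exp
# arithmetic; only evidence-normalized probabilities are handled in
# probability space.

# Shared engine: computes evidence, zone-occupancy (sum-type) and
# segmentation-probability (max-type) profiles, and change-point posteriors
# from a precomputed cost table.
.posterior_engine <- function(costs, J) {
  .check_feasible(costs, J)
  T <- costs$T; ml <- costs$min_len; cost <- costs$cost
  if (J == 1L) {
    return(list(J = 1L, log_evidence = cost[1, T],
                occupancy = matrix(1, T, 1),
                profiles = matrix(1, T, 1),
                changepoints = list()))
  }
  Fs <- .dp_forward(costs, J, "sum")
  Bs <- .dp_backward(costs, J, "sum")
  Fm <- .dp_forward(costs, J, "max")
  Bm <- .dp_backward(costs, J, "max")
  logE <- Fs[J, T]
  occ <- matrix(0, T, J)
  prof <- matrix(0, T, J)
  for (j in seq_len(J)) {
    u_cand <- seq.int((j - 1L) * ml + 1L, T - (J - j + 1L) * ml + 1L)
    if (j == 1L) u_cand <- 1L
    for (u in u_cand) {
      fs_prev <- if (j == 1L) 0 else Fs[j - 1L, u - 1L]
      fm_prev <- if (j == 1L) 0 else Fm[j - 1L, u - 1L]
      if (!is.finite(fs_prev)) next
      v_cand <- if (j == J) T else seq.int(u + ml - 1L, T - (J - j) * ml)
      bs_next <- if (j == J) 0 else Bs[J - j, v_cand + 1L]
      bm_next <- if (j == J) 0 else Bm[J - j, v_cand + 1L]
      lw_s <- fs_prev + cost[u, v_cand] + bs_next - logE
      lw_m <- fm_prev + cost[u, v_cand] + bm_next - logE
      pr_s <- exp(lw_s); pr_s[!is.finite(pr_s)] <- 0
      pr_m <- exp(lw_m); pr_m[!is.finite(pr_m)] <- 0
      v0 <- v_cand[1]
      vmax <- v_cand[length(v_cand)]
      rc <- rev(cumsum(rev(pr_s)))
      rcm <- rev(cummax(rev(pr_m)))
      if (v0 > u) {
        occ[u:(v0 - 1L), j] <- occ[u:(v0 - 1L), j] + rc[1]
        prof[u:(v0 - 1L), j] <- pmax(prof[u:(v0 - 1L), j], rcm[1])
      }
      occ[v0:vmax, j] <- occ[v0:vmax, j] + rc
      prof[v0:vmax, j] <- pmax(prof[v0:vmax, j], rcm)
    }
  }
  cps <- lapply(seq_len(J - 1L), function(j) {
    p <- numeric(T)
    t_cand <- seq.int(j * ml + 1L, T - (J - j) * ml + 1L)
    lw <- Fs[j, t_cand - 1L] + Bs[J - j, t_cand] - logE
    pj <- exp(lw); pj[!is.finite(pj)] <- 0
    p[t_cand] <- pj
    p
  })
  list(J = J, log_evidence = logE, occupancy = occ, profiles = prof,
       changepoints = cps)
}

#' Log-evidence of the J-zone model
#'
#' Log of the summed likelihood over all feasible segmentations of the
#' profile into `J` zones, computed by a forward recursion in log-sum-exp
#' arithmetic. This is the denominator of the posterior probability of any
#' individual segmentation.
#'
#' @inheritParams optimal_segmentation
#' @return A number with attributes `J` and `T` recording the model it was
#'   computed for.
#' @export
log_evidence <- function(profile, J, min_len = 4L, var_floor = 1e-6) {
  costs <- .linear_costs(profile, min_len, var_floor)
  .check_feasible(costs, J)
  Fs <- .dp_forward(costs, J, "sum")
  structure(Fs[J, costs$T], J = as.integer(J), T = costs$T)
}

#' Posterior probability of a segmentation
#'
#' Weight of `seg` among all feasible segmentations in the same number of
#' zones: `exp(log L(seg) - log evidence)`.
#'
#' @param seg a `segmentation`.
#' @param log_evidence value returned by [log_evidence()] for the same
#'   profile, `J` and `min_len`.
#' @return A probability in (0, 1].
#' @export
segmentation_posterior <- function(seg, log_evidence) {
  stopifnot(inherits(seg, "segmentation"))
  J_ev <- attr(log_evidence, "J")
  if (!is.null(J_ev) && J_ev != seg$J)
    stop("evidence was computed for J = ", J_ev,
         " but the segmentation has J = ", seg$J)
  min(exp(seg$log_likelihood - as.numeric(log_evidence)), 1)
}

#' Posterior zone-occupancy profiles
#'
#' Entry (t, j) is the posterior probability that cell t lies in zone j,
#' summed over all feasible segmentations weighted by their posterior. Each
#' row sums to 1; cell 1 belongs to zone 1 and cell T to zone J with
#' probability 1.
#'
#' @inheritParams optimal_segmentation
#' @return A T x J matrix of probabilities.
#' @export
zone_occupancy_profiles <- function(profile, J, min_len = 4L,
                                    var_floor = 1e-6) {
  costs <- .linear_costs(profile, min_len, var_floor)
  .posterior_engine(costs, J)$occupancy
}

#' Posterior segmentation-probability profiles
#'
#' Max-type analog of [zone_occupancy_profiles()]: entry (t, j) is the
#' maximum posterior probability over segmentations that assign cell t to
#' zone j. Elementwise bounded above by the zone-occupancy profile.
#'
#' @inheritParams optimal_segmentation
#' @return A T x J matrix of probabilities.
#' @export
segmentation_probability_profiles <- function(profile, J, min_len = 4L,
                                              var_floor = 1e-6) {
  costs <- .linear_costs(profile, min_len, var_floor)
  .posterior_engine(costs, J)$profiles
}

#' Posterior distribution of one change point
#'
#' Probability that `tau_j` (the first cell of zone j + 1) equals each cell
#' index, summed over all feasible segmentations. The support respects the
#' minimum segment length on both sides.
#'
#' @inheritParams optimal_segmentation
#' @param j limit index, `1 <= j <= J - 1`.
#' @return A numeric vector of length T summing to 1.
#' @export
changepoint_posterior <- function(profile, J, min_len = 4L, j,
                                  var_floor = 1e-6) {
  j <- as.integer(j)
  if (j < 1L || j > J - 1L) stop("limit index out of range")
  costs <- .linear_costs(profile, min_len, var_floor)
  .posterior_engine(costs, J)$changepoints[[j]]
}

#' Uncertainty interval around a change point
#'
#' Smallest contiguous index interval containing the most probable change
#' point whose total posterior mass reaches `coverage`, grown greedily toward
#' the side offering more mass (ties toward the rootward side). The MAP
#' change point may sit at an interval endpoint.
#'
#' @param distribution numeric vector of probabilities over cell indices
#'   (e.g. from [changepoint_posterior()]); must sum to 1.
#' @param map_index index of the most probable change point; must carry
#'   positive mass.
#' @param coverage target mass in (0, 1]; default 0.95.
#' @param positions optional axial positions (um) used to report the interval
#'   on the micrometre scale.
#' @return A list with `lo`, `hi` (cell indices), `mass`, and — when
#'   `positions` is given — `lo_um`, `hi_um`.
#' @export
uncertainty_interval <- function(distribution, map_index, coverage = 0.95,
                                 positions = NULL) {
  if (coverage <= 0 || coverage > 1)
    stop("`coverage` must be in (0, 1]")
  p <- as.numeric(distribution)
  if (abs(sum(p) - 1) > 1e-6)
    stop("`distribution` must be normalized")
  map_index <- as.integer(map_index)
  if (map_index < 1L || map_index > length(p) || p[map_index] <= 0)
    stop("`map_index` must lie in the support of the distribution")
  supp <- range(which(p > 0))
  lo <- hi <- map_index
  mass <- p[map_index]
  while (mass < coverage - 1e-12 && (lo > supp[1] || hi < supp[2])) {
    left <- if (lo > supp[1]) p[lo - 1L] else -Inf
    right <- if (hi < supp[2]) p[hi + 1L] else -Inf
    if (left >= right) {            # ties grow rootward
      lo <- lo - 1L; mass <- mass + p[lo]
    } else {
      hi <- hi + 1L; mass <- mass + p[hi]
    }
  }
  out <- list(lo = lo, hi = hi, mass = mass)
  if (!is.null(positions)) {
    out$lo_um <- positions[lo]
    out$hi_um <- positions[hi]
  }
  out
}

#' Full posterior summary at fixed J
#'
#' One-call wrapper computing the evidence, the optimal segmentation and its
#' posterior, both posterior probability profiles, and the change-point
#' posteriors with their uncertainty intervals.
#'
#' @inheritParams optimal_segmentation
#' @param coverage coverage of the change-point uncertainty intervals.
#' @return An object of class `posterior_summary`.
#' @export
posterior_summary <- function(profile, J, min_len = 4L, coverage = 0.95,
                              var_floor = 1e-6) {
  costs <- .linear_costs(profile, min_len, var_floor)
  eng <- .posterior_engine(costs, J)
  cps <- .optimal_cps(costs, J)
  seg <- .build_segmentation(profile, cps, min_len, var_floor)
  intervals <- lapply(seq_along(cps), function(j)
    uncertainty_interval(eng$changepoints[[j]], cps[j], coverage,
                         positions = profile$positions))
  structure(list(J = as.integer(J),
                 log_evidence = eng$log_evidence,
                 segmentation = seg,
                 optimal_posterior = min(exp(seg$log_likelihood -
                                               eng$log_evidence), 1),
                 zone_occupancy = eng$occupancy,
                 segmentation_profiles = eng$profiles,
                 changepoint_posteriors = eng$changepoints,
                 uncertainty_intervals = intervals,
                 coverage = coverage),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> J = ", x$J,
      ", optimal segmentation posterior = ",
      format(x$optimal_posterior, digits = 3), "\n", sep = "")
  for (j in seq_along(x$uncertainty_intervals)) {
    ui <- x$uncertainty_intervals[[j]]
    cat("  limit ", j, ": cell ", x$segmentation$change_points[j],
        " (", round(x$segmentation$limit_positions[j], 1), " um), ",
        100 * x$coverage, "% interval cells [", ui$lo, ", ", ui$hi, "]",
        if (!is.null(ui$lo_um)) paste0(" (", round(ui$lo_um, 1), ", ",
                                       round(ui$hi_um, 1), " um)"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Export posterior profiles as a tidy table
#'
#' @param summary a [posterior_summary()].
#' @param positions axial positions (um) of the profiled cells.
#' @return A data frame with columns `cell_index`, `position_um`, `zone`,
#'   `occupancy`, `segmentation_probability`.
#' @export
tidy_posterior_profiles <- function(summary, positions) {
  stopifnot(inherits(summary, "posterior_summary"))
  T <- nrow(summary$zone_occupancy)
  J <- summary$J
  data.frame(cell_index = rep(seq_len(T), J),
             position_um = rep(positions, J),
             zone = rep(seq_len(J), each = T),
             occupancy = as.vector(summary$zone_occupancy),
             segmentation_probability = as.vector(summary$segmentation_profiles))
}
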