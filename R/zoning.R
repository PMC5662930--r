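#' Configuration of the biologically guided segmentation choice
#'
#' Collects the thresholds used to turn a statistical segmentation into
#' labeled developmental zones and to screen well-supported alternative
#' segmentations.
#'
#' @param sig_level two-sided significance level for slope tests (matches the
#'   "n.s." annotations of the reference tables). Default 0.05.
#' @param ez_slope_min minimum slope (um/mm) for calling the first of two
#'   segments an elongation zone; used only for 2-segment disambiguation.
#'   Default 20 um/mm (reported elongation-zone slopes range 9.8-201.8,
#'   division-zone slopes -22.1 to 27.9).
#' @param jump_factor maximum acceptable discontinuity at a limit, as a
#'   multiple of the smaller adjacent residual standard deviation. Default 2
#'   (a jump of ~4 residual sd is rejected, ~1 sd accepted).
#' @param support_ratio a segmentation is "well-supported" when its posterior
#'   probability is within this factor of the best segmentation's. Default 10.
#' @param continuity_level confidence level of the rootward/shootward
#'   conditional-mean intervals at limits. Default 0.95.
#' @param coverage coverage of change-point uncertainty intervals. Default
#'   0.95.
#' @param J_max largest number of zones considered by the slope heuristic.
#' @param min_len minimum segment length (cells).
#' @param top_n number of alternative segmentations screened.
#' @param var_floor variance floor (um^2).
#' @return A list of class `zoning_config`.
#' @export
zoning_config <- function(sig_level = 0.05, ez_slope_min = 20,
                          jump_factor = 2, support_ratio = 10,
                          continuity_level = 0.95, coverage = 0.95,
                          J_max = 5L, min_len = 4L, top_n = 5L,
                          var_floor = 1e-6) {
  stopifnot(sig_level > 0, sig_level < 1, ez_slope_min > 0, jump_factor > 0,
            support_ratio >= 1, continuity_level > 0, continuity_level < 1,
            coverage > 0, coverage <= 1)
  structure(list(sig_level = sig_level, ez_slope_min = ez_slope_min,
                 jump_factor = jump_factor, support_ratio = support_ratio,
                 continuity_level = continuity_level, coverage = coverage,
                 J_max = as.integer(J_max), min_len = as.integer(min_len),
                 top_n = as.integer(top_n), var_floor = var_floor),
            class = "zoning_config")
}

#' Two-sided t-test of a segment slope
#'
#' Tests slope = 0 with n - 2 degrees of freedom, as summarized by the
#' "n.s." flags of the reference tables.
#'
#' @param fit a `segment_fit`.
#' @param level significance level.
#' @return A list with `significant`, `p_value`, `statistic` and `df`.
#' @export
slope_significant <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "segment_fit"))
  if (fit$n < 3L)
    stop("slope test undefined: fewer than 3 cells")
  if (fit$degenerate || fit$rss <= 0)
    stop("slope test undefined: zero residual variance")
  tstat <- fit$slope / fit$slope_se
  df <- fit$n - 2L
  p <- 2 * stats::pt(-abs(tstat), df)
  list(significant = p < level, p_value = p, statistic = tstat, df = df)
}

# Is a slope significantly positive? (helper used by the labeling rules;
# degenerate noiseless fits with positive slope count as significant)
.sig_positive <- function(fit, level) {
  if (fit$degenerate || fit$rss <= 0) return(fit$slope > 0)
  s <- slope_significant(fit, level)
  s$significant && fit$slope > 0
}

#' Label the segments of a segmentation as developmental zones
#'
#' Applies the biological reading of the zones: the division zone (DZ) holds
#' small cells, the elongation zone (EZ) cells of gradually increasing
#' length, the mature zone (MZ) large cells. The mature zone is always
#' present and last.
#'
#' A single segment is a mature zone. With two segments the first is an
#' elongation zone when its slope is significantly positive and at least
#' `ez_slope_min` um/mm, otherwise a division zone. Three segments are read
#' positionally as DZ, EZ, MZ, with diagnosis `"EZ-missing"` when the middle
#' slope is not significantly positive. Four segments are read as a split of
#' the division zone into proliferation and transition domains (DZ, TZ, EZ,
#' MZ) when the first two segments hold small cells (mean length below the
#' elongation-zone start prediction); otherwise the diagnosis is
#' `"unexpected-pattern"`.
#'
#' @param seg a `segmentation` with 1-4 segments.
#' @param config a [zoning_config()].
#' @return A list with `labels` (character vector) and `diagnosis`
#'   (`NA_character_` when the pattern is consistent).
#' @export
label_zones <- function(seg, config = zoning_config()) {
  stopifnot(inherits(seg, "segmentation"))
  J <- seg$J
  if (J > 4L) stop("unsupported pattern: more than 4 segments")
  diagnosis <- NA_character_
  if (J == 1L) {
    labels <- "MZ"
  } else if (J == 2L) {
    f1 <- seg$fits[[1]]
    is_ez <- .sig_positive(f1, config$sig_level) &&
      f1$slope_per_mm >= config$ez_slope_min
    labels <- c(if (is_ez) "EZ" else "DZ", "MZ")
    if (!is_ez) diagnosis <- "EZ-missing"
  } else if (J == 3L) {
    labels <- c("DZ", "EZ", "MZ")
    if (!.sig_positive(seg$fits[[2]], config$sig_level))
      diagnosis <- "EZ-missing"
  } else {
    labels <- c("DZ", "TZ", "EZ", "MZ")
    f3 <- seg$fits[[3]]
    ez_start_pred <- f3$intercept +
      f3$slope * seg$limit_positions[2]
    m1 <- .mean_cell_length(seg, 1L)
    m2 <- .mean_cell_length(seg, 2L)
    if (!(m1 < ez_start_pred && m2 < ez_start_pred))
      diagnosis <- "unexpected-pattern"
  }
  list(labels = labels, diagnosis = diagnosis)
}

# mean observed cell length within segment k (used by the 4-zone rule)
.mean_cell_length <- function(seg, k) {
  f <- seg$fits[[k]]
  # reconstruct from the fit: mean of the line at the mean position equals
  # the segment's mean observed length under OLS
  f$intercept + f$slope * f$x_mean
}

#' Rootward and shootward confidence intervals at a limit
#'
#' For both segments adjacent to limit `j`, the OLS confidence interval for
#' the conditional mean cell length at the limit position:
#' `prediction +/- t(n-2, (1+level)/2) * s * sqrt(1/n + (x0 - xbar)^2 / Sxx)`
#' with `s^2 = RSS / (n - 2)`. Overlap of the two intervals indicates that
#' the piecewise linear function is approximately continuous at the limit.
#'
#' @param seg a `segmentation`.
#' @param j limit index, `1 <= j <= J - 1`.
#' @param level confidence level (default 0.95); wider intervals for higher
#'   levels.
#' @return A list with `rootward` and `shootward`, each `c(lo, hi)` in um,
#'   and `at` (the limit position).
#' @export
continuity_intervals <- function(seg, j, level = 0.95) {
  stopifnot(inherits(seg, "segmentation"))
  j <- as.integer(j)
  if (j < 1L || j > seg$J - 1L) stop("limit index out of range")
  x0 <- seg$limit_positions[j]
  ci <- function(f) {
    if (f$n < 3L || f$degenerate || f$rss <= 0)
      stop("confidence interval undefined for a degenerate segment fit")
    s <- sqrt(f$rss / (f$n - 2))
    se <- s * sqrt(1 / f$n + (x0 - f$x_mean)^2 / f$sxx)
    pred <- f$intercept + f$slope * x0
    tq <- stats::qt(1 - (1 - level) / 2, f$n - 2)
    c(pred - tq * se, pred + tq * se)
  }
  list(rootward = ci(seg$fits[[j]]), shootward = ci(seg$fits[[j + 1L]]),
       at = x0)
}

#' Overlap test for rootward/shootward confidence intervals
#'
#' Closed-interval intersection; touching endpoints overlap.
#'
#' @param rootward_ci,shootward_ci numeric `c(lo, hi)` intervals.
#' @return `TRUE` when the intervals intersect.
#' @export
continuity_overlap <- function(rootward_ci, shootward_ci) {
  colocalized(rootward_ci, shootward_ci)
}

# jump-acceptability rule: |jump| <= factor * min(adjacent residual sds)
.jumps_ok <- function(seg, config) {
  if (seg$J < 2L) return(TRUE)
  all(vapply(seq_len(seg$J - 1L), function(j) {
    sd_min <- min(seg$fits[[j]]$residual_sd, seg$fits[[j + 1L]]$residual_sd)
    abs(jump_at_limit(seg, j)) <= config$jump_factor * sd_min
  }, logical(1)))
}

.label_ok <- function(lab) is.na(lab$diagnosis)

#' Select and label the final segmentation of a root
#'
#' The full inference pipeline for one root: (1) the slope heuristic selects
#' the number of zones J*; (2) the optimal segmentation at J* is labeled;
#' (3) if two consecutive zones appear merged (diagnosis `"EZ-missing"`),
#' well-supported segmentations with one more zone are explored and the
#' highest-posterior consistent candidate retained; (4) if the retained
#' piecewise linear function carries an unacceptably large discontinuity
#' (|jump| above `jump_factor` times the smaller adjacent residual sd),
#' well-supported alternative segmentations at the same J are screened and
#' the highest-posterior candidate passing the jump rule retained; (5) if no
#' candidate passes, the optimal segmentation is retained with a warning
#' recorded. The first-root-hair position is never used to choose a
#' segmentation; it is only compared afterwards.
#'
#' @param profile a [cell_profile()].
#' @param config a [zoning_config()].
#' @return An object of class `zoned_root`: retained `segmentation`, zone
#'   `labels`, `limits` (positions with uncertainty intervals), per-limit
#'   `continuity` intervals and overlap flags, `jumps`, `hair_match`
#'   (`NA` when not applicable), `provenance` (source, rank, model weight)
#'   and the model-selection trace.
#' @export
select_final_segmentation <- function(profile, config = zoning_config()) {
  stopifnot(inherits(profile, "cell_profile"))
  if (profile$T < 2L * config$min_len && profile$T < config$min_len)
    stop("profile too short to segment")
  sel <- slope_heuristic(profile, config$J_max, config$min_len,
                         family = "linear", var_floor = config$var_floor)
  J_star <- sel$J_star
  notes <- character(0)

  chosen <- optimal_segmentation(profile, J_star, config$min_len,
                                 config$var_floor)
  lab <- label_zones(chosen, config)
  provenance <- list(source = "optimal", rank = 1L, J = J_star,
                     model_weight = sel$trace$weight[J_star])

  # (3) merged zones: explore well-supported segmentations with one more zone
  if (identical(lab$diagnosis, "EZ-missing") &&
      (J_star + 1L) * config$min_len <= profile$T &&
      J_star + 1L <= 4L) {
    J1 <- J_star + 1L
    cands <- top_segmentations(profile, J1, config$top_n, config$min_len,
                               config$var_floor)
    ev1 <- log_evidence(profile, J1, config$min_len, config$var_floor)
    posts <- vapply(cands, segmentation_posterior, numeric(1),
                    log_evidence = ev1)
    supported <- posts >= posts[1] / config$support_ratio
    for (k in seq_along(cands)) {
      if (!supported[k]) next
      lk <- label_zones(cands[[k]], config)
      if (.label_ok(lk) && .jumps_ok(cands[[k]], config)) {
        chosen <- cands[[k]]; lab <- lk
        provenance <- list(source = "J+1 model", rank = k, J = J1,
                           model_weight = if (J1 <= nrow(sel$trace))
                             sel$trace$weight[J1] else NA_real_,
                           segmentation_posterior = posts[k])
        break
      }
    }
    if (identical(provenance$source, "optimal") &&
        identical(lab$diagnosis, "EZ-missing"))
      notes <- c(notes, "no consistent well-supported J+1 candidate; optimal retained")
  }

  # (4) strong discontinuity: screen alternatives at the same J
  if (!.jumps_ok(chosen, config) && chosen$J >= 2L) {
    Jc <- chosen$J
    cands <- top_segmentations(profile, Jc, config$top_n, config$min_len,
                               config$var_floor)
    evc <- log_evidence(profile, Jc, config$min_len, config$var_floor)
    posts <- vapply(cands, segmentation_posterior, numeric(1),
                    log_evidence = evc)
    supported <- posts >= posts[1] / config$support_ratio
    found <- FALSE
    for (k in seq_along(cands)) {
      if (!supported[k]) next
      lk <- label_zones(cands[[k]], config)
      if (.jumps_ok(cands[[k]], config) && .label_ok(lk)) {
        chosen <- cands[[k]]; lab <- lk
        provenance <- list(source = if (k == 1L && identical(provenance$source,
                                                             "optimal"))
          "optimal" else "alternative", rank = k, J = Jc,
          segmentation_posterior = posts[k])
        found <- TRUE
        break
      }
    }
    if (!found)
      notes <- c(notes, "no well-supported alternative passes the jump rule; optimal retained")
  }

  # (5) uncertainty intervals and continuity at the retained limits
  J <- chosen$J
  if (J >= 2L) {
    eng <- .posterior_engine(.linear_costs(profile, config$min_len,
                                           config$var_floor), J)
    lims <- do.call(rbind, lapply(seq_len(J - 1L), function(j) {
      ui <- uncertainty_interval(eng$changepoints[[j]],
                                 chosen$change_points[j], config$coverage,
                                 positions = profile$positions)
      data.frame(limit = j, position_um = chosen$limit_positions[j],
                 lo_um = ui$lo_um, hi_um = ui$hi_um)
    }))
    continuity <- lapply(seq_len(J - 1L), function(j) {
      ci <- tryCatch(continuity_intervals(chosen, j, config$continuity_level),
                     error = function(e) NULL)
      if (is.null(ci)) return(list(rootward = NULL, shootward = NULL,
                                   overlap = NA))
      c(ci, list(overlap = continuity_overlap(ci$rootward, ci$shootward)))
    })
    jumps <- vapply(seq_len(J - 1L), function(j) jump_at_limit(chosen, j),
                    numeric(1))
  } else {
    lims <- data.frame(limit = integer(0), position_um = numeric(0),
                       lo_um = numeric(0), hi_um = numeric(0))
    continuity <- list()
    jumps <- numeric(0)
  }

  zoned <- structure(list(labels = lab$labels, diagnosis = lab$diagnosis,
                          segmentation = chosen, limits = lims,
                          continuity = continuity, jumps = jumps,
                          provenance = provenance, selection = sel,
                          notes = notes, hair_match = NA,
                          root_id = profile$root_id),
                     class = "zoned_root")
  hair <- profile$metadata$first_hair_um
  if (!is.null(hair) && !is.na(hair))
    zoned$hair_match <- hair_match(zoned, hair)
  zoned
}

#' @export
print.zoned_root <- function(x, ...) {
  cat("<zoned_root> ", x$root_id, ": zones [",
      paste(x$labels, collapse = ", "), "], provenance ",
      x$provenance$source, " (rank ", x$provenance$rank, ")\n", sep = "")
  if (nrow(x$limits)) {
    for (i in seq_len(nrow(x$limits)))
      cat("  ", x$labels[i], "-", x$labels[i + 1], " limit at ",
          round(x$limits$position_um[i], 1), " um (",
          round(x$limits$lo_um[i], 1), ", ", round(x$limits$hi_um[i], 1),
          "), jump ", round(x$jumps[i], 1), " um\n", sep = "")
  }
  if (!is.na(x$hair_match))
    cat("  first-root-hair match: ", x$hair_match, "\n", sep = "")
  invisible(x)
}

#' Does the first root hair match the EZ-MZ limit?
#'
#' `TRUE` when the first-root-hair position lies rootward of (or exactly at)
#' the elongation-to-mature limit, or inside that limit's closed uncertainty
#' interval. Returns `NA` (not applicable) when the root has no EZ-MZ limit.
#'
#' @param zoned a `zoned_root`.
#' @param hair_position first-root-hair position (um).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
hair_match <- function(zoned, hair_position) {
  stopifnot(inherits(zoned, "zoned_root"))
  k <- which(zoned$labels == "EZ")
  if (length(k) == 0L || k[1] >= length(zoned$labels)) return(NA)
  i <- k[1]                                  # limit i separates EZ from MZ
  if (i > nrow(zoned$limits)) return(NA)
  lim <- zoned$limits[i, ]
  .hair_match_rule(hair_position, lim$position_um, lim$lo_um, lim$hi_um)
}

# shared rule, also applied to the packaged reference tables
.hair_match_rule <- function(hair, limit, lo, hi) {
  if (is.na(hair) || is.na(limit)) return(NA)
  hair <= limit || (!is.na(lo) && !is.na(hi) && hair >= lo && hair <= hi)
}

#' Serialize a zoned root as a report list
#'
#' @param zoned a `zoned_root`.
#' @return A plain list (zones, limits, provenance, hair match) suitable for
#'   JSON export.
#' @export
as_zoned_report <- function(zoned) {
  stopifnot(inherits(zoned, "zoned_root"))
  seg <- zoned$segmentation
  starts_um <- c(seg$span[1], seg$limit_positions)
  ends_um <- c(seg$limit_positions, seg$span[2])
  zones <- lapply(seq_len(seg$J), function(j) {
    f <- seg$fits[[j]]
    list(label = zoned$labels[j], start_um = starts_um[j], end_um = ends_um[j],
         slope_per_mm = f$slope_per_mm, correlation = f$correlation,
         n_cells = f$n, residual_sd = f$residual_sd)
  })
  limits <- lapply(seq_len(max(seg$J - 1L, 0L)), function(j) {
    cont <- zoned$continuity[[j]]
    list(position_um = zoned$limits$position_um[j],
         uncertainty_um = c(zoned$limits$lo_um[j], zoned$limits$hi_um[j]),
         continuity = list(ci_rootward = cont$rootward,
                           ci_shootward = cont$shootward,
                           overlap = cont$overlap),
         jump_um = zoned$jumps[j])
  })
  list(root_id = zoned$root_id, zones = zones, limits = limits,
       hair_match = zoned$hair_match,
       provenance = zoned$provenance, notes = zoned$notes)
}
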