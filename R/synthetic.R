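#' Zone specification for the synthetic profile generator
#'
#' One developmental zone of a synthetic root: its axial span, the linear
#' mean cell-length trend in global coordinates, and the zone-specific
#' residual spread.
#'
#' @param label zone label (`"DZ"`, `"TZ"`, `"EZ"`, `"MZ"`).
#' @param span_um axial extent of the zone (um), positive.
#' @param intercept_um intercept of the mean cell-length line at position 0
#'   (global coordinates, um).
#' @param slope_per_mm slope of the mean line (um of cell length per mm of
#'   axis).
#' @param sd_um residual standard deviation of drawn cell lengths (um).
#' @return A list of class `zone_spec`.
#' @export
zone_spec <- function(label, span_um, intercept_um, slope_per_mm, sd_um) {
  if (span_um <= 0) stop("zone span must be positive")
  if (sd_um < 0) stop("zone sd must be nonnegative")
  structure(list(label = label, span_um = span_um,
                 intercept_um = intercept_um,
                 slope_per_mm = slope_per_mm, sd_um = sd_um),
            class = "zone_spec")
}

#' Profile specification for the synthetic generator
#'
#' @param zones list of [zone_spec()]s ordered rootward to shootward.
#' @param n_files number of independently tiled cell files merged into the
#'   profile (the protocol measures the central 3-4 clearly visible files;
#'   default 3).
#' @param floor_um truncation floor for drawn cell lengths (um); prevents
#'   non-positive lengths. Default 0.5.
#' @param hair_offset_um offset of the synthetic first-root-hair position
#'   shootward of the EZ-MZ limit (um). Default 100.
#' @param seed optional RNG seed.
#' @param root_id identifier.
#' @return A list of class `profile_spec`.
#' @export
profile_spec <- function(zones, n_files = 3L, floor_um = 0.5,
                         hair_offset_um = 100, seed = NULL,
                         root_id = "synthetic") {
  if (!length(zones)) stop("at least one zone is required")
  if (n_files < 1L) stop("at least one cell file is required")
  for (z in zones) {
    if (!inherits(z, "zone_spec")) stop("zones must be zone_spec objects")
  }
  # the mean line must stay above the truncation floor over the whole span
  bounds <- cumsum(vapply(zones, `[[`, numeric(1), "span_um"))
  starts <- c(0, bounds[-length(bounds)])
  for (i in seq_along(zones)) {
    z <- zones[[i]]
    m <- z$intercept_um + z$slope_per_mm / 1000 * c(starts[i], bounds[i])
    if (any(m <= floor_um))
      stop("mean cell length falls to the truncation floor within zone ",
           z$label)
  }
  structure(list(zones = zones, n_files = as.integer(n_files),
                 floor_um = floor_um, hair_offset_um = hair_offset_um,
                 seed = seed, root_id = root_id),
            class = "profile_spec")
}

# one truncated-normal draw, lower-truncated at `lower`
.rtnorm1 <- function(mean, sd, lower) {
  if (sd <= 0) return(max(mean, lower))
  pl <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(1, pl, 1)
  min(stats::qnorm(u, mean, sd), mean + 8 * sd)
}

#' Generate a synthetic cell-length profile with known ground truth
#'
#' Each cell file tiles the axis from 0: the mean length is the zone line
#' evaluated at the current rootward edge, the drawn length is normal with
#' the zone's sd (truncated at the floor), the recorded position is the cell
#' center, and the edge advances by the drawn length. A cell's zone is the
#' zone containing its center. Files are generated independently and merged
#' by position. A synthetic first-root-hair position is placed a fixed
#' offset shootward of the EZ-MZ limit.
#'
#' @param spec a [profile_spec()].
#' @return A list with `profile` (a [cell_profile()], metadata attached) and
#'   `truth` (list: `limits_um`, per-zone parameter table `zones`,
#'   `hair_um`).
#' @export
generate_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  zl <- spec$zones
  spans <- vapply(zl, `[[`, numeric(1), "span_um")
  bounds <- cumsum(spans)
  total <- bounds[length(bounds)]
  # a center exactly at a boundary belongs to the shootward zone, matching
  # the first-cell-of-shootward-segment limit convention
  zone_at <- function(p) min(findInterval(p, bounds) + 1L, length(zl))
  pos <- len <- numeric(0)
  fid <- integer(0)
  zid <- integer(0)
  for (f in seq_len(spec$n_files)) {
    edge <- 0
    while (edge < total) {
      z <- zl[[zone_at(edge)]]
      m <- z$intercept_um + z$slope_per_mm / 1000 * edge
      L <- .rtnorm1(m, z$sd_um, spec$floor_um)
      center <- edge + L / 2
      pos <- c(pos, center)
      len <- c(len, L)
      fid <- c(fid, f)
      zid <- c(zid, zone_at(min(center, total)))
      edge <- edge + L
    }
  }
  labels <- vapply(zl, `[[`, character(1), "label")
  k_ez <- which(labels == "EZ")
  hair <- if (length(k_ez) && k_ez[1] < length(zl))
    bounds[k_ez[1]] + spec$hair_offset_um else NA_real_
  md <- root_metadata(first_hair_um = hair)
  prof <- cell_profile(pos, len, file_ids = fid, root_id = spec$root_id,
                       metadata = md)
  truth_zones <- data.frame(label = labels,
                            start_um = c(0, bounds[-length(bounds)]),
                            end_um = bounds,
                            slope_per_mm = vapply(zl, `[[`, numeric(1),
                                                  "slope_per_mm"),
                            intercept_um = vapply(zl, `[[`, numeric(1),
                                                  "intercept_um"),
                            sd_um = vapply(zl, `[[`, numeric(1), "sd_um"),
                            stringsAsFactors = FALSE)
  list(profile = prof,
       truth = list(limits_um = bounds[-length(bounds)],
                    zones = truth_zones, hair_um = hair,
                    cell_zone = zid[order(pos)]))
}

#' Generate a cohort of synthetic roots
#'
#' @param specs list of [profile_spec()]s with distinct `root_id`s.
#' @param seed master seed; per-root seeds are derived from it, so a rerun
#'   with the same specs and seed is identical.
#' @return A list with `profiles` (named list) and `truth` (data frame of
#'   per-root ground-truth summaries).
#' @export
generate_cohort <- function(specs, seed = NULL) {
  if (!length(specs)) stop("empty spec list")
  ids <- vapply(specs, `[[`, character(1), "root_id")
  if (anyDuplicated(ids)) stop("duplicate root_ids in cohort specs")
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (!is.null(seed)) sp$seed <- (seed + 7919L * i) %% .Machine$integer.max
    out[[i]] <- generate_profile(sp)
  }
  names(out) <- ids
  truth <- do.call(rbind, lapply(seq_along(out), function(i) {
    tz <- out[[i]]$truth$zones
    ez <- tz[tz$label == "EZ", ]
    dz <- tz[tz$label %in% c("DZ", "TZ"), ]
    data.frame(root_id = ids[i],
               dz_length = if (nrow(dz)) max(dz$end_um) else 0,
               ez_length = if (nrow(ez)) ez$end_um - ez$start_um else 0,
               first_hair_um = out[[i]]$truth$hair_um,
               stringsAsFactors = FALSE)
  }))
  list(profiles = lapply(out, `[[`, "profile"),
       truth_full = lapply(out, `[[`, "truth"),
       truth = truth)
}

#' Preset: vigorous three-zone lateral root
#'
#' Parameters emulate a typical long type-A lateral: a flat division zone of
#' small cells (855 um, ~5.4-6 um cells, sd 1.3), an elongation zone with
#' linearly increasing cell length (to 1494 um, slope 59.5 um/mm, sd 5.5)
#' and a mature zone of large dispersed cells (to 2990 um, slope 49.6 um/mm,
#' sd 18.2). With the protocol's three measured cell files the elongation
#' and mature zones are tiled at the sampling density of the reference
#' profiles (roughly 95 and 50 cells).
#'
#' @param seed optional RNG seed.
#' @param n_files number of cell files (default 3, the protocol's usual
#'   count).
#' @return A [profile_spec()].
#' @export
spec_vigorous <- function(seed = NULL, n_files = 3L) {
  profile_spec(list(
    zone_spec("DZ", 855, 5.4, 0.8, 1.3),
    zone_spec("EZ", 1494 - 855, 7.3 - 59.5e-3 * 855, 59.5, 5.5),
    zone_spec("MZ", 2990 - 1494, 53.3 - 49.6e-3 * 1494, 49.6, 18.2)),
    n_files = n_files, seed = seed, root_id = "vigorous")
}

#' Preset: arrested lateral root (mature zone only)
#'
#' A single mature-like zone with a mild positive trend and large spread,
#' mirroring short arrested type-C roots.
#'
#' @param seed optional RNG seed.
#' @param n_files number of cell files (default 3).
#' @return A [profile_spec()].
#' @export
spec_arrested <- function(seed = NULL, n_files = 3L) {
  profile_spec(list(zone_spec("MZ", 2100, 25, 26, 13)),
               n_files = n_files, seed = seed, root_id = "arrested")
}

#' Read a profile specification from YAML
#'
#' The YAML mirrors the [profile_spec()] fields: a `zones` list (each with
#' `label`, `span_um`, `intercept_um`, `slope_per_mm`, `sd_um`) plus
#' optional `n_files`, `floor_um`, `hair_offset_um`, `seed`, `root_id`.
#'
#' @param path YAML file.
#' @return A [profile_spec()].
#' @export
read_profile_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$zones)) stop("spec YAML needs a `zones` list")
  zones <- lapply(y$zones, function(z)
    zone_spec(z$label, z$span_um, z$intercept_um, z$slope_per_mm, z$sd_um))
  profile_spec(zones,
               n_files = if (is.null(y$n_files)) 3L else y$n_files,
               floor_um = if (is.null(y$floor_um)) 0.5 else y$floor_um,
               hair_offset_um = if (is.null(y$hair_offset_um)) 100
                                else y$hair_offset_um,
               seed = y$seed,
               root_id = if (is.null(y$root_id)) "synthetic" else y$root_id)
}
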