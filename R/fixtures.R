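#' Load the packaged reference tables for 36 maize lateral roots
#'
#' Four plain-CSV tables encode the published per-root results for the 36
#' retained lateral roots (18 wild type, 8 rtcs, 10 rum-1): the change-point
#' models (limits with uncertainty intervals, residual standard deviations,
#' first-root-hair positions, posterior probabilities, for both the piecewise
#' linear and the change-in-variance model), the retained piecewise linear
#' functions (slope, correlation, cell counts, zone ends), the predicted
#' cell lengths at the two ends of each zone's linear function, and the
#' rootward/shootward confidence intervals at each limit.
#'
#' The loader validates the tables (root counts per genotype, zone-count
#' consistency between blocks, interval orientation, strictly increasing
#' limits) and fails with a fixture-corruption error on any mismatch.
#'
#' @return An object of class `root_tables`: a list of data frames `models`,
#'   `zones`, `predictions`, `continuity`.
#' @export
load_table_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "rootzones",
                                  mustWork = TRUE)
  models <- utils::read.csv(path("changepoint_models.csv"),
                            stringsAsFactors = FALSE)
  zones <- utils::read.csv(path("zone_fits.csv"), stringsAsFactors = FALSE)
  preds <- utils::read.csv(path("zone_predictions.csv"),
                           stringsAsFactors = FALSE)
  cont <- utils::read.csv(path("limit_continuity.csv"),
                          stringsAsFactors = FALSE)

  fail <- function(...) stop("fixture corruption: ", ..., call. = FALSE)

  roots <- unique(models[, c("genotype", "root_id")])
  if (nrow(roots) != 36L) fail("expected 36 roots, found ", nrow(roots))
  counts <- table(roots$genotype)
  if (!identical(as.integer(counts[c("wild_type", "rtcs", "rum1")]),
                 c(18L, 8L, 10L)))
    fail("per-genotype root counts are not 18/8/10")
  if (nrow(models) != 72L) fail("expected one linear and one variance row per root")

  key <- function(df) paste(df$genotype, df$root_id)
  # zone counts must agree between the retained-fit block and the
  # prediction block
  zc1 <- table(key(zones))
  zc2 <- table(key(preds))
  if (!identical(zc1[sort(names(zc1))], zc2[sort(names(zc2))]))
    fail("zone counts differ between the fit and prediction blocks")
  # linear-model limits must match the retained zone count (J - 1 limits)
  lin <- models[models$model == "linear", ]
  nlim <- ifelse(!is.na(lin$dzez_limit), 1L, 0L) +
    ifelse(!is.na(lin$ezmz_limit), 1L, 0L)
  names(nlim) <- key(lin)
  if (!all(nlim[names(zc1)] == as.integer(zc1) - 1L))
    fail("limit counts inconsistent with zone counts")

  ok_int <- function(lo, hi) all(is.na(lo) | is.na(hi) | lo <= hi)
  if (!ok_int(models$dzez_lo, models$dzez_hi) ||
      !ok_int(models$ezmz_lo, models$ezmz_hi) ||
      !ok_int(cont$rootward_lo, cont$rootward_hi) ||
      !ok_int(cont$shootward_lo, cont$shootward_hi))
    fail("an interval has low > high")
  both <- !is.na(models$dzez_limit) & !is.na(models$ezmz_limit)
  if (!all(models$dzez_limit[both] < models$ezmz_limit[both]))
    fail("zone limits not strictly increasing within a root")

  structure(list(models = models, zones = zones, predictions = preds,
                 continuity = cont),
            class = "root_tables")
}

#' @export
print.root_tables <- function(x, ...) {
  cat("<root_tables> 36 roots; ", nrow(x$zones), " retained zones, ",
      nrow(x$continuity), " limits\n", sep = "")
  invisible(x)
}

#' Per-root summaries derived from the reference tables
#'
#' Builds the meta-analysis variables from the packaged tables: division- and
#' elongation-zone lengths (zero when a zone is absent), the elongation-zone
#' slope, the cell lengths predicted at the two ends of the elongation-zone
#' line, the first-root-hair position and the per-zone residual standard
#' deviations.
#'
#' @param tables a [load_table_fixtures()] result.
#' @return A data frame with one row per root.
#' @export
fixture_summaries <- function(tables) {
  stopifnot(inherits(tables, "root_tables"))
  lin <- tables$models[tables$models$model == "linear", ]
  key <- paste(lin$genotype, lin$root_id)
  zget <- function(df, g, id, zone, col) {
    v <- df[[col]][df$genotype == g & df$root_id == id & df$zone == zone]
    if (length(v)) v[1] else NA_real_
  }
  out <- do.call(rbind, lapply(seq_len(nrow(lin)), function(i) {
    g <- lin$genotype[i]; id <- lin$root_id[i]
    dz_end <- zget(tables$zones, g, id, "DZ", "end_um")
    ez_end <- zget(tables$zones, g, id, "EZ", "end_um")
    has_dz <- !is.na(dz_end); has_ez <- !is.na(ez_end)
    n_zones <- sum(tables$zones$genotype == g & tables$zones$root_id == id)
    data.frame(genotype = g, root_id = id, root_type = lin$root_type[i],
               n_zones = n_zones,
               dz_length = if (has_dz) dz_end else 0,
               ez_length = if (has_ez) ez_end - (if (has_dz) dz_end else 0)
                           else 0,
               ez_slope = zget(tables$zones, g, id, "EZ", "slope_per_mm"),
               pred_dzez = zget(tables$predictions, g, id, "EZ",
                                "pred_start_um"),
               pred_ezmz = zget(tables$predictions, g, id, "EZ",
                                "pred_end_um"),
               first_hair_um = lin$first_hair_um[i],
               dz_sd = lin$dz_sd[i], ez_sd = lin$ez_sd[i],
               mz_sd = lin$mz_sd[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Approximate-continuity overlap per limit, from the reference tables
#'
#' Applies [continuity_overlap()] to the printed rootward and shootward
#' confidence intervals of every limit.
#'
#' @param tables a [load_table_fixtures()] result.
#' @return The continuity table with an added logical `overlap` column.
#' @export
fixture_continuity_overlaps <- function(tables) {
  stopifnot(inherits(tables, "root_tables"))
  ct <- tables$continuity
  ct$overlap <- vapply(seq_len(nrow(ct)), function(i)
    continuity_overlap(c(ct$rootward_lo[i], ct$rootward_hi[i]),
                       c(ct$shootward_lo[i], ct$shootward_hi[i])),
    logical(1))
  ct
}

#' First-root-hair match per root, from the reference tables
#'
#' Applies the matching rule (hair rootward of the EZ-MZ limit, or inside the
#' limit's uncertainty interval of the linear model) to every root. Roots
#' without an EZ-MZ limit give `NA`.
#'
#' @param tables a [load_table_fixtures()] result.
#' @return A data frame `genotype, root_id, hair_match`.
#' @export
fixture_hair_matches <- function(tables) {
  stopifnot(inherits(tables, "root_tables"))
  lin <- tables$models[tables$models$model == "linear", ]
  data.frame(genotype = lin$genotype, root_id = lin$root_id,
             hair_match = vapply(seq_len(nrow(lin)), function(i)
               .hair_match_rule(lin$first_hair_um[i], lin$ezmz_limit[i],
                                lin$ezmz_lo[i], lin$ezmz_hi[i]),
               NA),
             stringsAsFactors = FALSE)
}

#' Co-localization of linear and variance-model limits, from the tables
#'
#' For each printed limit, tests whether the uncertainty interval under the
#' piecewise linear model overlaps the interval of the matching limit under
#' the change-in-variance model fitted to the residual series. `NA` when the
#' variance model has no printed counterpart limit.
#'
#' @param tables a [load_table_fixtures()] result.
#' @return A data frame with one row per (root, limit) and a `colocalized`
#'   column.
#' @export
fixture_colocalization <- function(tables) {
  stopifnot(inherits(tables, "root_tables"))
  lin <- tables$models[tables$models$model == "linear", ]
  var <- tables$models[tables$models$model == "variance", ]
  rows <- list()
  for (i in seq_len(nrow(lin))) {
    v <- var[var$genotype == lin$genotype[i] & var$root_id == lin$root_id[i], ]
    for (lim in c("dzez", "ezmz")) {
      lo <- lin[[paste0(lim, "_lo")]][i]; hi <- lin[[paste0(lim, "_hi")]][i]
      if (is.na(lo)) next
      vlo <- v[[paste0(lim, "_lo")]][1]; vhi <- v[[paste0(lim, "_hi")]][1]
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = lin$genotype[i], root_id = lin$root_id[i],
        limit = if (lim == "dzez") "DZ-EZ" else "EZ-MZ",
        colocalized = if (is.na(vlo)) NA else
          colocalized(c(lo, hi), c(vlo, vhi)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
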