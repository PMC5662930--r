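#' Summarize a zoned root for the cohort meta-analysis
#'
#' Derives the per-root variables: division-zone length (position of the
#' DZ-EZ limit, 0 when the division zone is absent), elongation-zone length
#' (EZ-MZ limit minus DZ-EZ limit), the elongation-zone slope (um/mm), the
#' cell lengths predicted at the two ends of the elongation-zone line, the
#' per-zone residual standard deviations, the first-root-hair position and
#' the mean mature-zone diameter. A transition zone, when present, is
#' collapsed into the division zone.
#'
#' @param zoned a `zoned_root` from [select_final_segmentation()].
#' @param metadata optional [root_metadata()]; defaults to the metadata
#'   attached to the profile the root was fitted on.
#' @return A one-row data frame.
#' @export
summarize_root <- function(zoned, metadata = NULL) {
  stopifnot(inherits(zoned, "zoned_root"))
  labels <- zoned$labels
  seg <- zoned$segmentation
  lims <- zoned$limits
  # collapse TZ into DZ: the DZ-EZ limit is the limit preceding EZ
  k_ez <- which(labels == "EZ")
  k_mz <- which(labels == "MZ")
  dzez <- if (length(k_ez) && k_ez[1] > 1L)
    lims$position_um[k_ez[1] - 1L] else NA_real_
  ezmz <- if (length(k_ez) && k_ez[1] < length(labels))
    lims$position_um[k_ez[1]] else NA_real_
  has_dz <- any(labels %in% c("DZ", "TZ"))
  dz_length <- if (has_dz && !is.na(dzez)) dzez else 0
  ez_length <- if (length(k_ez)) {
    end <- if (!is.na(ezmz)) ezmz else seg$span[2]
    end - (if (has_dz && !is.na(dzez)) dzez else 0)
  } else 0
  ez_fit <- if (length(k_ez)) seg$fits[[k_ez[1]]] else NULL
  ez_start <- if (has_dz && !is.na(dzez)) dzez else seg$span[1]
  pred <- function(f, x) if (is.null(f)) NA_real_ else f$intercept + f$slope * x
  sd_of <- function(lab) {
    k <- which(labels == lab)
    if (length(k)) seg$fits[[k[1]]]$residual_sd else NA_real_
  }
  if (is.null(metadata)) metadata <- root_metadata()
  data.frame(root_id = zoned$root_id,
             genotype = metadata$genotype, root_type = metadata$root_type,
             n_zones = length(labels),
             dz_length = dz_length, ez_length = ez_length,
             dzez_limit = dzez, ezmz_limit = ezmz,
             ez_slope = if (is.null(ez_fit)) NA_real_ else ez_fit$slope_per_mm,
             pred_dzez = pred(ez_fit, ez_start),
             pred_ezmz = pred(ez_fit, if (!is.na(ezmz)) ezmz else seg$span[2]),
             first_hair_um = if (is.null(metadata$first_hair_um)) NA_real_
                             else metadata$first_hair_um,
             dz_sd = sd_of("DZ"), ez_sd = sd_of("EZ"), mz_sd = sd_of("MZ"),
             mz_diameter = if (length(metadata$diameters))
               mean(metadata$diameters) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Mean zone lengths for a set of root types
#'
#' Arithmetic means of division- and elongation-zone lengths over the roots
#' of the requested types. Roots lacking a zone contribute length 0, so that
#' cohort means reflect the whole type, not only roots where the zone was
#' detected.
#'
#' @param summaries data frame with columns `root_type`, `dz_length`,
#'   `ez_length` (from [summarize_root()] or [fixture_summaries()]).
#' @param types character vector of root types to pool (e.g. `c("A", "A'")`).
#' @return A list with `dz_mean`, `ez_mean` and `n`.
#' @export
type_zone_means <- function(summaries, types) {
  sub <- summaries[summaries$root_type %in% types, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no roots of type ", paste(types, collapse = "/"))
  list(dz_mean = mean(sub$dz_length), ez_mean = mean(sub$ez_length),
       n = nrow(sub))
}

#' Pearson correlation matrix of summary variables
#'
#' @param summaries per-root summary data frame.
#' @param variables column names to correlate (at least two, over at least
#'   three complete rows).
#' @return A correlation matrix with unit diagonal; variables with zero
#'   variance give `NA` entries and are flagged in the `"degenerate"`
#'   attribute.
#' @export
pairwise_correlations <- function(summaries, variables) {
  X <- summaries[, variables, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete rows")
  sds <- vapply(X, stats::sd, numeric(1))
  degenerate <- names(sds)[sds == 0]
  M <- suppressWarnings(stats::cor(as.matrix(X)))
  diag(M) <- 1
  attr(M, "degenerate") <- degenerate
  M
}

#' Principal component analysis of the cohort
#'
#' Correlation-matrix PCA (z-standardized active variables). Supplementary
#' variables are projected afterwards as correlations with the axis scores
#' and never influence the axes. Axis signs are fixed by forcing the
#' largest-magnitude loading of each axis to be positive.
#'
#' @param summaries per-root summary data frame.
#' @param active_variables column names entering the PCA.
#' @param supplementary_variables column names projected afterwards.
#' @return An object of class `pca_result` with `loadings`, `scores`,
#'   `explained` (variance fractions summing to 1) and `supplementary`
#'   (correlation of each supplementary variable with each axis).
#' @export
run_pca <- function(summaries, active_variables,
                    supplementary_variables = character(0)) {
  if (length(active_variables) < 2L) stop("need at least 2 active variables")
  cols <- c(active_variables, supplementary_variables)
  X <- summaries[, cols, drop = FALSE]
  cc <- stats::complete.cases(X[, active_variables, drop = FALSE])
  if (sum(cc) < nrow(X))
    warning("dropping ", nrow(X) - sum(cc), " incomplete row(s)")
  X <- X[cc, , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete rows")
  A <- scale(as.matrix(X[, active_variables, drop = FALSE]))
  pc <- stats::prcomp(A, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  # deterministic axis orientation
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  supp <- NULL
  if (length(supplementary_variables)) {
    S <- as.matrix(X[, supplementary_variables, drop = FALSE])
    supp <- suppressWarnings(stats::cor(S, pc$x, use = "pairwise.complete.obs"))
  }
  structure(list(loadings = pc$rotation, scores = pc$x, explained = expl,
                 supplementary = supp, n = nrow(X)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> n = ", x$n, "; explained variance: ",
      paste(sprintf("%.0f%%", 100 * x$explained[seq_len(min(3, length(x$explained)))]),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}
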