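#' Cell-length profile of a single root apex
#'
#' Bundles the ordered epidermal cell lengths of one root together with their
#' axial positions. Positions are center-of-cell coordinates in micrometres
#' measured from the root cap junction (origin of the longitudinal axis);
#' cells from several epidermal files are merged and ordered by position, not
#' by cell index, because files project independently onto the root axis.
#' Ties in position are kept in stable input order.
#'
#' @param positions numeric vector of axial positions (um from the root cap
#'   junction).
#' @param lengths numeric vector of cell lengths (um), strictly positive,
#'   same length as `positions`.
#' @param file_ids optional per-cell file label (any atomic vector).
#' @param root_id identifier for the root.
#' @param metadata optional [root_metadata()] record.
#' @return An object of class `cell_profile`: a list with elements
#'   `root_id`, `positions`, `lengths`, `file_ids`, `T` (cell count) and
#'   `metadata`.
#' @seealso [read_profile()], [generate_profile()]
#' @export
cell_profile <- function(positions, lengths, file_ids = NULL,
                         root_id = "root", metadata = NULL) {
  positions <- as.numeric(positions)
  lengths <- as.numeric(lengths)
  if (length(positions) != length(lengths))
    stop("`positions` and `lengths` must have the same length")
  if (length(lengths) < 1L)
    stop("a profile needs at least one cell")
  if (anyNA(positions) || anyNA(lengths))
    stop("positions and lengths must not contain NA")
  if (any(lengths <= 0))
    stop("cell lengths must be strictly positive")
  if (!is.null(file_ids) && length(file_ids) != length(positions))
    stop("`file_ids` must match the number of cells")
  ord <- order(positions)            # stable: ties keep input order
  structure(list(root_id = as.character(root_id)[1],
                 positions = positions[ord],
                 lengths = lengths[ord],
                 file_ids = if (is.null(file_ids)) NULL else file_ids[ord],
                 T = length(lengths),
                 metadata = metadata),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat("<cell_profile> ", x$root_id, ": ", x$T, " cells, positions ",
      round(min(x$positions), 1), "-", round(max(x$positions), 1), " um\n",
      sep = "")
  invisible(x)
}

#' Per-root metadata record
#'
#' @param genotype one of `"wild_type"`, `"rtcs"`, `"rum1"`, `"other"`.
#' @param root_type one of `"A"`, `"A'"`, `"B"`, `"C"`, `"unknown"`. Type A
#'   roots are long vigorous laterals, A' vigorous roots emerging from
#'   curvatures, B intermediate decelerating, C short arrested roots.
#' @param first_hair_um position (um) of the most rootward epidermal cell with
#'   an incipient root-hair bulge, or `NA`.
#' @param diameters up to two root diameter measurements (um) taken beyond the
#'   first root hair, or `NULL`.
#' @return A list of class `root_metadata`.
#' @export
root_metadata <- function(genotype = "other", root_type = "unknown",
                          first_hair_um = NA_real_, diameters = NULL) {
  genotype <- match.arg(genotype, c("wild_type", "rtcs", "rum1", "other"))
  root_type <- match.arg(root_type, c("A", "A'", "B", "C", "unknown"))
  first_hair_um <- as.numeric(first_hair_um)[1]
  if (!is.na(first_hair_um) && first_hair_um <= 0)
    stop("`first_hair_um` must be positive")
  if (!is.null(diameters)) {
    diameters <- as.numeric(diameters)
    if (length(diameters) > 2) stop("at most two diameter measurements")
    if (any(diameters <= 0, na.rm = TRUE)) stop("diameters must be positive")
  }
  structure(list(genotype = genotype, root_type = root_type,
                 first_hair_um = first_hair_um, diameters = diameters),
            class = "root_metadata")
}

#' Read a cell-length profile from CSV
#'
#' Expects columns `position_um` and `cell_length_um`, optionally `file_id`.
#' Rows with missing or non-positive cell length are dropped; the number of
#' dropped rows is recorded in the `"dropped"` attribute of the result. Cells
#' are sorted by position (stable for ties).
#'
#' @param path path to the CSV file.
#' @param root_id root identifier; defaults to the file name without
#'   extension.
#' @param metadata optional [root_metadata()] record attached to the profile.
#' @return A [cell_profile()] with attribute `dropped` (count of rows removed
#'   for non-positive length).
#' @export
read_profile <- function(path, root_id = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("position_um", "cell_length_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("profile CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("profile CSV contains no data rows: ", path)
  keep <- !is.na(df$cell_length_um) & df$cell_length_um > 0
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no rows with positive cell length in: ", path)
  if (is.null(root_id))
    root_id <- sub("\\.[^.]*$", "", basename(path))
  prof <- cell_profile(df$position_um, df$cell_length_um,
                       file_ids = if ("file_id" %in% names(df)) df$file_id,
                       root_id = root_id, metadata = metadata)
  attr(prof, "dropped") <- dropped
  prof
}

#' Write a cell-length profile to CSV
#'
#' Inverse of [read_profile()]: a round trip reproduces positions and lengths
#' exactly at stored precision.
#'
#' @param profile a [cell_profile()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cell_profile"))
  df <- data.frame(position_um = profile$positions,
                   cell_length_um = profile$lengths)
  if (!is.null(profile$file_ids)) df$file_id <- profile$file_ids
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-root metadata sidecar (CSV or JSON)
#'
#' The sidecar carries `root_id, genotype, root_type, first_hair_um,
#' diameter1_um, diameter2_um`.
#'
#' @param path CSV or JSON file.
#' @return A named list of [root_metadata()] records, keyed by `root_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!"root_id" %in% names(df)) stop("metadata needs a `root_id` column")
  get <- function(row, col, default = NA_real_)
    if (col %in% names(df)) row[[col]] else default
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    d <- c(get(row, "diameter1_um"), get(row, "diameter2_um"))
    d <- d[!is.na(d)]
    root_metadata(genotype = as.character(get(row, "genotype", "other")),
                  root_type = as.character(get(row, "root_type", "unknown")),
                  first_hair_um = get(row, "first_hair_um"),
                  diameters = if (length(d)) d)
  })
  names(out) <- df$root_id
  out
}
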