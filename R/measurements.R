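#' Moisture absorption as a percentage of dry weight
#'
#' Computes water uptake of an oven-dried specimen after reconditioning at
#' fixed humidity, expressed as a percentage of its dry weight:
#' `(wet - dry) / dry * 100`.
#'
#' A wet weight below the dry weight (evaporative loss between weighings) is
#' physically suspect but not impossible to record; it raises a warning and
#' the (negative) value is still returned.
#'
#' @param wet_weight Wet weight in grams. Vectorised.
#' @param dry_weight Dry weight in grams, strictly positive. Vectorised.
#' @return Numeric vector of moisture absorption percentages.
#' @examples
#' moisture_absorption(1.10, 1.00) # 10
#' @export
moisture_absorption <- function(wet_weight, dry_weight) {
  if (!is.numeric(wet_weight) || !is.numeric(dry_weight)) {
    stop("`wet_weight` and `dry_weight` must be numeric.", call. = FALSE)
  }
  if (any(!is.finite(dry_weight)) || any(dry_weight <= 0)) {
    stop("Invalid measurement: `dry_weight` must be finite and > 0.",
         call. = FALSE)
  }
  if (any(is.finite(wet_weight) & wet_weight < dry_weight)) {
    warning("wet weight below dry weight for some specimens ",
            "(evaporative loss?); negative moisture absorption returned.",
            call. = FALSE)
  }
  (wet_weight - dry_weight) / dry_weight * 100
}

specimen_columns <- c("specimen_id", "sheet_id", "dry_weight_g",
                      "wet_weight_g", "moisture_pct", "mode_skewness")

#' Load and validate a specimen measurement table
#'
#' Reads a CSV of veneer-disc measurements and returns a validated specimen
#' tibble. Required columns are `specimen_id` and `sheet_id`, plus
#' `dry_weight_g`, and either `moisture_pct` or `wet_weight_g` (moisture is
#' computed from wet/dry when absent), and either `mode_skewness` or
#' `image_path` (the brightness statistic is computed from each photograph
#' when only paths are given; relative paths are resolved against the CSV's
#' directory).
#'
#' @param path Path to a UTF-8 CSV file with a header row and dot decimal
#'   separator.
#' @param cutoff Background intensity cutoff passed to
#'   [image_mode_skewness()] when mode skewness must be computed from images.
#' @return A tibble with one row per specimen and columns `specimen_id`,
#'   `sheet_id`, `dry_weight_g`, `wet_weight_g` (NA when not supplied),
#'   `moisture_pct` and `mode_skewness`.
#' @seealso [write_specimens()], [build_feature_matrix()]
#' @export
load_specimens <- function(path, cutoff = 60) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("specimen_id", "sheet_id", "dry_weight_g")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("Missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!any(c("moisture_pct", "wet_weight_g") %in% names(raw))) {
    stop("Need either a `moisture_pct` or a `wet_weight_g` column.",
         call. = FALSE)
  }
  if (!any(c("mode_skewness", "image_path") %in% names(raw))) {
    stop("Need either a `mode_skewness` or an `image_path` column.",
         call. = FALSE)
  }
  dup <- unique(raw$specimen_id[duplicated(raw$specimen_id)])
  if (length(dup) > 0) {
    stop("Duplicate specimen_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }

  num_col <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      stop("Unparseable numeric in column `", col, "`, row ", bad[1],
           " (value \"", x[bad[1]], "\").", call. = FALSE)
    }
    out
  }

  spec <- tibble::tibble(
    specimen_id = raw$specimen_id,
    sheet_id = raw$sheet_id,
    dry_weight_g = num_col("dry_weight_g"),
    wet_weight_g = num_col("wet_weight_g"),
    moisture_pct = num_col("moisture_pct"),
    mode_skewness = num_col("mode_skewness")
  )
  if (any(is.na(spec$dry_weight_g))) {
    stop("Missing dry weight in row ", which(is.na(spec$dry_weight_g))[1],
         ".", call. = FALSE)
  }

  fill <- is.na(spec$moisture_pct)
  if (any(fill)) {
    if (any(is.na(spec$wet_weight_g[fill]))) {
      stop("Row ", which(fill & is.na(spec$wet_weight_g))[1],
           " has neither moisture_pct nor wet_weight_g.", call. = FALSE)
    }
    spec$moisture_pct[fill] <- moisture_absorption(
      spec$wet_weight_g[fill], spec$dry_weight_g[fill])
  }

  fill_ms <- is.na(spec$mode_skewness)
  if (any(fill_ms)) {
    if (!"image_path" %in% names(raw)) {
      stop("Row ", which(fill_ms)[1], " has no mode_skewness and the table ",
           "has no image_path column.", call. = FALSE)
    }
    paths <- raw$image_path[fill_ms]
    if (any(is.na(paths) | paths == "")) {
      stop("Row ", which(fill_ms)[is.na(paths) | paths == ""][1],
           " has neither mode_skewness nor image_path.", call. = FALSE)
    }
    base <- dirname(path)
    resolved <- ifelse(file.exists(paths), paths, file.path(base, paths))
    spec$mode_skewness[fill_ms] <- vapply(
      resolved, function(p) image_mode_skewness(p, cutoff = cutoff)$mode_skewness,
      numeric(1))
  }

  validate_specimens(spec)
  spec
}

validate_specimens <- function(spec) {
  stopifnot(is.data.frame(spec))
  if (any(!is.finite(spec$dry_weight_g)) || any(spec$dry_weight_g <= 0)) {
    stop("All dry weights must be finite and > 0.", call. = FALSE)
  }
  if (any(!is.finite(spec$moisture_pct))) {
    stop("All moisture absorption values must be finite.", call. = FALSE)
  }
  if (any(spec$moisture_pct < 0)) {
    warning("Negative moisture absorption present (wet weight below dry ",
            "weight).", call. = FALSE)
  }
  if (any(!is.finite(spec$mode_skewness))) {
    stop("All mode skewness values must be finite.", call. = FALSE)
  }
  invisible(spec)
}

#' Write a specimen table to CSV
#'
#' Writes the schema read by [load_specimens()]. Weights recorded to four
#' significant figures survive a write/reload round trip bit-identically.
#'
#' @param specimens Specimen tibble (see [load_specimens()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  keep <- intersect(specimen_columns, names(specimens))
  readr::write_csv(specimens[keep], path)
  invisible(path)
}

#' Assemble the specimen-by-property feature matrix
#'
#' Stacks the three measured properties into an N x 3 matrix in the fixed
#' column order (dry weight, moisture absorption, mode skewness), so that
#' partitions are reproducible across runs. With `standardize = TRUE`
#' (the default) each column is z-scored; the three properties live on
#' incommensurate scales (g, %, dimensionless) and the clustering distance is
#' an unweighted Euclidean one, so standardisation stops any single property
#' from dominating. Raw mode is retained for completeness.
#'
#' @param specimens Specimen tibble with columns `specimen_id`,
#'   `dry_weight_g`, `moisture_pct`, `mode_skewness`; at least two rows.
#' @param standardize Z-score each column? Default `TRUE`.
#' @return A numeric matrix with specimen ids as row names, columns
#'   `dry_weight_g`, `moisture_pct`, `mode_skewness`, and attributes
#'   `center` and `scale` (per-column, `NULL` when `standardize = FALSE`).
#' @export
build_feature_matrix <- function(specimens, standardize = TRUE) {
  cols <- c("dry_weight_g", "moisture_pct", "mode_skewness")
  stopifnot(all(c("specimen_id", cols) %in% names(specimens)))
  if (nrow(specimens) < 2) stop("Need at least 2 specimens.", call. = FALSE)
  x <- as.matrix(specimens[cols])
  storage.mode(x) <- "double"
  rownames(x) <- specimens$specimen_id
  if (anyNA(x)) stop("Feature matrix contains missing values.", call. = FALSE)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      stop("Cannot standardize zero-variance column(s): ",
           paste(cols[zero], collapse = ", "), call. = FALSE)
    }
    ctr <- colMeans(x)
    x <- scale(x, center = ctr, scale = sds)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    attr(x, "center") <- ctr
    attr(x, "scale") <- sds
  }
  x
}
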