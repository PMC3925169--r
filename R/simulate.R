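#' Simulate a sheet-structured specimen table
#'
#' Generates veneer-disc measurements with the hierarchical structure of
#' discs punched from source sheets: each sheet s gets a latent property
#' mean drawn from `Normal(global_means, between_sheet_sd^2)` per
#' coordinate, and each disc of that sheet draws its properties from
#' `Normal(sheet mean, within_sheet_sd^2)`. Coordinates are (dry weight in
#' g, moisture absorption in %, mode skewness). Nonpositive dry weights and
#' negative moisture values are resampled (not clipped), so column means are
#' not materially distorted.
#'
#' The defaults emulate a study set of 10 sheets with about 50 discs each:
#' a 60 mm x 1 mm softwood veneer disc of about 1.3 g dry weight, 15 %
#' moisture uptake after reconditioning at 28 C / 80 % RH, and a negative
#' (earlywood-dominated) mode skewness, with between-sheet spread three
#' times the within-sheet spread in every coordinate.
#'
#' @param n_sheets Number of source sheets S. Default 10.
#' @param discs_per_sheet Discs per sheet (scalar or length-S vector).
#'   Default 50.
#' @param global_means Length-3 vector of global property means
#'   (g, %, dimensionless). Default `c(1.3, 15, -0.5)`.
#' @param between_sheet_sd Length-3 vector of between-sheet standard
#'   deviations. Default `c(0.15, 1.5, 0.15)`.
#' @param within_sheet_sd Length-3 vector of within-sheet standard
#'   deviations. Default `c(0.05, 0.5, 0.05)`.
#' @param seed Integer seed; the table is byte-identical across runs given
#'   the same seed.
#' @return Specimen tibble (`specimen_id`, `sheet_id`, `dry_weight_g`,
#'   `wet_weight_g`, `moisture_pct`, `mode_skewness`) in the schema read by
#'   [load_specimens()]; `wet_weight_g` is back-filled from dry weight and
#'   moisture so the table round-trips through the wet/dry route too.
#' @export
simulate_specimens <- function(n_sheets = 10, discs_per_sheet = 50,
                               global_means = c(1.3, 15, -0.5),
                               between_sheet_sd = c(0.15, 1.5, 0.15),
                               within_sheet_sd = c(0.05, 0.5, 0.05),
                               seed = NULL) {
  stopifnot(n_sheets >= 1, all(discs_per_sheet >= 1),
            length(global_means) == 3,
            length(between_sheet_sd) == 3, length(within_sheet_sd) == 3,
            all(between_sheet_sd >= 0), all(within_sheet_sd >= 0))
  n_s <- if (length(discs_per_sheet) == 1) {
    rep(as.integer(discs_per_sheet), n_sheets)
  } else {
    stopifnot(length(discs_per_sheet) == n_sheets)
    as.integer(discs_per_sheet)
  }

  # draw from Normal(mean, sd) resampling values below `lower` (truncation by
  # resampling, not clipping); a mean far below the bound cannot yield valid
  # draws, so attempts are capped
  rnorm_above <- function(n, mean, sd, lower, what, strict = FALSE) {
    v <- stats::rnorm(n, mean, sd)
    for (attempt in 1:1000) {
      bad <- if (strict) v <= lower else v < lower
      if (!any(bad)) return(v)
      v[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    stop("Cannot draw valid ", what, ": mean ", format(mean),
         " lies too far below ", lower,
         "; reduce the standard deviations or raise the global mean.",
         call. = FALSE)
  }

  draw <- function() {
    sheet_means <- sapply(1:3, function(d) {
      lower <- c(0, 0, -Inf)[d]
      if (is.finite(lower)) {
        rnorm_above(n_sheets, global_means[d], between_sheet_sd[d], lower,
                    c("dry weight", "moisture absorption", "")[d],
                    strict = d == 1)
      } else {
        stats::rnorm(n_sheets, global_means[d], between_sheet_sd[d])
      }
    })
    if (is.null(dim(sheet_means))) sheet_means <- matrix(sheet_means, nrow = n_sheets)
    rows <- lapply(seq_len(n_sheets), function(s) {
      n <- n_s[s]
      vals <- sapply(1:3, function(d) {
        if (d == 1) {
          rnorm_above(n, sheet_means[s, d], within_sheet_sd[d], 0,
                      "dry weight", strict = TRUE)
        } else if (d == 2) {
          rnorm_above(n, sheet_means[s, d], within_sheet_sd[d], 0,
                      "moisture absorption")
        } else {
          stats::rnorm(n, sheet_means[s, d], within_sheet_sd[d])
        }
      })
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = n)
      tibble::tibble(
        specimen_id = sprintf("S%02d-D%03d", s, seq_len(n)),
        sheet_id = sprintf("S%02d", s),
        dry_weight_g = vals[, 1],
        moisture_pct = vals[, 2],
        mode_skewness = vals[, 3]
      )
    })
    dplyr::bind_rows(rows)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  out |>
    dplyr::mutate(
      wet_weight_g = .data$dry_weight_g * (1 + .data$moisture_pct / 100),
      .after = "dry_weight_g"
    )
}

#' Simulate a photographed veneer disc image
#'
#' Draws a circular disc of alternating concentric growth-ring bands — pale
#' earlywood and dark latewood — on a dark background, with optional
#' Gaussian pixel noise, as an 8-bit grayscale matrix. Band levels must
#' survive the background cutoff (default foreground floor 60) and the
#' background must fall below it.
#'
#' @param diameter_px Disc diameter in pixels. Default 200.
#' @param earlywood_level,latewood_level Band intensities in 60..255.
#'   Defaults 180 (pale) and 100 (dark).
#' @param ring_width_px Width of one earlywood band in pixels;
#'   `latewood_width_px` of one latewood band (defaults to
#'   `ring_width_px %/% 3`, at least 1 — earlywood is typically the wider
#'   band). The pattern alternates radially.
#' @param latewood_width_px See above.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   units), clipped to 0..255 after adding. Default 0.
#' @param background_level Background intensity, must be < 60. Default 20.
#' @param seed Seed for the noise.
#' @return Integer matrix of 8-bit intensities, `diameter_px` square.
#' @export
simulate_disc_image <- function(diameter_px = 200, earlywood_level = 180,
                                latewood_level = 100, ring_width_px = 9,
                                latewood_width_px = max(1, ring_width_px %/% 3),
                                noise_sd = 0, background_level = 20,
                                seed = NULL) {
  if (earlywood_level < 60 || latewood_level < 60 ||
      earlywood_level > 255 || latewood_level > 255) {
    stop("Band levels must lie in 60..255 so the foreground survives the ",
         "background cutoff.", call. = FALSE)
  }
  if (background_level >= 60 || background_level < 0) {
    stop("`background_level` must lie in 0..59.", call. = FALSE)
  }
  stopifnot(diameter_px >= 4, ring_width_px >= 1, latewood_width_px >= 1,
            noise_sd >= 0)
  r <- diameter_px / 2
  ctr <- (diameter_px + 1) / 2
  xy <- expand.grid(row = seq_len(diameter_px), col = seq_len(diameter_px))
  rad <- sqrt((xy$row - ctr)^2 + (xy$col - ctr)^2)
  period <- ring_width_px + latewood_width_px
  phase <- rad %% period
  level <- ifelse(phase < ring_width_px, earlywood_level, latewood_level)
  img <- ifelse(rad <= r, level, background_level)
  img <- matrix(img, diameter_px, diameter_px)
  if (noise_sd > 0) {
    add_noise <- function() img + stats::rnorm(length(img), 0, noise_sd)
    img <- if (is.null(seed)) add_noise() else
      withr::with_seed(as.integer(seed), add_noise())
  }
  out <- pmin(pmax(round(img), 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Write a gray8 matrix as an 8-bit grayscale PNG
#'
#' @param gray8 Integer matrix of intensities 0..255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_gray8_png <- function(gray8, path) {
  stopifnot(is.matrix(gray8), all(gray8 >= 0), all(gray8 <= 255))
  png::writePNG(gray8 / 255, path)
  invisible(path)
}
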