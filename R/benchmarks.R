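#' Hypergeometric null curve for a cluster composition
#'
#' Null probability of finding at least one same-sheet neighbour when the i
#' inspected neighbours are drawn from the cluster without replacement (an
#' urn model), ignoring the ordering produced by the clustering. For a focal
#' specimen from a sheet with K members in a cluster of length L, the
#' at-least-one probability at width i is
#' `1 - choose(L - K, i) / choose(L - 1, i)`; the curve averages this over
#' focal specimens (sheet s is focal with probability K_s / L). The
#' `"analytic"` mode evaluates this exactly via the hypergeometric pmf
#' ([stats::dhyper()]); the `"monte_carlo"` mode estimates the same quantity
#' from `n_draws` simulated focal-plus-neighbour draws.
#'
#' @param sheet_counts Named or unnamed vector of per-sheet specimen counts
#'   within the cluster; must sum to the cluster length L >= 2.
#' @param i_max Largest neighbourhood width; widths above L - 1 are clipped
#'   with a warning.
#' @param mode `"analytic"` (default) or `"monte_carlo"`.
#' @param n_draws Number of Monte-Carlo draws (default 8000).
#' @param seed Seed for the Monte-Carlo mode.
#' @param cluster Optional cluster index recorded in the output.
#' @return Tibble of class `wood_curves`: `kind`
#'   (`"hypergeometric_analytic"` or `"hypergeometric_mc"`), `cluster`,
#'   `width`, `probability_pct`, `cluster_length`, and for Monte-Carlo mode
#'   `n_draws` and `seed`.
#' @export
hypergeometric_curve <- function(sheet_counts, i_max = 10,
                                 mode = c("analytic", "monte_carlo"),
                                 n_draws = 8000, seed = NULL,
                                 cluster = NA_integer_) {
  mode <- match.arg(mode)
  k <- as.numeric(sheet_counts)
  if (any(k < 1) || any(k != round(k))) {
    stop("`sheet_counts` must be positive integers.", call. = FALSE)
  }
  L <- sum(k)
  if (L < 2) stop("Cluster length must be at least 2.", call. = FALSE)
  widths <- seq_len(i_max)
  if (i_max > L - 1) {
    warning("Widths above cluster_length - 1 clipped to ", L - 1, ".",
            call. = FALSE)
  }
  eff <- pmin(widths, L - 1)

  if (mode == "analytic") {
    # P(no same-sheet among i of the other L-1) = dhyper(0, K-1, L-K, i)
    p <- vapply(eff, function(i) {
      sum((k / L) * (1 - stats::dhyper(0, k - 1, L - k, i)))
    }, numeric(1))
    out <- tibble::tibble(
      kind = "hypergeometric_analytic", cluster = as.integer(cluster),
      width = widths, probability_pct = 100 * p, cluster_length = L
    )
  } else {
    if (n_draws < 1) stop("`n_draws` must be at least 1.", call. = FALSE)
    labels <- rep(seq_along(k), times = k)
    sim <- function() {
      hits <- matrix(FALSE, n_draws, length(widths))
      for (r in seq_len(n_draws)) {
        focal <- sample.int(L, 1)
        others <- sample(labels[-focal])  # a random without-replacement order
        same <- cumsum(others == labels[focal]) > 0
        hits[r, ] <- same[eff]
      }
      colMeans(hits)
    }
    p <- if (is.null(seed)) sim() else withr::with_seed(as.integer(seed), sim())
    out <- tibble::tibble(
      kind = "hypergeometric_mc", cluster = as.integer(cluster),
      width = widths, probability_pct = 100 * p, cluster_length = L,
      n_draws = n_draws, seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  }
  class(out) <- c("wood_curves", class(out))
  out
}

#' Hypergeometric null curves for every cluster of a partition
#'
#' With `composition = "uniform_pool"` (the default) each cluster's urn holds
#' the set's sheets in as-equal-as-possible counts summing to the cluster
#' length — the urn for a cluster whose sheet membership were assigned
#' uniformly at random, i.e. a null that carries no clustering signal at all
#' (it closely tracks the uniform bootstrap). With `composition = "cluster"`
#' the urn holds the cluster's own observed sheet counts, which conditions
#' the null on the composition the clustering achieved and so benchmarks
#' only the *ordering* within the cluster.
#'
#' @param lists `wood_cluster_lists` from [rank_and_split()].
#' @param specimens Specimen tibble with `specimen_id`, `sheet_id`.
#' @param composition `"uniform_pool"` (default) or `"cluster"`; see above.
#' @inheritParams hypergeometric_curve
#' @return Stacked [hypergeometric_curve()] tibble, one per cluster of
#'   length >= 2.
#' @export
hypergeometric_curves <- function(lists, specimens, i_max = 10,
                                  mode = c("analytic", "monte_carlo"),
                                  composition = c("uniform_pool", "cluster"),
                                  n_draws = 8000, seed = NULL) {
  mode <- match.arg(mode)
  composition <- match.arg(composition)
  df <- dplyr::left_join(lists,
                         dplyr::select(specimens, "specimen_id", "sheet_id"),
                         by = "specimen_id")
  n_sheets <- length(unique(specimens$sheet_id))
  comp <- df |>
    dplyr::count(.data$cluster, .data$sheet_id) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(counts = list(.data$n), .groups = "drop") |>
    dplyr::filter(vapply(.data$counts, sum, numeric(1)) >= 2)
  if (composition == "uniform_pool") {
    comp$counts <- lapply(comp$counts, function(k)
      balanced_composition(sum(k), n_sheets))
  }
  out <- purrr::pmap_dfr(comp, function(cluster, counts) {
    sd_i <- if (is.null(seed)) NULL else as.integer(seed) + cluster
    hypergeometric_curve(counts, i_max = i_max, mode = mode,
                         n_draws = n_draws, seed = sd_i, cluster = cluster)
  })
  class(out) <- c("wood_curves", class(out))
  out
}

# L specimens split over S sheets as evenly as possible (deterministic)
balanced_composition <- function(L, S) {
  k <- rep(L %/% S, S)
  r <- L - sum(k)
  if (r > 0) k[seq_len(r)] <- k[seq_len(r)] + 1
  k[k > 0]
}

#' Bootstrapped uniform null curves of matched cluster lengths
#'
#' For each experimental cluster length, draws `n_reps` synthetic lists whose
#' entries are sheet labels sampled uniformly at random from the full sheet
#' pool of the set, computes the neighbour curve of each, and averages the
#' curves over the repeats. This is the "same length as the experimental
#' data" uniform benchmark: with S sheets and one direct neighbour (width 1)
#' it converges to 100/S percent.
#'
#' @param cluster_lengths Integer vector of cluster lengths (>= 2 each);
#'   names (or position) become the cluster index.
#' @param sheet_pool Vector of distinct sheet labels (the set's sheets).
#' @param n_reps Bootstrap repeats to average. Default 8.
#' @param i_max Largest neighbourhood width. Default 10.
#' @param sided Window sidedness. Default `"one"`.
#' @param seed Seed; the draw is deterministic given it.
#' @return Tibble of class `wood_curves`: `kind = "uniform_bootstrap"`,
#'   `cluster`, `width`, `probability_pct` (averaged over repeats),
#'   `cluster_length`, `n_reps`, `seed`.
#' @export
uniform_bootstrap <- function(cluster_lengths, sheet_pool, n_reps = 8,
                              i_max = 10, sided = c("one", "two"),
                              seed = NULL) {
  sided <- match.arg(sided)
  if (length(sheet_pool) < 1) {
    stop("`sheet_pool` must contain at least one sheet.", call. = FALSE)
  }
  if (n_reps < 1) stop("`n_reps` must be at least 1.", call. = FALSE)
  if (any(cluster_lengths < 2)) {
    stop("All cluster lengths must be at least 2.", call. = FALSE)
  }
  pool <- unique(as.character(sheet_pool))
  idx <- if (is.null(names(cluster_lengths))) seq_along(cluster_lengths) else
    as.integer(names(cluster_lengths))

  run <- function() {
    purrr::map2_dfr(cluster_lengths, idx, function(L, cl) {
      reps <- purrr::map(seq_len(n_reps), function(r) {
        labels <- sample(pool, L, replace = TRUE)
        neighbor_curve(labels, i_max = i_max, sided = sided, cluster = cl)
      })
      avg <- dplyr::bind_rows(reps) |>
        dplyr::group_by(.data$cluster, .data$width) |>
        dplyr::summarise(probability_pct = mean(.data$probability_pct),
                         cluster_length = L, .groups = "drop")
      avg
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  out <- out |>
    dplyr::mutate(kind = "uniform_bootstrap", .before = 1) |>
    dplyr::mutate(n_reps = n_reps,
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                  sided = sided)
  class(out) <- c("wood_curves", class(out))
  out
}

#' Balanced bootstrap: identical cluster lengths, resampled sheet sequences
#'
#' Tests the influence of cluster length by reducing every cluster to the
#' same target length — the minimum experimental cluster length minus five —
#' and, for each of `n_reps` repeats, drawing that many sheet labels with
#' replacement from the cluster's own sheet-membership sequence. Neighbour
#' curves are averaged over the repeats.
#'
#' @param sheet_sequences Named list: per cluster, the sheet label sequence
#'   of its ordered list (as produced by [rank_and_split()] joined to the
#'   specimens). At least 2 clusters; the minimum length must exceed 5.
#' @param n_reps Bootstrap repeats to average. Default 10.
#' @param i_max Largest neighbourhood width. Default 10.
#' @param sided Window sidedness. Default `"one"`.
#' @param seed Seed.
#' @return Tibble of class `wood_curves`: `kind = "balanced_bootstrap"`,
#'   with `cluster_length` equal to the common target length.
#' @export
balanced_bootstrap <- function(sheet_sequences, n_reps = 10, i_max = 10,
                               sided = c("one", "two"), seed = NULL) {
  sided <- match.arg(sided)
  if (length(sheet_sequences) < 2) {
    stop("Need at least 2 clusters.", call. = FALSE)
  }
  lens <- lengths(sheet_sequences)
  if (min(lens) <= 5) {
    stop("Minimum cluster length must exceed 5 (target is min - 5).",
         call. = FALSE)
  }
  if (n_reps < 1) stop("`n_reps` must be at least 1.", call. = FALSE)
  target <- min(lens) - 5L
  idx <- if (is.null(names(sheet_sequences))) seq_along(sheet_sequences) else
    as.integer(names(sheet_sequences))

  run <- function() {
    purrr::map2_dfr(sheet_sequences, idx, function(seqs, cl) {
      reps <- purrr::map(seq_len(n_reps), function(r) {
        labels <- sample(as.character(seqs), target, replace = TRUE)
        neighbor_curve(labels, i_max = i_max, sided = sided, cluster = cl)
      })
      dplyr::bind_rows(reps) |>
        dplyr::group_by(.data$cluster, .data$width) |>
        dplyr::summarise(probability_pct = mean(.data$probability_pct),
                         cluster_length = target, .groups = "drop")
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  out <- out |>
    dplyr::mutate(kind = "balanced_bootstrap", .before = 1) |>
    dplyr::mutate(n_reps = n_reps,
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                  sided = sided)
  class(out) <- c("wood_curves", class(out))
  out
}

#' Analytic uniform-label null for the one-sided neighbour search
#'
#' Expected neighbour curve when every list entry's sheet is an independent
#' uniform draw from S sheets: a position with j successors inside the window
#' succeeds with probability `1 - (1 - 1/S)^j`, so
#' `P(i) = 100/L * sum_p (1 - (1 - 1/S)^min(i, L - p))`. At width 1 this is
#' `100 * (L - 1) / (L * S)`, i.e. 100/S percent up to the end-of-list
#' truncation term.
#'
#' @param n_sheets Number of sheets S.
#' @param cluster_length List length L.
#' @param i_max Largest neighbourhood width. Default 10.
#' @return Tibble `width`, `probability_pct`.
#' @export
uniform_neighbor_null <- function(n_sheets, cluster_length, i_max = 10) {
  stopifnot(n_sheets >= 1, cluster_length >= 2)
  q <- 1 - 1 / n_sheets
  p <- vapply(seq_len(i_max), function(i) {
    j <- pmin(i, cluster_length - seq_len(cluster_length))
    mean(1 - q^j)
  }, numeric(1))
  tibble::tibble(width = seq_len(i_max), probability_pct = 100 * p)
}
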