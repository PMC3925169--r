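#' Same-sheet indicator for one position in a cluster list
#'
#' Along a cluster's ordered specimen list, the indicator at a `position` is
#' 1 if any entry within the neighbourhood of width `width` shares the focal
#' entry's source sheet, 0 otherwise. The default window is one-sided: only
#' the `width` entries *after* the position are inspected (truncated at the
#' list end). A two-sided window additionally inspects the `width` entries
#' before the position.
#'
#' @param sheets Character (or factor) vector: the sheet label of each list
#'   entry, in list order.
#' @param position Integer position in the list (1-based).
#' @param width Neighbourhood width i, at least 1.
#' @param sided `"one"` (default, successors only) or `"two"`.
#' @return 0 or 1.
#' @export
same_sheet_indicator <- function(sheets, position, width, sided = c("one", "two")) {
  sided <- match.arg(sided)
  sheets <- as.character(sheets)
  n <- length(sheets)
  if (position < 1 || position > n) {
    stop("`position` out of range 1..", n, ".", call. = FALSE)
  }
  if (width < 1) stop("`width` must be at least 1.", call. = FALSE)
  lo <- if (sided == "two") max(1, position - width) else position + 1
  hi <- min(n, position + width)
  window <- if (lo > hi) integer(0) else setdiff(lo:hi, position)
  as.integer(any(sheets[window] == sheets[position]))
}

# cumulative success matrix: successes[p] after including offsets 1..i
neighbor_success_counts <- function(sheets, i_max, sided) {
  n <- length(sheets)
  succ <- rep(FALSE, n)
  counts <- integer(i_max)
  for (k in seq_len(i_max)) {
    if (k < n) {
      hit <- sheets[seq_len(n - k)] == sheets[seq(k + 1, n)]
      succ[seq_len(n - k)] <- succ[seq_len(n - k)] | hit
      if (sided == "two") {
        succ[seq(k + 1, n)] <- succ[seq(k + 1, n)] | hit
      }
    }
    counts[k] <- sum(succ)
  }
  counts
}

#' Neighbour-search curve for one cluster list
#'
#' For each neighbourhood width `i = 1..i_max`, the percentage of list
#' positions whose indicator ([same_sheet_indicator()]) is 1 — interpreted as
#' the cumulative probability of encountering at least one neighbour from the
#' same source sheet within an i-neighbourhood of the descending-membership
#' cluster list. Positions whose window is truncated by the list end still
#' count in the denominator (the percentage is relative to the full list
#' length), so the curve for a random ordering converges to the
#' without-replacement (hypergeometric) null.
#'
#' @param sheets Sheet label of each list entry, in list order. Length >= 2.
#' @param i_max Largest neighbourhood width. Default 10.
#' @param sided Window sidedness, `"one"` (default) or `"two"`.
#' @param cluster Optional cluster index recorded in the output.
#' @return Tibble: `cluster`, `width` (1..`i_max`), `probability_pct`
#'   (non-decreasing, in \[0, 100\]), `cluster_length`, `sided`.
#' @export
neighbor_curve <- function(sheets, i_max = 10, sided = c("one", "two"),
                           cluster = NA_integer_) {
  sided <- match.arg(sided)
  sheets <- as.character(sheets)
  n <- length(sheets)
  if (n < 2) {
    stop("Undefined curve: cluster list must have at least 2 entries.",
         call. = FALSE)
  }
  if (i_max < 1) stop("`i_max` must be at least 1.", call. = FALSE)
  counts <- neighbor_success_counts(sheets, i_max, sided)
  tibble::tibble(
    cluster = as.integer(cluster),
    width = seq_len(i_max),
    probability_pct = 100 * counts / n,
    cluster_length = n,
    sided = sided
  )
}

#' Neighbour-search curves for every cluster of a partition
#'
#' Joins sheet labels onto the ordered cluster lists and computes one
#' [neighbor_curve()] per cluster. Singleton clusters are dropped with a
#' warning (their curve is undefined).
#'
#' @param lists `wood_cluster_lists` tibble from [rank_and_split()].
#' @param specimens Specimen tibble carrying `specimen_id` and `sheet_id`.
#' @param i_max Largest neighbourhood width. Default 10.
#' @param sided Window sidedness, `"one"` (default) or `"two"`.
#' @param region `"all"` (default) to use full lists (unique + fuzzy
#'   regions), `"unique"` to restrict to the unique region.
#' @return Tibble of class `wood_curves` (one [neighbor_curve()] per
#'   cluster, stacked) with an extra `kind = "experimental"` column.
#' @export
cluster_curves <- function(lists, specimens, i_max = 10,
                           sided = c("one", "two"),
                           region = c("all", "unique")) {
  sided <- match.arg(sided)
  region <- match.arg(region)
  stopifnot(all(c("cluster", "rank", "specimen_id") %in% names(lists)),
            all(c("specimen_id", "sheet_id") %in% names(specimens)))
  df <- dplyr::left_join(
    lists, dplyr::select(specimens, "specimen_id", "sheet_id"),
    by = "specimen_id"
  )
  if (anyNA(df$sheet_id)) {
    stop("Some listed specimens have no sheet_id in `specimens`.",
         call. = FALSE)
  }
  if (region == "unique") df <- dplyr::filter(df, .data$region == "unique")
  df <- dplyr::arrange(df, .data$cluster, .data$rank)
  sizes <- dplyr::count(df, .data$cluster)
  if (any(sizes$n < 2)) {
    warning("Dropping singleton cluster(s): ",
            paste(sizes$cluster[sizes$n < 2], collapse = ", "),
            call. = FALSE)
    df <- dplyr::filter(df, !.data$cluster %in% sizes$cluster[sizes$n < 2])
  }
  out <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(~ neighbor_curve(.x$sheet_id, i_max = i_max,
                                      sided = sided, cluster = .y$cluster)) |>
    dplyr::bind_rows() |>
    dplyr::mutate(kind = "experimental", .before = 1)
  class(out) <- c("wood_curves", class(out))
  out
}

#' Compare median neighbour probabilities between curve groups
#'
#' The summary statistic of each curve is its median probability over the
#' widths. Normality of the medians is screened with the Lilliefors
#' (Kolmogorov-Smirnov) test; if not rejected in any group (at `alpha`), the
#' groups are compared with Fisher's one-way ANOVA, otherwise with the
#' Kruskal-Wallis rank test. Classical test internals are delegated to
#' [nortest::lillie.test()], [stats::oneway.test()] and
#' [stats::kruskal.test()].
#'
#' @param experimental,benchmark Curve tibbles (columns `cluster`, `width`,
#'   `probability_pct`), at least 2 curves each.
#' @param alpha Normality screening level. Default 0.001 (a permissive
#'   screen: only gross non-normality diverts to the rank test).
#' @param var_equal Assume equal group variances in the ANOVA (classical
#'   Fisher ANOVA). Default `TRUE`.
#' @return Object of class `wood_quality_test`: list with the chosen `test`,
#'   `statistic`, `df`, `p_value`, per-group medians and the Lilliefors
#'   screening results. Supports `tidy()` and `glance()`.
#' @export
compare_medians <- function(experimental, benchmark, alpha = 0.001,
                            var_equal = TRUE) {
  med_of <- function(curves) {
    stopifnot(all(c("cluster", "width", "probability_pct") %in% names(curves)))
    curves |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(median_pct = stats::median(.data$probability_pct),
                       .groups = "drop")
  }
  m1 <- med_of(experimental)
  m2 <- med_of(benchmark)
  if (nrow(m1) < 2 || nrow(m2) < 2) {
    stop("Need at least 2 curves per group.", call. = FALSE)
  }
  values <- c(m1$median_pct, m2$median_pct)
  group <- factor(rep(c("experimental", "benchmark"),
                      c(nrow(m1), nrow(m2))))
  if (stats::var(values) == 0) {
    warning("Degenerate test: all median probabilities identical.",
            call. = FALSE)
    res <- list(test = "none", statistic = NA_real_, df = c(1, length(values) - 2),
                p_value = NA_real_)
  } else {
    lil <- lapply(split(values, group), function(v) {
      if (length(v) >= 5 && stats::sd(v) > 0) nortest::lillie.test(v) else NULL
    })
    lil_p <- vapply(lil, function(t) if (is.null(t)) NA_real_ else t$p.value,
                    numeric(1))
    normal_ok <- all(is.na(lil_p) | lil_p > alpha)
    if (normal_ok) {
      fit <- stats::oneway.test(values ~ group, var.equal = var_equal)
      res <- list(test = "one-way ANOVA", statistic = unname(fit$statistic),
                  df = unname(c(fit$parameter[1], fit$parameter[2])),
                  p_value = fit$p.value, lilliefors_p = lil_p)
    } else {
      fit <- stats::kruskal.test(values ~ group)
      res <- list(test = "Kruskal-Wallis", statistic = unname(fit$statistic),
                  df = c(unname(fit$parameter), NA_real_),
                  p_value = fit$p.value, lilliefors_p = lil_p)
    }
  }
  res$group_medians <- tibble::tibble(
    group = group, cluster = c(m1$cluster, m2$cluster), median_pct = values
  )
  structure(res, class = "wood_quality_test")
}

#' @export
print.wood_quality_test <- function(x, ...) {
  cat("Median neighbour-probability comparison (", x$test, ")\n",
      "  statistic = ", format(x$statistic, digits = 4),
      ", df = ", paste(stats::na.omit(x$df), collapse = ", "),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname compare_medians
#' @param x A `wood_quality_test` object.
#' @param ... Unused.
#' @export
tidy.wood_quality_test <- function(x, ...) {
  x$group_medians
}

#' @rdname compare_medians
#' @export
glance.wood_quality_test <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic,
    df1 = x$df[1], df2 = x$df[2], p_value = x$p_value
  )
}

#' Plot neighbour-search curves
#'
#' One line per cluster, one panel (linetype/colour) per curve kind, in the
#' style of cumulative-probability-vs-neighbourhood-width figures.
#'
#' @param object A `wood_curves` tibble (experimental and/or benchmark
#'   curves; a `kind` column separates them).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wood_curves <- function(object, ...) {
  df <- object
  if (!"kind" %in% names(df)) df$kind <- "experimental"
  ggplot2::ggplot(df, ggplot2::aes(.data$width, .data$probability_pct,
                                   group = interaction(.data$kind, .data$cluster),
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(df$width)) +
    ggplot2::labs(x = "neighbourhood width i",
                  y = "P(>=1 same-sheet neighbour) [%]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wood_curves
#' @param curves A curves tibble.
#' @export
plot_neighbor_curves <- function(curves, ...) autoplot.wood_curves(curves, ...)
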