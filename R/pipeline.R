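`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run the full similarity-and-pairing pipeline
#'
#' End-to-end orchestration: feature assembly, fuzzy c-means clustering,
#' descending-membership cluster lists, experimental neighbour curves,
#' hypergeometric and bootstrapped-uniform null benchmarks (plus the
#' balanced identical-length bootstrap when feasible), the median comparison
#' test, and matched-pair selection. All result tables are returned and,
#' when `out_dir` is given, written as CSV together with a machine-readable
#' JSON run manifest (parameters, seeds, package version), so a rerun from
#' the manifest reproduces every number exactly.
#'
#' @param specimens Specimen tibble (see [load_specimens()]) or a path to a
#'   specimen CSV.
#' @param n_clusters,m,n_init Clustering parameters (see [fcm_fit()]).
#'   Defaults 6 and 2.
#' @param standardize Z-score the features? Default `TRUE`.
#' @param threshold Unique-region membership threshold. Default 0.5.
#' @param i_max Largest neighbourhood width. Default 10.
#' @param sided Neighbour window sidedness. Default `"one"`.
#' @param n_reps_uniform Uniform-bootstrap repeats. Default 8.
#' @param n_reps_balanced Balanced-bootstrap repeats. Default 10.
#' @param n_draws Monte-Carlo draws for the hypergeometric benchmark when
#'   `hyper_mode = "monte_carlo"`. Default 8000.
#' @param hyper_mode `"analytic"` (default) or `"monte_carlo"`.
#' @param hyper_composition Urn composition for the hypergeometric benchmark
#'   (see [hypergeometric_curves()]). Default `"uniform_pool"`.
#' @param max_distance Pairing distance threshold. Default `Inf`.
#' @param unique_only Pair only unique-region members? Default `FALSE`.
#' @param seed Master seed; stage seeds are derived from it and logged.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return (Invisibly when writing) a list with `specimens`, `features`,
#'   `fit` (`wood_fcm`), `lists`, `curves` (experimental + all benchmark
#'   curves stacked), `test` (`wood_quality_test`), `pairs` and `manifest`.
#' @export
run_pipeline <- function(specimens, n_clusters = 6, m = 2, n_init = 1,
                         standardize = TRUE, threshold = 0.5, i_max = 10,
                         sided = c("one", "two"), n_reps_uniform = 8,
                         n_reps_balanced = 10, n_draws = 8000,
                         hyper_mode = c("analytic", "monte_carlo"),
                         hyper_composition = c("uniform_pool", "cluster"),
                         max_distance = Inf, unique_only = FALSE,
                         seed = 1, out_dir = NULL) {
  sided <- match.arg(sided)
  hyper_mode <- match.arg(hyper_mode)
  hyper_composition <- match.arg(hyper_composition)
  seed <- as.integer(seed)
  stage_seeds <- list(fcm = seed, uniform = seed + 1000L,
                      balanced = seed + 2000L, hyper = seed + 3000L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  if (is.character(specimens)) {
    specimens <- stage("load", load_specimens(specimens))
  } else {
    stage("load", validate_specimens(specimens))
  }

  features <- stage("features",
                    build_feature_matrix(specimens, standardize = standardize))
  fit <- stage("cluster",
               fcm_fit(features, n_clusters = n_clusters, m = m,
                       seed = stage_seeds$fcm, n_init = n_init))
  lists <- stage("cluster", rank_and_split(fit, threshold = threshold))

  curves_exp <- stage("quality",
                      cluster_curves(lists, specimens, i_max = i_max,
                                     sided = sided))
  lengths_tbl <- curves_exp |>
    dplyr::distinct(.data$cluster, .data$cluster_length)
  lens <- stats::setNames(lengths_tbl$cluster_length,
                          lengths_tbl$cluster)
  pool <- unique(specimens$sheet_id)

  curves_hyper <- stage("benchmarks",
                        hypergeometric_curves(lists, specimens, i_max = i_max,
                                              mode = hyper_mode,
                                              composition = hyper_composition,
                                              n_draws = n_draws,
                                              seed = stage_seeds$hyper))
  curves_unif <- stage("benchmarks",
                       uniform_bootstrap(lens, pool,
                                         n_reps = n_reps_uniform,
                                         i_max = i_max, sided = sided,
                                         seed = stage_seeds$uniform))
  curves_bal <- NULL
  if (length(lens) >= 2 && min(lens) > 5) {
    seqs <- lists |>
      dplyr::left_join(dplyr::select(specimens, "specimen_id", "sheet_id"),
                       by = "specimen_id") |>
      dplyr::arrange(.data$cluster, .data$rank)
    seqs <- split(seqs$sheet_id, seqs$cluster)
    curves_bal <- stage("benchmarks",
                        balanced_bootstrap(seqs, n_reps = n_reps_balanced,
                                           i_max = i_max, sided = sided,
                                           seed = stage_seeds$balanced))
  }
  curves <- dplyr::bind_rows(curves_exp, curves_hyper, curves_unif, curves_bal)
  class(curves) <- c("wood_curves", class(tibble::tibble()))

  test <- stage("quality", compare_medians(curves_exp, curves_unif))
  pairs <- stage("pairs",
                 select_pairs(lists, features, max_distance = max_distance,
                              unique_only = unique_only))

  manifest <- list(
    package = "woodmatch",
    version = as.character(utils::packageVersion("woodmatch")),
    n_specimens = nrow(specimens),
    n_sheets = length(pool),
    parameters = list(
      n_clusters = n_clusters, m = m, n_init = n_init,
      standardize = standardize, threshold = threshold, i_max = i_max,
      sided = sided, n_reps_uniform = n_reps_uniform,
      n_reps_balanced = n_reps_balanced, n_draws = n_draws,
      hyper_mode = hyper_mode, hyper_composition = hyper_composition,
      max_distance = max_distance,
      unique_only = unique_only
    ),
    seeds = stage_seeds
  )

  result <- list(specimens = specimens, features = features, fit = fit,
                 lists = lists, curves = curves, test = test, pairs = pairs,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(result, out_dir))
    return(invisible(result))
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name))
  }
  w(result$specimens, "specimens.csv")
  partition <- result$lists |>
    dplyr::select(specimen_id = "specimen_id", assigned_cluster = "cluster",
                  membership = "membership", region = "region",
                  rank = "rank", dist_to_centroid = "dist_to_centroid")
  w(partition, "partition.csv")
  cen <- tibble::as_tibble(result$fit$centroids,
                           .name_repair = ~ colnames(result$fit$centroids)) |>
    dplyr::mutate(cluster = dplyr::row_number(), .before = 1)
  w(cen, "centroids.csv")
  w(result$curves, "curves.csv")
  w(result$pairs, "pairs.csv")
  report <- c(glance(result$test),
              list(group_medians = tidy(result$test)))
  jsonlite::write_json(report, file.path(out_dir, "test_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
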