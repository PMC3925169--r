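#' Fuzzy c-means cost function
#'
#' The objective minimised by fuzzy c-means:
#' \deqn{J = \sum_i \sum_j u_{ij}^m \, \lVert x_i - v_j \rVert_2^2}
#' where `u_ij` is the membership of specimen i in cluster j, `v_j` the
#' cluster centre and `m > 1` the fuzzifier.
#'
#' @param features N x d numeric feature matrix (see
#'   [build_feature_matrix()]).
#' @param memberships N x c membership matrix with rows summing to 1.
#' @param centroids c x d matrix of cluster centres.
#' @param m Fuzzifier, > 1.
#' @return The cost, a single non-negative number.
#' @export
fcm_cost <- function(features, memberships, centroids, m = 2) {
  features <- as.matrix(features)
  memberships <- as.matrix(memberships)
  centroids <- as.matrix(centroids)
  if (m <= 1) stop("Fuzzifier `m` must be > 1.", call. = FALSE)
  stopifnot(nrow(features) == nrow(memberships),
            ncol(memberships) == nrow(centroids),
            ncol(features) == ncol(centroids))
  sum(memberships^m * sq_dist(features, centroids))
}

# N x c matrix of squared Euclidean distances between rows of x and rows of v
sq_dist <- function(x, v) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * tcrossprod(x, v)
  pmax(d2, 0)
}

# membership update from squared distances; exact zero distance gives the
# point full membership in the coincident centroid(s), split equally
memberships_from_dist <- function(d2, m) {
  expo <- 1 / (m - 1)
  u <- 1 / (d2^expo * rowSums((1 / d2)^expo))
  zero <- d2 == 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fit fuzzy c-means to the specimen feature matrix
#'
#' Alternating optimisation of the fuzzy c-means cost ([fcm_cost()]): cluster
#' centres are recomputed as `u^m`-weighted means, memberships from
#' inverse-distance ratios with exponent `2/(m-1)`. Iteration stops when the
#' cost decreases by less than `tol` or after `max_iter` iterations. The
#' initial membership matrix is drawn at random (rows normalised) from a
#' seeded generator, so fits are exactly reproducible given `seed`. With
#' `n_init > 1` that many seeded starts are run and the fit with the lowest
#' final cost is kept.
#'
#' A specimen exactly on a centroid receives membership 1 for that centroid
#' and 0 elsewhere (split equally if it coincides with several centres).
#'
#' @param features N x d numeric matrix, N > `n_clusters`.
#' @param n_clusters Number of clusters c, at least 2. Default 6.
#' @param m Fuzzifier, > 1. Default 2.
#' @param tol Convergence tolerance on the cost decrease. Default 1e-6.
#' @param max_iter Iteration cap. Default 200.
#' @param seed Integer seed for the random initialisation (required for
#'   reproducibility; if `NULL` the current RNG state is used).
#' @param n_init Number of random restarts; best final cost wins. Default 1.
#' @return An object of class `wood_fcm`: list with `memberships` (N x c),
#'   `centroids` (c x d), `m`, `n_clusters`, `cost_trajectory`
#'   (non-increasing), `converged`, `n_iter`, `seed`, and the `features`
#'   used. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fcm_fit <- function(features, n_clusters = 6, m = 2, tol = 1e-6,
                    max_iter = 200, seed = NULL, n_init = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (m <= 1) stop("Fuzzifier `m` must be > 1.", call. = FALSE)
  if (n_clusters < 2) stop("`n_clusters` must be at least 2.", call. = FALSE)
  if (n <= n_clusters) {
    stop("Need more specimens than clusters (N > c).", call. = FALSE)
  }
  if (all(sq_dist(x, x[1, , drop = FALSE]) == 0)) {
    stop("Degenerate clustering problem: all specimens are identical.",
         call. = FALSE)
  }

  run_once <- function() {
    u <- matrix(stats::runif(n * n_clusters), n, n_clusters)
    u <- u / rowSums(u)
    traj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      um <- u^m
      v <- crossprod(um, x) / colSums(um)
      d2 <- sq_dist(x, v)
      u <- memberships_from_dist(d2, m)
      cost <- sum(u^m * d2)
      traj <- c(traj, cost)
      if (it > 1 && abs(traj[it - 1] - cost) < tol) {
        converged <- TRUE
        break
      }
    }
    list(u = u, v = v, traj = traj, converged = converged)
  }

  fits <- if (is.null(seed)) {
    replicate(n_init, run_once(), simplify = FALSE)
  } else {
    withr::with_seed(as.integer(seed),
                     replicate(n_init, run_once(), simplify = FALSE))
  }
  best <- fits[[which.min(vapply(fits, function(f) min(f$traj), numeric(1)))]]

  rownames(best$u) <- rownames(x)
  colnames(best$v) <- colnames(x)
  structure(
    list(memberships = best$u, centroids = best$v, m = m,
         n_clusters = n_clusters, cost_trajectory = best$traj,
         converged = best$converged, n_iter = length(best$traj),
         seed = seed, features = x),
    class = "wood_fcm"
  )
}

#' @export
print.wood_fcm <- function(x, ...) {
  cat("Fuzzy c-means fit: ", nrow(x$memberships), " specimens, ",
      x$n_clusters, " clusters, m = ", x$m, "\n",
      "  cost ", format(min(x$cost_trajectory), digits = 6), " after ",
      x$n_iter, " iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fuzzy c-means fit into a long membership table
#'
#' @param x A `wood_fcm` object.
#' @param ... Unused.
#' @return Tibble with columns `specimen_id`, `cluster`, `membership`.
#' @export
tidy.wood_fcm <- function(x, ...) {
  u <- x$memberships
  ids <- rownames(u)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(u)))
  tibble::tibble(
    specimen_id = rep(ids, times = ncol(u)),
    cluster = rep(seq_len(ncol(u)), each = nrow(u)),
    membership = as.numeric(u)
  )
}

#' One-row summary of a fuzzy c-means fit
#'
#' @param x A `wood_fcm` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_clusters`, `m`, `n_iter`, `final_cost`,
#'   `converged`.
#' @export
glance.wood_fcm <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$memberships), n_clusters = x$n_clusters, m = x$m,
    n_iter = x$n_iter, final_cost = min(x$cost_trajectory),
    converged = x$converged
  )
}

#' Rank specimens within clusters and split unique and fuzzy regions
#'
#' Assigns each specimen to the cluster of its maximal membership and orders
#' each cluster's list. Specimens with maximal membership at or above
#' `threshold` form the cluster's unique region, sorted by descending
#' membership; those below it form the fuzzy region (they could belong to
#' more than one cluster). The fuzzy region is sub-ordered by a second
#' distance function: Euclidean distance to the assigned centroid, nearest
#' first (`fuzzy_order = "distance"`, the default), or by descending
#' membership (`fuzzy_order = "membership"`, which keeps memberships
#' non-increasing along the whole list). All ties break by `specimen_id` so
#' the ordering is deterministic.
#'
#' @param partition A `wood_fcm` fit.
#' @param threshold Unique-region membership threshold. Default 0.5.
#' @param fuzzy_order `"distance"` or `"membership"` (see above).
#' @return Tibble of class `wood_cluster_lists`: columns `cluster`, `rank`,
#'   `specimen_id`, `membership`, `region` (`"unique"`/`"fuzzy"`),
#'   `dist_to_centroid`.
#' @export
rank_and_split <- function(partition, threshold = 0.5,
                           fuzzy_order = c("distance", "membership")) {
  stopifnot(inherits(partition, "wood_fcm"))
  fuzzy_order <- match.arg(fuzzy_order)
  u <- partition$memberships
  ids <- rownames(u)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(u)))
  assigned <- max.col(u, ties.method = "first")
  memb <- u[cbind(seq_len(nrow(u)), assigned)]
  d2 <- sq_dist(partition$features, partition$centroids)
  dist_cen <- sqrt(d2[cbind(seq_len(nrow(u)), assigned)])

  out <- tibble::tibble(
    cluster = assigned, specimen_id = ids, membership = memb,
    region = ifelse(memb >= threshold, "unique", "fuzzy"),
    dist_to_centroid = dist_cen
  )
  # deterministic ordering: unique region first (desc membership), then the
  # fuzzy region by the chosen second ordering
  key_main <- ifelse(out$region == "unique", 0L, 1L)
  key_second <- ifelse(
    out$region == "unique" | fuzzy_order == "membership",
    -out$membership, out$dist_to_centroid
  )
  ord <- order(out$cluster, key_main, key_second, out$specimen_id)
  out <- out[ord, ]
  out <- out |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", "rank", "specimen_id", "membership", "region",
                  "dist_to_centroid")
  class(out) <- c("wood_cluster_lists", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "fuzzy_order") <- fuzzy_order
  out
}

#' Plot a fuzzy c-means fit
#'
#' Scatter plot of two feature coordinates with cluster centres; unique-region
#' members are coloured by cluster, fuzzy-region members are grey.
#'
#' @param object A `wood_fcm` fit.
#' @param x_var,y_var Feature column names (defaults: first two columns).
#' @param threshold Unique-region membership threshold. Default 0.5.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wood_fcm <- function(object, x_var = NULL, y_var = NULL,
                              threshold = 0.5, ...) {
  feats <- object$features
  nm <- colnames(feats)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(feats)))
  if (is.null(x_var)) x_var <- nm[1]
  if (is.null(y_var)) y_var <- nm[2]
  lists <- rank_and_split(object, threshold = threshold)
  df <- tibble::as_tibble(feats, .name_repair = ~nm) |>
    dplyr::mutate(specimen_id = rownames(feats) %||%
                    as.character(dplyr::row_number())) |>
    dplyr::left_join(lists, by = "specimen_id")
  cen <- tibble::as_tibble(object$centroids, .name_repair = ~nm)
  ggplot2::ggplot(df, ggplot2::aes(.data[[x_var]], .data[[y_var]])) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$region == "fuzzy"),
      colour = "grey60", size = 1
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$region == "unique"),
      ggplot2::aes(colour = factor(.data$cluster)), size = 1.5
    ) +
    ggplot2::geom_point(data = cen, colour = "red", shape = 3, size = 4,
                        stroke = 1.5) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_minimal()
}
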