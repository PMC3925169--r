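#' Select matched specimen pairs within clusters
#'
#' The end product for the experimentalist: within each cluster (optionally
#' its unique region only), specimens are paired greedily by similarity —
#' repeatedly pair the two closest not-yet-paired specimens in (standardised)
#' feature space — until no remaining pair is closer than `max_distance`.
#' Each specimen appears in at most one pair. Ties in distance break by the
#' lexicographic specimen-id pair, so the result is deterministic and
#' invariant to input row order. Greedy matching is transparent and adequate
#' here because clusters are already homogeneous; an exhaustive
#' minimum-total-distance mode (`method = "optimal"`) is available for small
#' clusters.
#'
#' @param lists `wood_cluster_lists` tibble from [rank_and_split()].
#' @param features Feature matrix with specimen ids as row names (same
#'   standardisation as used for clustering).
#' @param max_distance Pairs farther apart than this are not formed; must be
#'   positive. Default `Inf` (pair everything possible).
#' @param unique_only Restrict pairing to unique-region members? Default
#'   `FALSE`.
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive
#'   minimum-total-distance matching; feasible for clusters of about a dozen
#'   specimens).
#' @return Tibble: `specimen_a`, `specimen_b` (a < b), `cluster`,
#'   `distance`, `both_unique_region`.
#' @export
select_pairs <- function(lists, features, max_distance = Inf,
                         unique_only = FALSE,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!is.numeric(max_distance) || length(max_distance) != 1 ||
      is.na(max_distance) || max_distance <= 0) {
    stop("`max_distance` must be a positive number.", call. = FALSE)
  }
  stopifnot(all(c("cluster", "specimen_id", "region") %in% names(lists)))
  feats <- as.matrix(features)
  if (is.null(rownames(feats))) {
    stop("`features` must carry specimen ids as row names.", call. = FALSE)
  }

  df <- if (unique_only) dplyr::filter(lists, .data$region == "unique") else lists
  out <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(members, key) {
      ids <- sort(members$specimen_id)
      if (length(ids) < 2) return(NULL)
      pairs <- match_within_cluster(feats[ids, , drop = FALSE],
                                    max_distance, method)
      if (is.null(pairs)) return(NULL)
      region <- stats::setNames(members$region, members$specimen_id)
      dplyr::mutate(
        pairs, cluster = key$cluster,
        both_unique_region = region[.data$specimen_a] == "unique" &
          region[.data$specimen_b] == "unique"
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(specimen_a = character(), specimen_b = character(),
                          cluster = integer(), distance = numeric(),
                          both_unique_region = logical()))
  }
  dplyr::select(out, "specimen_a", "specimen_b", "cluster", "distance",
                "both_unique_region")
}

match_within_cluster <- function(x, max_distance, method) {
  ids <- rownames(x)
  n <- length(ids)
  d <- as.matrix(stats::dist(x))
  if (method == "greedy") {
    avail <- rep(TRUE, n)
    res <- list()
    repeat {
      live <- which(avail)
      if (length(live) < 2) break
      sub <- d[live, live, drop = FALSE]
      diag(sub) <- Inf
      best <- min(sub)
      if (!is.finite(best) || best > max_distance) break
      # deterministic tie-break: first (row-major by sorted ids) minimal pair
      hit <- which(sub == best, arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      a <- live[hit[1, 1]]; b <- live[hit[1, 2]]
      res[[length(res) + 1]] <- tibble::tibble(
        specimen_a = ids[a], specimen_b = ids[b], distance = best)
      avail[c(a, b)] <- FALSE
    }
    if (length(res) == 0) return(NULL)
    dplyr::bind_rows(res)
  } else {
    best <- optimal_matching(d, max_distance)
    if (is.null(best) || nrow(best) == 0) return(NULL)
    tibble::tibble(specimen_a = ids[best[, 1]], specimen_b = ids[best[, 2]],
                   distance = d[best])
  }
}

# exhaustive minimum-total-distance matching, pairs above max_distance barred;
# maximises the number of pairs first, then minimises total distance
optimal_matching <- function(d, max_distance) {
  n <- nrow(d)
  best_pairs <- NULL
  best_key <- c(-Inf, Inf)  # (n_pairs, -total): maximise pairs, minimise total
  recurse <- function(remaining, pairs, total) {
    if (length(remaining) < 2) {
      key <- c(nrow(pairs) %||% 0, total)
      if (is.null(best_pairs) ||
          key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best_pairs <<- pairs
        best_key <<- key
      }
      return(invisible())
    }
    a <- remaining[1]
    # option: leave a unmatched
    recurse(remaining[-1], pairs, total)
    for (b in remaining[-1]) {
      if (d[a, b] <= max_distance) {
        recurse(setdiff(remaining, c(a, b)),
                rbind(pairs, c(a, b)), total + d[a, b])
      }
    }
  }
  recurse(seq_len(n), matrix(integer(0), 0, 2), 0)
  best_pairs
}
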