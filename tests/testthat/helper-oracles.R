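# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive every quantity by direct enumeration, never by
# calling the package functions they are used to check.

# neighbour curve by explicit (position, width) double loop
oracle_neighbor_curve <- function(sheets, i_max, sided = "one") {
  n <- length(sheets)
  p <- numeric(i_max)
  for (i in seq_len(i_max)) {
    hits <- 0
    for (pos in seq_len(n)) {
      window <- if (sided == "one") {
        seq(pos + 1, min(n, pos + i))
      } else {
        seq(max(1, pos - i), min(n, pos + i))
      }
      window <- window[window >= 1 & window <= n & window != pos]
      if (pos + 1 > min(n, pos + i) && sided == "one") window <- integer(0)
      if (any(sheets[window] == sheets[pos])) hits <- hits + 1
    }
    p[i] <- 100 * hits / n
  }
  p
}

# exact at-least-one-same-sheet probability for i neighbours drawn without
# replacement, by full enumeration of focal specimens and neighbour subsets
oracle_hypergeometric <- function(sheet_counts, i) {
  labels <- rep(seq_along(sheet_counts), times = sheet_counts)
  L <- length(labels)
  i <- min(i, L - 1)
  total <- 0
  for (focal in seq_len(L)) {
    others <- labels[-focal]
    subsets <- utils::combn(length(others), i)
    hit <- mean(apply(subsets, 2, function(s) any(others[s] == labels[focal])))
    total <- total + hit
  }
  100 * total / L
}

# exhaustive minimum-total-distance matching for <= 8 points: maximum number
# of pairs first, then minimum total distance, pairs above max_distance barred
oracle_optimal_matching_total <- function(d, max_distance = Inf) {
  n <- nrow(d)
  best <- list(npairs = -1, total = Inf)
  recurse <- function(remaining, npairs, total) {
    if (length(remaining) < 2) {
      if (npairs > best$npairs ||
          (npairs == best$npairs && total < best$total)) {
        best <<- list(npairs = npairs, total = total)
      }
      return(invisible())
    }
    a <- remaining[1]
    recurse(remaining[-1], npairs, total)
    for (b in remaining[-1]) {
      if (d[a, b] <= max_distance) {
        recurse(setdiff(remaining, c(a, b)), npairs + 1, total + d[a, b])
      }
    }
  }
  recurse(seq_len(n), 0, 0)
  best
}

# two tight, far-separated 3-D blobs
make_two_blobs <- function(n_per = 15, sep = 20, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per * 3, 0, 0.1), ncol = 3),
      matrix(rnorm(n_per * 3, sep, 0.1), ncol = 3)
    )
  })
  rownames(x) <- sprintf("sp%02d", seq_len(2 * n_per))
  colnames(x) <- c("dry_weight_g", "moisture_pct", "mode_skewness")
  x
}

# small well-formed specimen tibble
make_specimens <- function(n = 6, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    specimen_id = sprintf("sp%02d", seq_len(n)),
    sheet_id = rep(c("A", "B"), length.out = n),
    dry_weight_g = round(runif(n, 1, 2), 4),
    wet_weight_g = NA_real_,
    moisture_pct = round(runif(n, 10, 20), 4),
    mode_skewness = round(rnorm(n, -0.5, 0.2), 4)
  ))
}

# intensity_distribution from a raw intensity vector
dist_from_values <- function(values) {
  intensity_distribution(matrix(as.integer(values), nrow = 1))
}
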