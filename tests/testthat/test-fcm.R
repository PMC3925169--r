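test_that("fcm_cost equals a term-by-term summation oracle", {
  expect_equal(fcm_cost(matrix(c(1, 1), 1), matrix(1, 1, 1),
                        matrix(c(1, 1), 1), m = 2), 0)
  # 1 point at distance 2 from its sole centroid with u = 1: 1 * 2^2
  expect_equal(fcm_cost(matrix(c(0, 0), 1), matrix(1, 1, 1),
                        matrix(c(2, 0), 1), m = 2), 4)

  withr::with_seed(11, {
    x <- matrix(rnorm(10), 5, 2)
    v <- matrix(rnorm(6), 3, 2)
    u <- matrix(runif(15), 5, 3)
    u <- u / rowSums(u)
  })
  oracle <- 0
  for (i in 1:5) for (j in 1:3) {
    oracle <- oracle + u[i, j]^2 * sum((x[i, ] - v[j, ])^2)
  }
  expect_equal(fcm_cost(x, u, v, m = 2), oracle)
  expect_error(fcm_cost(x, u, v, m = 1), "m")
})

test_that("fcm_fit separates far blobs with near-crisp memberships", {
  x <- make_two_blobs(n_per = 15, sep = 20)
  fit <- fcm_fit(x, n_clusters = 2, seed = 4)
  expect_true(fit$converged)
  maxu <- apply(fit$memberships, 1, max)
  expect_true(all(maxu > 0.99))
  # blob mates share a cluster
  hard <- max.col(fit$memberships)
  expect_equal(length(unique(hard[1:15])), 1)
  expect_equal(length(unique(hard[16:30])), 1)
  expect_true(hard[1] != hard[16])
})

test_that("membership rows sum to 1 and the cost never increases", {
  for (seed in 1:5) {
    withr::with_seed(100 + seed, {
      x <- matrix(rnorm(90), 30, 3)
    })
    fit <- fcm_fit(x, n_clusters = 4, seed = seed)
    expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
    expect_true(all(diff(fit$cost_trajectory) <= 1e-12))
    # centroids lie inside the per-coordinate data range
    expect_true(all(fit$centroids >= matrix(apply(x, 2, min), 4, 3, byrow = TRUE)))
    expect_true(all(fit$centroids <= matrix(apply(x, 2, max), 4, 3, byrow = TRUE)))
  }
})

test_that("a specimen exactly on a centroid gets membership one there", {
  # the documented zero-distance rule of the membership update
  u <- woodmatch:::memberships_from_dist(matrix(c(0, 4, 9), 1), m = 2)
  expect_equal(as.numeric(u), c(1, 0, 0))
  # coincident with two centroids: split equally
  u2 <- woodmatch:::memberships_from_dist(matrix(c(0, 0, 9), 1), m = 2)
  expect_equal(as.numeric(u2), c(0.5, 0.5, 0))
  # and rows without zero distances are untouched inverse-distance ratios
  u3 <- woodmatch:::memberships_from_dist(matrix(c(1, 4), 1), m = 2)
  expect_equal(as.numeric(u3), c(4 / 5, 1 / 5))
})

test_that("fcm_fit matches the established reference implementation", {
  skip_if_not_installed("e1071")
  for (seed in 1:10) {
    withr::with_seed(200 + seed, {
      x <- matrix(rnorm(90, sd = 1), 30, 3) +
        matrix(rep(c(0, 4, 8), each = 10), 30, 3)
    })
    fit <- fcm_fit(x, n_clusters = 3, m = 2, seed = seed, tol = 1e-10)
    our_cost <- min(fit$cost_trajectory)
    # our cost recomputed from the returned partition agrees with fcm_cost
    expect_equal(fcm_cost(x, fit$memberships, fit$centroids, m = 2),
                 our_cost, tolerance = 1e-9)
    # stationarity: one more full update pair changes memberships < tol
    um <- fit$memberships^2
    v <- crossprod(um, x) / colSums(um)
    d2 <- woodmatch:::sq_dist(x, v)
    u_new <- woodmatch:::memberships_from_dist(d2, 2)
    expect_lt(max(abs(u_new - fit$memberships)), 1e-3)
    # independent reference seeded at our solution stays at the same optimum;
    # e1071 reports the objective normalised by the number of points
    ref <- e1071::cmeans(x, centers = fit$centroids, m = 2,
                         iter.max = 500, method = "cmeans")
    expect_lt(abs(ref$withinerror * nrow(x) - our_cost), 1e-6)
  }
})

test_that("fuzzifier limits: crisp as m -> 1+, uniform as m grows", {
  x <- make_two_blobs(n_per = 10, sep = 30, seed = 8)
  crisp <- fcm_fit(x, n_clusters = 2, m = 1.05, seed = 1)
  expect_true(all(apply(crisp$memberships, 1, max) > 0.999))
  soft <- fcm_fit(x, n_clusters = 2, m = 40, seed = 1)
  expect_true(all(abs(soft$memberships - 0.5) < 0.05))
})

test_that("row permutation yields the same clusters up to relabeling", {
  x <- make_two_blobs(n_per = 12, sep = 15, seed = 3)
  fit1 <- fcm_fit(x, n_clusters = 2, seed = 5)
  perm <- withr::with_seed(6, sample(nrow(x)))
  fit2 <- fcm_fit(x[perm, ], n_clusters = 2, seed = 5)
  # match centroids by nearest assignment
  d <- woodmatch:::sq_dist(fit1$centroids, fit2$centroids)
  matched <- apply(d, 1, which.min)
  expect_setequal(matched, 1:2)
  expect_lt(max(abs(fit1$centroids - fit2$centroids[matched, ])), 1e-6)
})

test_that("fcm_fit rejects invalid problems", {
  x <- make_two_blobs(4)
  expect_error(fcm_fit(x, n_clusters = 1), "at least 2")
  expect_error(fcm_fit(x, n_clusters = 8), "N > c")
  expect_error(fcm_fit(x, m = 1), "m")
  same <- matrix(1, 10, 3)
  expect_error(fcm_fit(same, n_clusters = 2), "Degenerate")
})

test_that("fits are deterministic given the seed", {
  x <- make_two_blobs(10, seed = 2)
  f1 <- fcm_fit(x, n_clusters = 2, seed = 99)
  f2 <- fcm_fit(x, n_clusters = 2, seed = 99)
  expect_identical(f1$memberships, f2$memberships)
  expect_identical(f1$cost_trajectory, f2$cost_trajectory)
})

test_that("rank_and_split orders, assigns and splits regions correctly", {
  x <- make_two_blobs(n_per = 8, sep = 10, seed = 7)
  fit <- fcm_fit(x, n_clusters = 2, seed = 3)
  lists <- rank_and_split(fit)
  expect_setequal(lists$specimen_id, rownames(x))
  expect_equal(anyDuplicated(lists$specimen_id), 0)
  # assignment is to the maximal membership
  for (r in sample(nrow(lists), 5)) {
    row <- lists[r, ]
    i <- match(row$specimen_id, rownames(fit$memberships))
    expect_equal(row$cluster, unname(which.max(fit$memberships[i, ])))
    expect_equal(row$membership, max(fit$memberships[i, ]))
  }
  # unique region: memberships non-increasing, all >= 0.5
  uo <- dplyr::filter(lists, region == "unique") |>
    dplyr::arrange(cluster, rank)
  by_cl <- split(uo$membership, uo$cluster)
  expect_true(all(vapply(by_cl, function(v) all(diff(v) <= 0), logical(1))))
  expect_true(all(uo$membership >= 0.5))
  expect_true(all(dplyr::filter(lists, region == "fuzzy")$membership < 0.5))
})

test_that("fuzzy region handling matches an independent sort oracle", {
  withr::with_seed(21, {
    x <- matrix(rnorm(120), 40, 3)  # diffuse data -> plenty of fuzzy members
  })
  rownames(x) <- sprintf("sp%02d", 1:40)
  fit <- fcm_fit(x, n_clusters = 3, seed = 17)
  # membership mode keeps the whole list non-increasing in membership
  lm <- rank_and_split(fit, fuzzy_order = "membership")
  memb_by_cl <- split(lm$membership[order(lm$cluster, lm$rank)],
                      lm$cluster[order(lm$cluster, lm$rank)])
  expect_true(all(vapply(memb_by_cl, function(v) all(diff(v) <= 1e-12),
                         logical(1))))
  # distance mode: within the fuzzy region, distance to centroid is sorted
  ld <- rank_and_split(fit, fuzzy_order = "distance")
  fz <- dplyr::filter(ld, region == "fuzzy") |> dplyr::arrange(cluster, rank)
  d_by_cl <- split(fz$dist_to_centroid, fz$cluster)
  expect_true(all(vapply(d_by_cl, function(v) all(diff(v) >= -1e-12),
                         logical(1))))
  # independent sort oracle for one cluster in membership mode
  u <- fit$memberships
  assigned <- max.col(u, ties.method = "first")
  cl <- 1
  ids <- rownames(u)[assigned == cl]
  memb <- u[assigned == cl, cl]
  oracle_order <- ids[order(-memb, ids)]
  got <- dplyr::filter(lm, cluster == cl) |> dplyr::arrange(rank)
  expect_identical(got$specimen_id, oracle_order)
})

test_that("a sub-0.5 specimen lands in the fuzzy region of its best cluster", {
  fit <- structure(list(
    memberships = matrix(c(0.4, 0.35, 0.25,
                           0.9, 0.05, 0.05,
                           0.1, 0.8, 0.1), 3, 3, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), NULL)),
    centroids = matrix(0, 3, 2), m = 2, n_clusters = 3,
    cost_trajectory = 1, converged = TRUE, n_iter = 1, seed = 1,
    features = matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  ), class = "wood_fcm")
  lists <- rank_and_split(fit)
  a <- dplyr::filter(lists, specimen_id == "a")
  expect_equal(a$cluster, 1)
  expect_equal(a$region, "fuzzy")
})

test_that("tidy and glance return the documented shapes", {
  x <- make_two_blobs(6, seed = 4)
  fit <- fcm_fit(x, n_clusters = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(x) * 2)
  expect_named(td, c("specimen_id", "cluster", "membership"))
  expect_equal(sum(td$membership), nrow(x))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$final_cost, min(fit$cost_trajectory))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
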