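test_that("zero within-sheet noise collapses each sheet to its latent mean", {
  spec <- simulate_specimens(n_sheets = 3, discs_per_sheet = 5,
                             within_sheet_sd = c(0, 0, 0), seed = 2)
  per_sheet <- split(spec, spec$sheet_id)
  for (s in per_sheet) {
    expect_equal(diff(range(s$dry_weight_g)), 0)
    expect_equal(diff(range(s$moisture_pct)), 0)
    expect_equal(diff(range(s$mode_skewness)), 0)
  }
})

test_that("with no between-sheet signal the pooled means hit the globals", {
  gm <- c(1.3, 15, -0.5)
  wsd <- c(0.05, 0.5, 0.05)
  spec <- simulate_specimens(n_sheets = 10, discs_per_sheet = 400,
                             global_means = gm,
                             between_sheet_sd = c(0, 0, 0),
                             within_sheet_sd = wsd, seed = 3)
  n <- nrow(spec)
  # law of large numbers: within 3 standard errors (mode skewness is not
  # truncated, weight/moisture truncation is negligible at these settings)
  for (d in 1:3) {
    col <- c("dry_weight_g", "moisture_pct", "mode_skewness")[d]
    expect_lt(abs(mean(spec[[col]]) - gm[d]), 3 * wsd[d] / sqrt(n))
  }
})

test_that("generated tables are valid, positive and byte-stable under a seed", {
  s1 <- simulate_specimens(n_sheets = 4, discs_per_sheet = 7, seed = 11)
  s2 <- simulate_specimens(n_sheets = 4, discs_per_sheet = 7, seed = 11)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 28)
  expect_equal(anyDuplicated(s1$specimen_id), 0)
  expect_true(all(s1$dry_weight_g > 0))
  expect_true(all(s1$moisture_pct >= 0))
  expect_true(all(s1$wet_weight_g >= s1$dry_weight_g))
  # the table round-trips through the measurement loader
  path <- withr::local_tempfile(fileext = ".csv")
  write_specimens(s1, path)
  expect_equal(nrow(load_specimens(path)), 28)
  # per-sheet disc counts can vary
  s3 <- simulate_specimens(n_sheets = 3, discs_per_sheet = c(2, 3, 4), seed = 1)
  expect_equal(as.numeric(table(s3$sheet_id)), c(2, 3, 4))
})

test_that("disc images have the stated geometry and band structure", {
  img <- simulate_disc_image(diameter_px = 200, earlywood_level = 180,
                             latewood_level = 100, ring_width_px = 9,
                             latewood_width_px = 3, background_level = 20)
  expect_true(is.integer(img))
  expect_equal(dim(img), c(200, 200))
  # foreground pixel count within 2% of the analytic disc area
  fg <- sum(img >= 60)
  expect_lt(abs(fg - pi * 100^2) / (pi * 100^2), 0.02)
  # only the three configured levels appear without noise
  expect_setequal(unique(as.vector(img)), c(20L, 100L, 180L))
  # wide pale bands, narrow dark bands -> negative mode skewness
  expect_lt(image_mode_skewness(img)$mode_skewness, 0)
})

test_that("degenerate single-level discs raise the undefined-skewness error", {
  img <- simulate_disc_image(diameter_px = 64, earlywood_level = 150,
                             latewood_level = 150, noise_sd = 0)
  expect_error(mode_skewness(background_cutoff(intensity_distribution(img))),
               "zero variance")
})

test_that("image configs that cannot survive the cutoff are rejected", {
  expect_error(simulate_disc_image(earlywood_level = 40), "cutoff")
  expect_error(simulate_disc_image(background_level = 80), "0..59")
  # noise is seeded and deterministic
  a <- simulate_disc_image(diameter_px = 64, noise_sd = 5, seed = 4)
  b <- simulate_disc_image(diameter_px = 64, noise_sd = 5, seed = 4)
  expect_identical(a, b)
})

test_that("strong sheet separation is recovered by the full pipeline", {
  skip_if_not_installed("mclust")
  # Between-sheet spread ten times the within-sheet spread.  Sheet means are
  # random draws, so two sheets can still land close by chance; the claim is
  # conditional on the sheets actually being far apart, so instances are
  # screened on the realised premise (minimum pairwise sheet-mean distance
  # of at least 5 within-sheet sd units) before recovery is asserted.
  wsd <- c(0.05, 0.5, 0.05)
  n_checked <- 0
  for (ds in 1:12) {
    spec <- simulate_specimens(n_sheets = 6, discs_per_sheet = 40,
                               between_sheet_sd = 10 * wsd,
                               within_sheet_sd = wsd, seed = ds)
    mu <- spec |>
      dplyr::group_by(sheet_id) |>
      dplyr::summarise(dplyr::across(c(dry_weight_g, moisture_pct,
                                       mode_skewness), mean),
                       .groups = "drop")
    sep <- min(dist(scale(as.matrix(mu[, -1]), center = FALSE, scale = wsd)))
    if (sep < 5) next
    n_checked <- n_checked + 1
    x <- build_feature_matrix(spec)
    fit <- fcm_fit(x, n_clusters = 6, seed = 72, n_init = 5)
    lists <- rank_and_split(fit)
    truth <- spec$sheet_id[match(lists$specimen_id, spec$specimen_id)]
    expect_gt(mclust::adjustedRandIndex(lists$cluster, truth), 0.95)
    # and the experimental curve beats the uniform null at every width
    exp_c <- cluster_curves(lists, spec, i_max = 10)
    lens_tbl <- dplyr::distinct(exp_c, cluster, cluster_length)
    unif <- uniform_bootstrap(stats::setNames(lens_tbl$cluster_length,
                                              lens_tbl$cluster),
                              unique(spec$sheet_id), n_reps = 8, i_max = 10,
                              seed = 73)
    e <- tapply(exp_c$probability_pct, exp_c$width, mean)
    u <- tapply(unif$probability_pct, unif$width, mean)
    expect_true(all(e > u))
  }
  expect_gte(n_checked, 3)  # the premise is the typical case, not a rarity
})

test_that("with no sheet signal, experimental and null curves are alike", {
  pvals <- vapply(1:10, function(r) {
    spec <- simulate_specimens(n_sheets = 6, discs_per_sheet = 25,
                               between_sheet_sd = c(0, 0, 0),
                               seed = 900 + r)
    x <- build_feature_matrix(spec)
    fit <- fcm_fit(x, n_clusters = 6, seed = 901 + r)
    lists <- rank_and_split(fit)
    exp_c <- cluster_curves(lists, spec, i_max = 10)
    lens_tbl <- dplyr::distinct(exp_c, cluster, cluster_length)
    unif <- uniform_bootstrap(stats::setNames(lens_tbl$cluster_length,
                                              lens_tbl$cluster),
                              unique(spec$sheet_id), n_reps = 8, i_max = 10,
                              seed = 902 + r)
    glance(compare_medians(exp_c, unif))$p_value
  }, numeric(1))
  # under the null the p-values should not concentrate at zero
  expect_gt(median(pvals), 0.05)
})
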