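test_that("rolling-ball subtraction flattens backgrounds and keeps small features", {
  flat <- matrix(7.3, 48, 48)
  expect_equal(subtract_background(flat, 12), matrix(0, 48, 48))

  # isolated bright spot, ball radius much larger than the spot: the spot
  # survives within 1% of the direct grey-level opening oracle
  img <- matrix(0, 60, 60)
  img[29:31, 29:31] <- 100
  radius <- 15
  out <- subtract_background(img, radius)
  scale <- radius / diff(range(img))
  oracle <- img - naive_ball_opening(img * scale, radius) / scale
  oracle[oracle < 0] <- 0
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_gt(out[30, 30], 0.99 * img[30, 30])

  # invariance under an additive constant offset
  expect_equal(subtract_background(img + 42, radius), out, tolerance = 1e-9)

  expect_error(subtract_background(img, 100), "smaller than the image")
  expect_error(subtract_background(img, 0), "positive")
})

test_that("alignment recovers known integer offsets with zero residual", {
  base <- triangle_profile()
  shifted <- lapply(c(0, 3, -2), function(s) {
    y <- base$intensity
    n <- length(y)
    out <- numeric(n)
    src <- seq_len(n) - s
    ok <- src >= 1 & src <= n
    out[ok] <- y[src[ok]]
    intensity_profile(out, base$pixel_size_um)
  })
  ps <- bin_and_align(shifted, seed = 42)  # seed picks profile 1 as reference
  expect_equal(ps$reference[[1]], 1L)
  expect_equal(ps$offset, c(0L, -3L, 2L))
  # zero residual after alignment
  avg <- average_profiles(ps)[[1]]
  sup <- attr(avg, "support")
  for (i in 2:3)
    expect_equal(shifted[[i]]$intensity[(sup[1]:sup[2]) - ps$offset[i]],
                 base$intensity[sup[1]:sup[2]])
  # aligning an aligned set yields zero additional offsets
  aligned <- lapply(seq_along(shifted), function(i) {
    y <- shifted[[i]]$intensity
    n <- length(y)
    src <- seq_len(n) - ps$offset[i]
    out <- numeric(n); ok <- src >= 1 & src <= n
    out[ok] <- y[src[ok]]
    intensity_profile(out, base$pixel_size_um)
  })
  ps2 <- bin_and_align(aligned, seed = 42)
  expect_true(all(ps2$offset == 0L))
})

test_that("a single profile aligns to itself with offset zero", {
  ps <- bin_and_align(list(triangle_profile()), seed = 1)
  expect_equal(ps$offset, 0L)
  avg <- average_profiles(ps)[[1]]
  expect_equal(avg$intensity, triangle_profile()$intensity)
})

test_that("alignment equals exhaustive search on noiseless shifted triangles", {
  a <- triangle_profile(n = 50, peak_at = 25)
  b_int <- c(0, a$intensity[-50])  # shifted by +1 px
  b <- intensity_profile(b_int, a$pixel_size_um)
  ps <- bin_and_align(list(a, b), max_shift_px = 10, seed = 42)
  # brute force over all shifts in +/-10 px
  brute <- sapply(-10:10, function(s)
    sd(b_int[pmax(1, 1 - s):min(50, 50 - s)] -
         a$intensity[pmax(1, 1 + s):min(50, 50 + s)]))
  expect_equal(ps$offset[2], (-10:10)[which.min(brute)])
  expect_equal(ps$offset[2], -1L)
})

test_that("profiles bin by length within +/- 0.64 um and average towards truth", {
  set.seed(99)
  short <- replicate(4, intensity_profile(runif(40), 0.107), simplify = FALSE)
  long <- replicate(3, intensity_profile(runif(80), 0.107), simplify = FALSE)
  ps <- bin_and_align(c(short, long), seed = 3)
  expect_equal(length(unique(ps$bin)), 2L)
  centred <- abs(vapply(ps$profiles, `[[`, numeric(1), "length_um") -
                   ps$bin * 2 * 0.64)
  expect_true(all(centred <= 0.64 + 1e-9))

  # noisy copies of a known comet shape: the bin mean approaches ground truth
  truth <- parametric_comet_profile(6, 100, 300, 0.4)
  n_rep <- 40
  noisy <- lapply(seq_len(n_rep), function(i)
    intensity_profile(pmax(0, truth$intensity + rnorm(length(truth$intensity), 0, 10)),
                      truth$pixel_size_um))
  avg <- average_profiles(bin_and_align(noisy, seed = 4))[[1]]
  sup <- attr(avg, "support")
  se <- 10 / sqrt(n_rep)
  expect_true(all(abs(avg$intensity - truth$intensity[sup[1]:sup[2]]) < 5 * se))
})

test_that("condition ratios divide region means by the low-condition average", {
  px <- 0.1
  mk <- function(level) intensity_profile(rep(level, 50), px)
  high <- list(mk(4), mk(8))
  low <- list(mk(2), mk(2))
  expect_equal(condition_ratio(high, low, c(0, 1)), c(2, 4))
  expect_equal(mean(condition_ratio(low, low, c(0, 1))), 1)
  expect_error(condition_ratio(high, list(mk(0)), c(0, 1)), "not positive")
})

test_that("condition ratios recover generator end and lattice ratios under noise", {
  set.seed(12)
  gen <- function(n, lattice_level, end_amplitude) {
    lapply(seq_len(n), function(i) {
      y <- parametric_comet_profile(6, lattice_level, end_amplitude, 0.3,
                                    pixel_size_um = 0.107)$intensity
      intensity_profile(pmax(0, y + rnorm(length(y), 0, 0.05 * max(y))), 0.107)
    })
  }
  low <- gen(25, 100, 200)
  high <- gen(25, 200, 800)  # true lattice ratio 2, end region dominated by 4x peak
  lat <- condition_ratio(high, low, c(2, 5))
  expect_equal(mean(lat), 2, tolerance = 0.1)
  end <- condition_ratio(high, low, c(0, 0.4))
  # noise has mean zero, so the expected ratio is the noiseless one
  noiseless_end_mean <- function(lattice_level, end_amplitude) {
    y <- parametric_comet_profile(6, lattice_level, end_amplitude, 0.3,
                                  pixel_size_um = 0.107)$intensity
    d <- (length(y):1 - 1) * 0.107
    mean(y[d <= 0.4])
  }
  true_end <- noiseless_end_mean(200, 800) / noiseless_end_mean(100, 200)
  expect_equal(mean(end), true_end, tolerance = 0.1)
})

test_that("condensate detection recovers count, centroids and axes", {
  # sharp (unblurred) disks: mask geometry equals the generating geometry
  ci <- synth_condensate_image(6, radii = c(5, 6, 7), tag_intensities = 0.5,
                               recruitment_factor = 1,
                               cfg = render_config(background = 0.01,
                                                   psf_fwhm_um = 0,
                                                   noise = "none", seed = 8))
  rec <- detect_condensates(ci$tag, 0.05)
  expect_equal(nrow(rec), 6L)
  truth <- ci$ground_truth
  ord <- vapply(seq_len(6), function(k)
    which.min((rec$cx - truth$centres[k, 1])^2 +
                (rec$cy - truth$centres[k, 2])^2), integer(1))
  expect_true(all(abs(rec$cx[ord] - truth$centres[, 1]) <= 0.5))
  expect_true(all(abs(rec$cy[ord] - truth$centres[, 2]) <= 0.5))
  expect_true(all(abs(rec$major[ord] / (2 * truth$radii) - 1) < 0.1))
  expect_true(all(rec$major >= rec$minor))

  # blank image and sub-threshold disks give empty results
  blank <- matrix(0.01, 128, 128)
  expect_equal(nrow(detect_condensates(blank, 0.05)), 0L)
  dim_img <- synth_condensate_image(3, radii = 6, tag_intensities = 0.03,
                                    cfg = render_config(background = 0,
                                                        noise = "none",
                                                        psf_fwhm_um = 0,
                                                        seed = 8))
  expect_equal(nrow(detect_condensates(dim_img$tag, 0.05)), 0L)
  expect_error(detect_condensates(matrix(2, 64, 64), 0.05), "normalized")
})

test_that("detected condensate count never increases with the threshold", {
  ci <- synth_condensate_image(8, radii = c(4, 6), tag_intensities = c(0.2, 0.5),
                               cfg = render_config(background = 0.01,
                                                   gaussian_sd = 0.01,
                                                   noise = "gaussian", seed = 14))
  counts <- vapply(c(0.03, 0.08, 0.15, 0.3, 0.6),
                   function(th) nrow(detect_condensates(ci$tag, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("client recruitment reads back the generator's recruitment factor", {
  ci <- synth_condensate_image(5, radii = 6, tag_intensities = 0.4,
                               recruitment_factor = 0.6,
                               cfg = render_config(background = 0.02,
                                                   noise = "none", seed = 21))
  rec <- client_recruitment(detect_condensates(ci$tag, 0.05), ci$client)
  expect_equal(rec$mean_client / rec$mean_tag, rep(0.6, 5), tolerance = 0.05)

  # degenerate clients: zero image, and the tag itself
  zeros <- client_recruitment(detect_condensates(ci$tag, 0.05),
                              matrix(0, 256, 256))
  expect_equal(zeros$mean_client, rep(0, 5))
  self <- client_recruitment(detect_condensates(ci$tag, 0.05), ci$tag)
  expect_equal(self$mean_client, self$mean_tag)
  expect_error(client_recruitment(detect_condensates(ci$tag, 0.05),
                                  matrix(0, 10, 10)), "geometry")
})
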