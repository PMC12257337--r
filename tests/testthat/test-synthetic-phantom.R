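test_that("rendered hole contrast matches a pixel-coverage oracle", {
  cfg <- simulation_config(snr = Inf, seed = 1,
                           slice_contrasts_pct = rep(5, 4))
  sim <- simulate_slice(cfg, 8)
  img <- sim$slice$intensities
  spacing <- 250 / 256
  # interior hole pixels (well inside the rim) for the three largest spokes
  for (k in 1:3) {
    holes <- sim$truth[sim$truth$spoke == k, ]
    for (i in seq_len(nrow(holes))) {
      h <- holes[i, ]
      rows <- row(img); cols <- col(img)
      d_px <- sqrt((rows - h$row_px)^2 + (cols - h$col_px)^2) * spacing
      interior <- d_px <= h$diameter_mm / 2 - spacing
      expect_gt(sum(interior), 0)
      ratio <- mean(img[interior]) / 0.6 - 1
      expect_equal(ratio, 0.05, tolerance = 0.002)
    }
  }
})

test_that("a zero-contrast noise-free interior is exactly uniform", {
  cfg <- simulation_config(snr = Inf, seed = 1, slice_contrasts_pct = rep(0, 4))
  sim <- simulate_slice(cfg, 9)
  img <- sim$slice$intensities
  rows <- row(img); cols <- col(img)
  d_mm <- sqrt((rows - 128.5)^2 + (cols - 128.5)^2) * 250 / 256
  interior <- d_mm <= 43
  expect_identical(length(unique(img[interior])), 1L)
})

test_that("simulation is seed-deterministic with seed-dependent noise", {
  cfg <- simulation_config(snr = 100, seed = 77)
  a <- simulate_slice(cfg, 10)$slice$intensities
  b <- simulate_slice(cfg, 10)$slice$intensities
  expect_identical(a, b)
  c2 <- simulate_slice(simulation_config(snr = 100, seed = 78),
                       10)$slice$intensities
  expect_false(identical(a, c2))
  # different seeds share the identical noiseless structure
  clean <- function(seed) {
    simulate_slice(simulation_config(snr = Inf, seed = seed),
                   10)$slice$intensities
  }
  expect_identical(clean(77), clean(78))
  # simulation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(simulate_slice(cfg, 8)); after <- runif(3)
  expect_identical(before, after)
})

test_that("rendered hole widths match the configured diameters", {
  # full width at half contrast along the spoke, spokes 1-5
  cfg <- simulation_config(snr = Inf, seed = 1,
                           slice_contrasts_pct = rep(8, 4))
  sim <- simulate_slice(cfg, 8)
  sl <- normalize_slice(sim$slice)
  mask <- segment_inner_disk(sl)
  layout <- phantom_layout()
  px_mm <- 250 / 256
  for (k in 1:5) {
    spec <- spoke_spec(k, 8, layout)
    raw <- cast_ray(sl, mask, spec$nominal_angle_deg)
    r <- (seq_along(raw$samples) - 1) * raw$step_mm
    bg <- median(raw$samples)
    amp <- max(raw$samples) - bg
    # first hole, centered at 12.5 mm
    near <- abs(r - 12.5) < 6
    above <- near & raw$samples > bg + amp / 2
    fwhm <- diff(range(r[above])) + raw$step_mm
    expect_lt(abs(fwhm - spec$diameter_mm), px_mm)
  }
})

test_that("the volume carries slices 7-11 with graded contrasts and truth", {
  vol <- simulate_volume(simulation_config(snr = 100, seed = 3))
  idx <- vapply(vol$slices, `[[`, integer(1), "slice_index_1based")
  expect_identical(idx, 7:11)
  expect_identical(nrow(vol$meta$truth[["7"]]), 0L)
  expect_identical(nrow(vol$meta$truth[["11"]]), 30L)
  contrasts <- vapply(vol$slices, function(s) s$meta$contrast_pct, numeric(1))
  expect_equal(contrasts, c(0, 1.4, 2.5, 3.6, 5.1))
})

test_that("measured image SNR tracks the configured SNR", {
  devs <- vapply(1:8, function(seed) {
    sim <- simulate_slice(simulation_config(snr = 150, seed = seed), 7)
    compute_snr(sim$slice) / 150 - 1
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.1)
})

test_that("rician noise yields a valid magnitude image at moderate SNR", {
  sim <- simulate_slice(simulation_config(snr = 100, seed = 5,
                                          noise_model = "rician"), 8)
  expect_true(all(sim$slice$intensities >= 0))
  expect_s3_class(segment_inner_disk(normalize_slice(sim$slice)), "disk_mask")
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(disk_radius_mm = 40))
  expect_error(simulation_config(snr = -5))
  expect_error(simulation_config(slice_contrasts_pct = c(1, 2, 3)))
  expect_error(simulate_slice(simulation_config(), 5), "7..11")
})
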