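test_that("the per-slice level is the family alpha Bonferroni-divided by 4", {
  cfg <- detection_config()
  expect_equal(cfg$per_slice_alpha, 0.0125)
  expect_equal(cfg$per_slice_alpha, cfg$alpha_total / cfg$n_lcod_slices)
  loose <- detection_config(alpha_total = 0.2, n_lcod_slices = 5)
  expect_equal(loose$per_slice_alpha, 0.04)
})

test_that("GLM recovers exact hole effects with zero residual", {
  spec <- spoke_spec(1, 8, phantom_layout())
  tpl <- build_spoke_template(spec, 45, 90)
  r <- tpl$radii_mm
  drift <- 0.3 + 0.002 * r - 1e-4 * r^2
  y <- drift + tpl$hole_indicators %*% c(0.05, 0.05, 0.05)
  prof <- structure(
    list(samples = as.vector(y), n_samples = 90L,
         sample_spacing_mm = 45 / 89, physical_length_mm = 45,
         angle_deg = spec$nominal_angle_deg, origin_rowcol_px = c(0, 0)),
    class = "radial_profile")
  fit <- fit_spoke_glm(prof, tpl)
  expect_equal(unname(fit$betas), rep(0.05, 3), tolerance = 1e-10)
  expect_identical(unname(fit$p_values), rep(0, 3))
  expect_identical(fit$dof, 84L)

  # pure quadratic, no holes: the nuisance absorbs everything
  prof$samples <- as.vector(drift)
  fit0 <- fit_spoke_glm(prof, tpl)
  expect_lt(max(abs(fit0$betas)), 1e-10)
  expect_lt(max(abs(fit0$t_stats)), 1e-6)
  expect_identical(unname(fit0$p_values), rep(1, 3))
})

test_that("GLM matches a normal-equations oracle on noisy profiles", {
  layout <- phantom_layout()
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(1:10, 1)
    spec <- spoke_spec(k, 8, layout)
    tpl <- build_spoke_template(spec, 45, 90)
    y <- 0.5 + tpl$hole_indicators %*% rep(0.03, 3) + rnorm(90, 0, 0.01)
    prof <- structure(
      list(samples = as.vector(y), n_samples = 90L,
           sample_spacing_mm = 45 / 89, physical_length_mm = 45,
           angle_deg = spec$nominal_angle_deg, origin_rowcol_px = c(0, 0)),
      class = "radial_profile")
    fit <- fit_spoke_glm(prof, tpl)
    oracle <- ols_oracle(template_design(tpl), as.vector(y))
    expect_equal(unname(fit$betas), oracle$betas[1:3], tolerance = 1e-8)
    expect_equal(unname(fit$t_stats), oracle$t[1:3], tolerance = 1e-8)
    expect_equal(unname(fit$p_values), oracle$p[1:3], tolerance = 1e-8)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
  }
})

test_that("BH step-up matches an exhaustive oracle", {
  # worked example: the largest k with p_(k) <= k q / m is 4
  expect_identical(benjamini_hochberg(c(0.001, 0.008, 0.039, 0.041), 0.05),
                   rep(TRUE, 4))
  expect_identical(benjamini_hochberg(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(benjamini_hochberg(0.01, 0.0125), TRUE)
  expect_identical(benjamini_hochberg(0.013, 0.0125), FALSE)
  expect_identical(benjamini_hochberg(numeric(0), 0.05), logical(0))
  # random p-value sets against the brute-force step-up
  set.seed(17)
  for (i in 1:200) {
    p <- round(runif(6), 2)  # rounding induces ties
    q <- runif(1, 0.01, 0.2)
    expect_identical(benjamini_hochberg(p, q), bh_oracle(p, q))
  }
})

test_that("the angle search recovers a known phantom rotation", {
  sim <- simulate_slice(simulation_config(snr = 300, seed = 21,
                                          rotation_deg = 4), 11)
  sl <- normalize_slice(sim$slice)
  mask <- segment_inner_disk(sl)
  sel <- vapply(1:10, function(k) {
    spec <- spoke_spec(k, 11)
    glm <- evaluate_spoke(sl, mask, spec)
    glm$angle_deg - spec$nominal_angle_deg
  }, numeric(1))
  expect_lte(abs(mean(sel) - 4), 1)
})

test_that("noise-free unrotated spokes select near-zero jitter", {
  seg <- noise_free_seg()
  for (k in c(1, 5)) {
    glm <- evaluate_spoke(seg$slice, seg$mask, spoke_spec(k, 11))
    expect_true(glm$jitter_samples %in% -1:1)
  }
})

test_that("a degenerate search equals the direct fit at the nominal angle", {
  seg <- noise_free_seg()
  spec <- spoke_spec(2, 11)
  cfg <- detection_config(angle_search_deg = 0, max_jitter_samples = 0)
  searched <- evaluate_spoke(seg$slice, seg$mask, spec, config = cfg)
  prof <- resample_profile(cast_ray(seg$slice, seg$mask,
                                    spec$nominal_angle_deg))
  tpl <- build_spoke_template(spec, prof$physical_length_mm, 90)
  direct <- fit_spoke_glm(prof, tpl)
  expect_equal(searched$betas, direct$betas)
  expect_equal(searched$t_stats, direct$t_stats)
  expect_identical(searched$jitter_samples, 0L)
})

test_that("a noise-free high-contrast slice scores 10 of 10", {
  sl <- get_slice(noise_free_volume(), 11)  # 5.1%, no noise
  res <- score_slice(sl)
  expect_identical(res$n_pass, 10L)
  expect_true(all(res$holes$pass))
})

test_that("partial spoke patterns score correctly in both scoring modes", {
  # spokes 1-6 at 5% contrast, 7-10 absent, no noise
  cfg <- simulation_config(snr = Inf, seed = 1, slice_contrasts_pct = rep(0, 4))
  sim <- simulate_slice(cfg, 8)
  img <- sim$slice$intensities
  layout <- phantom_layout()
  spacing <- 250 / 256
  ctr <- c(128.5, 128.5)
  for (k in 1:6) {
    ang <- 90 - (k - 1) * 36
    d <- hole_diameter(k, layout)
    for (r_mm in layout$hole_radial_centers_mm) {
      hc <- ctr + r_mm * acrlcod:::ray_direction(ang) / spacing
      img <- acrlcod:::add_hole(img, hc, d / 2, spacing, 0.6 * 0.05)
    }
  }
  sl <- phantom_slice(img, spacing, 8)
  res_all <- score_slice(sl, layout, detection_config())
  expect_identical(res_all$n_pass, 6L)
  res_consec <- score_slice(sl, layout,
                            detection_config(scoring_mode = "acr-consecutive"))
  expect_identical(res_consec$n_pass, 6L)
  expect_identical(res_all$spokes$spoke_pass, c(rep(TRUE, 6), rep(FALSE, 4)))
})

test_that("an unreadable slice is scored zero and flagged, not dropped", {
  set.seed(31)
  noise <- phantom_slice(matrix(rnorm(256^2), 256), 250 / 256, 8)
  expect_warning(res <- score_slice(noise), "scored 0")
  expect_true(res$failed)
  expect_identical(res$n_pass, 0L)
  expect_match(res$failure_message, "segmentation failure")
})

test_that("study scoring is bitwise deterministic", {
  vol <- simulate_volume(simulation_config(snr = 150, seed = 13))
  s1 <- score_volume(vol)
  s2 <- score_volume(vol)
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(glance(s1), glance(s2))
  expect_identical(s1$total, s2$total)
})

test_that("SNR measurement matches the simulated noise level", {
  cfg <- simulation_config(background_intensity = 0.8, snr = 200, seed = 19)
  sim <- simulate_slice(cfg, 7)
  snr <- compute_snr(sim$slice)
  expect_lt(abs(snr - 200) / 200, 0.1)
  # invariant to constant rescaling
  scaled <- phantom_slice(sim$slice$intensities * 3.7,
                          sim$slice$pixel_spacing_mm, 7)
  expect_equal(compute_snr(scaled), snr, tolerance = 1e-6)
  # noise-free image: guarded infinity
  clean <- simulate_slice(simulation_config(snr = Inf, seed = 19), 7)
  expect_warning(val <- compute_snr(clean$slice), "infinite")
  expect_identical(val, Inf)
})
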