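test_that("group_template is the voxelwise mean", {
  dims <- c(8L, 8L, 8L)
  v <- gm_volume(random_volume(dims, 1))
  expect_equal(group_template(list(v))$data, v$data)

  # symmetric pair about a constant averages to that constant
  c0 <- 0.4
  a <- random_volume(dims, 2) * 0.3
  v1 <- gm_volume(c0 + a); v2 <- gm_volume(c0 - a + 1e-9)
  expect_equal(group_template(list(v1, v2))$data,
               array(c0 + 5e-10, dims), tolerance = 1e-12)

  vols <- lapply(1:3, function(i) gm_volume(random_volume(dims, i + 10)))
  manual <- (vols[[1]]$data + vols[[2]]$data + vols[[3]]$data) / 3
  expect_equal(group_template(vols)$data, manual, tolerance = 1e-12)

  bad <- list(v, gm_volume(random_volume(c(8L, 8L, 10L), 3)))
  expect_error(group_template(bad), "common grid")
})

test_that("qc_correlations detects slab corruption and is affine-invariant", {
  dims <- c(8L, 8L, 48L)
  tmpl <- gm_volume(random_volume(dims, 4) + 0.1)
  r <- qc_correlations(tmpl, tmpl, n_slices = 20)
  expect_equal(c(r$r_whole, r$r_top, r$r_bottom), c(1, 1, 1))
  expect_true(r$passed)

  scaled <- gm_volume(2.5 * tmpl$data + 0.3)
  rs <- qc_correlations(scaled, tmpl, n_slices = 20)
  expect_equal(c(rs$r_whole, rs$r_top, rs$r_bottom), c(1, 1, 1), tolerance = 1e-12)

  # zeroed bottom slab: undefined bottom correlation -> flagged failure
  corrupted <- tmpl$data
  corrupted[, , 1:20] <- 0
  rc <- qc_correlations(gm_volume(corrupted), tmpl, n_slices = 20)
  expect_false(rc$passed)
  expect_match(rc$reason, "zero-variance")
  expect_lt(rc$r_whole, 1)

  # partially degraded (not constant) slab: r_bottom < r_whole
  deg <- tmpl$data
  set.seed(9)
  deg[, , 1:20] <- mean(tmpl$data) + 0.01 * runif(8 * 8 * 20)
  rd <- qc_correlations(gm_volume(deg), tmpl, n_slices = 20)
  expect_lt(rd$r_bottom, rd$r_whole)

  expect_error(qc_correlations(tmpl, tmpl, n_slices = 30), "2 \\* n_slices")
})

test_that("apply_qc partitions its input and catches generator corruptions", {
  ds <- small_dataset()
  qc <- apply_qc(ds$volumes)
  expect_identical(nrow(qc$reports), length(ds$volumes))
  expect_identical(length(qc$retained) + sum(!qc$reports$passed),
                   length(ds$volumes))
  # exactly the 4 corrupted volumes are discarded under default thresholds
  expect_identical(which(!qc$reports$passed), which(ds$records$qc_corrupted))

  all_in <- apply_qc(ds$volumes, thresholds = c(-1, -1, -1))
  # threshold -1 retains everything except undefined (zero-variance) slabs
  expect_identical(which(!all_in$reports$passed), which(ds$records$qc_corrupted))
  clean <- ds$volumes[!ds$records$qc_corrupted]
  none <- apply_qc(clean, thresholds = c(1, 1, 1))
  expect_identical(length(none$retained), sum(none$reports$r_whole == 1))
})

test_that("match_visits picks the nearest visit inside the window", {
  expect_identical(match_visits(100, 150), 1L)
  expect_identical(match_visits(100, 300), NA_integer_)
  # tie at +/-90 days resolves to the earlier visit
  expect_identical(match_visits(100, c(10, 190)), 1L)
  expect_identical(match_visits(100, c(190, 10)), 2L)
  expect_identical(match_visits(c(0, 500), c(80, 480), max_days = 90),
                   c(1L, 2L))
  expect_identical(match_visits(100, numeric(0)), NA_integer_)
  expect_identical(match_visits(100, 100, max_days = 0), 1L)
})

test_that("smooth_volume applies the FWHM-to-sigma rule and preserves mass", {
  # closed-form oracle: sigma = FWHM / (voxel * 2 sqrt(2 ln 2))
  expect_equal(fwhm_to_sigma(6, 1.5), 1.6986436, tolerance = 1e-6)

  v <- gm_volume(random_volume(c(16L, 16L, 16L), 5))
  expect_identical(smooth_volume(v, fwhm_mm = 0)$data, v$data)

  const <- gm_volume(array(0.7, c(16L, 16L, 16L)))
  expect_equal(smooth_volume(const, 6)$data, const$data, tolerance = 1e-12)

  # interior-supported volume: reflect boundary never clips mass
  interior <- array(0, c(24L, 24L, 24L))
  interior[9:16, 9:16, 9:16] <- random_volume(c(8L, 8L, 8L), 6)
  vi <- gm_volume(interior)
  sm <- smooth_volume(vi, fwhm_mm = 4)
  expect_equal(mean(sm$data), mean(vi$data), tolerance = 1e-10)
})

test_that("gaussian kernel taps are normalized and symmetric", {
  for (sd in c(0.8, 1.7, 2, 3)) {
    k <- gaussian_kernel1d(sd, truncate = 4)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, rev(k))
  }
})
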