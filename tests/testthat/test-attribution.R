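test_that("integrated gradients is exact for linear models at any step count", {
  dims <- c(6L, 6L, 6L)
  set.seed(41)
  w <- array(rnorm(prod(dims)), dim = dims)
  x <- array(runif(prod(dims)), dim = dims)
  model <- linear_scorer(w, b = 2)
  for (steps in c(1L, 7L, 64L)) {
    att <- integrated_gradients(model, x, n_steps = steps)
    expect_equal(att$data, w * x, tolerance = 1e-12)
  }
  # constant model: zero weights -> all-zero attribution
  flat <- integrated_gradients(linear_scorer(w * 0, b = 5), x, n_steps = 8)
  expect_true(all(flat$data == 0))
})

test_that("completeness error shrinks with the step count on a smooth net", {
  net <- mrinet(tiny_config(), seed = 17)
  # roughen the head so the function is genuinely nonlinear
  set.seed(2)
  net$heads[[1]]$W2 <- net$heads[[1]]$W2 + rnorm(64, sd = 0.3)
  x <- random_volume(c(16L, 16L, 16L), 3) + 0.2
  f_x <- csfproxy:::net_forward(net, list(x), train = FALSE)$pred[1, 1]
  f_0 <- csfproxy:::net_forward(net, list(x * 0), train = FALSE)$pred[1, 1]
  errs <- vapply(c(8L, 32L, 128L), function(steps) {
    att <- integrated_gradients(net, x, n_steps = steps)
    abs(sum(att$data) - (f_x - f_0)) / abs(f_x - f_0)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))  # monotone improvement
  expect_lt(errs[3], 0.005)
})

test_that("postprocessing smooths with a 9-voxel kernel and scales to [0, 1]", {
  # sd 2 truncated at 1.75 sd -> radius 4 -> 9 taps per axis
  expect_length(gaussian_kernel1d(2, truncate = 1.75), 9L)

  dims <- c(12L, 12L, 12L)
  set.seed(6)
  raw <- csfproxy:::attribution_volume(array(rnorm(prod(dims)), dims),
                                       subject_id = "s1", target = "abeta")
  out <- postprocess_attribution(raw)
  expect_identical(out$stage, "scaled")
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 1)
  expect_identical(min(out$data), 0)
  expect_identical(max(out$data), 1)

  # without smoothing, scaling is the plain min-max map
  m <- raw$data
  plain <- postprocess_attribution(raw, smoothing_sd = 0)
  expect_equal(plain$data, (m - min(m)) / (max(m) - min(m)), tolerance = 1e-12)

  const <- csfproxy:::attribution_volume(array(3, dims))
  expect_true(all(postprocess_attribution(const)$data == 0))
})

test_that("group means and pair differences follow the mean oracle", {
  dims <- c(6L, 6L, 6L)
  set.seed(12)
  mk <- function(s) array(rnorm(prod(dims), sd = s), dims)
  maps <- c(lapply(1:2, function(i) mk(1)), lapply(1:2, function(i) mk(2)),
            lapply(1:2, function(i) mk(1)), lapply(1:2, function(i) mk(3)))
  groups <- rep(c("CN", "sMCI", "pMCI", "AD"), each = 2)
  gd <- group_difference_maps(maps, groups)
  expect_equal(gd$group_means$CN, (maps[[1]] + maps[[2]]) / 2, tolerance = 1e-12)
  expect_equal(gd$pair_diffs[["CN-AD"]],
               gd$group_means$CN - gd$group_means$AD, tolerance = 1e-12)
  expect_named(gd$pair_diffs, c("CN-sMCI", "CN-pMCI", "CN-AD", "sMCI-pMCI",
                                "sMCI-AD", "pMCI-AD"))

  # identical groups difference to zero; singleton groups subtract directly
  same <- group_difference_maps(maps[c(1, 1, 1, 1)],
                                c("CN", "sMCI", "pMCI", "AD"))
  expect_true(all(same$pair_diffs[["sMCI-pMCI"]] == 0))
  expect_equal(same$pair_diffs[["CN-AD"]], maps[[1]] - maps[[1]])

  expect_error(group_difference_maps(maps[1:2], c("CN", "CN")), "empty group")
})

test_that("regional summaries respect the atlas partition", {
  atlas <- make_atlas(c(16L, 16L, 16L), n_rois = 4, n_signal = 2, seed = 31)
  ones <- array(1, c(16L, 16L, 16L))
  s <- regional_summary(ones, atlas)
  expect_identical(s$sum, as.numeric(s$n_voxels))
  expect_identical(s$mean, rep(1, 4))

  zero <- regional_summary(array(0, c(16L, 16L, 16L)), atlas)
  expect_identical(zero$sum, rep(0, 4))

  set.seed(44)
  rnd <- array(rnorm(16^3), c(16L, 16L, 16L))
  sr <- regional_summary(rnd, atlas)
  expect_equal(sum(sr$sum), sum(rnd[atlas$labels > 0]), tolerance = 1e-10)
})

test_that("pair ranking is scale invariant with alphabetical tie-breaks", {
  atlas <- make_atlas(c(12L, 12L, 12L), n_rois = 3, n_signal = 2, seed = 3)
  set.seed(9)
  diffs <- lapply(csfproxy:::GROUP_PAIRS, function(p) {
    array(rnorm(12^3), c(12L, 12L, 12L))
  })
  names(diffs) <- vapply(csfproxy:::GROUP_PAIRS, paste, "", collapse = "-")
  r1 <- rank_pair_magnitudes(diffs, atlas)
  r2 <- rank_pair_magnitudes(lapply(diffs, function(d) 7.3 * d), atlas)
  expect_identical(r1$pair, r2$pair)

  zeros <- lapply(diffs, function(d) d * 0)
  rz <- rank_pair_magnitudes(zeros, atlas)
  expect_identical(rz$pair, sort(names(diffs)))
  expect_true(all(rz$magnitude == 0))
})
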