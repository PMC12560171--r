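test_that("make_atlas is deterministic, disjoint and complete", {
  a1 <- make_atlas(c(32L, 32L, 32L), n_rois = 6, n_signal = 3, seed = 7)
  a2 <- make_atlas(c(32L, 32L, 32L), n_rois = 6, n_signal = 3, seed = 7)
  expect_identical(a1$labels, a2$labels)
  expect_identical(sum(a1$signal_flags), 3L)
  # labelled ellipsoids are pairwise disjoint by construction: every voxel
  # carries at most one label, so each region's voxel set is recoverable
  for (r in 1:6) expect_gte(sum(a1$labels == r), 1L)
  expect_setequal(unique(as.integer(a1$labels)), 0:6)

  single <- make_atlas(c(16L, 16L, 16L), n_rois = 1, n_signal = 1, seed = 3)
  expect_true(all(single$labels[single$labels != 0L] == 1L))

  expect_error(make_atlas(c(8L, 8L, 8L), n_rois = 200, n_signal = 1, seed = 1,
                          max_tries = 5),
               "could not place region")
})

test_that("noise-free cohorts have exactly ordered group means", {
  eff <- effect_config(severity_sd = 0,
                       marker_noise_sd = c(abeta = 0, ptau = 0, tau = 0),
                       age_sd = 0)
  rec <- sample_cohort(5, eff, seed = 2)
  means <- sapply(split(rec, rec$group), function(d) colMeans(d[MARKERS]))
  ab <- means["abeta", c("CN", "sMCI", "pMCI", "AD")]
  expect_true(all(diff(ab) < 0))
  for (m in c("ptau", "tau")) {
    expect_true(all(diff(means[m, c("CN", "sMCI", "pMCI", "AD")]) > 0))
  }
})

test_that("sampled cohorts reproduce the qualitative biomarker correlations", {
  rec <- sample_cohort(200, seed = 1)
  expect_gt(cor(rec$ptau, rec$tau), 0)
  expect_lt(cor(rec$abeta, rec$tau), 0)
  expect_lt(cor(rec$abeta, rec$ptau), 0)
  # all values inside the configured clamps
  cl <- effect_config()$clamps
  for (m in MARKERS) {
    expect_true(all(rec[[m]] >= cl[[m]][1] & rec[[m]] <= cl[[m]][2]))
  }
  expect_identical(nrow(sample_cohort(0)), 0L)
  expect_error(sample_cohort(-1), "non-negative")
})

test_that("severity gaps rank with the attribution-difference ordering", {
  sv <- effect_config()$severity_by_group
  gaps <- c("CN-AD" = sv[["AD"]] - sv[["CN"]],
            "sMCI-AD" = sv[["AD"]] - sv[["sMCI"]],
            "CN-pMCI" = sv[["pMCI"]] - sv[["CN"]],
            "sMCI-pMCI" = sv[["pMCI"]] - sv[["sMCI"]],
            "pMCI-AD" = sv[["AD"]] - sv[["pMCI"]],
            "CN-sMCI" = sv[["sMCI"]] - sv[["CN"]])
  expect_identical(names(sort(gaps, decreasing = TRUE)),
                   c("CN-AD", "sMCI-AD", "CN-pMCI", "sMCI-pMCI",
                     "pMCI-AD", "CN-sMCI"))
})

test_that("render_volume follows the severity forward model", {
  atlas <- make_atlas(c(16L, 16L, 16L), n_rois = 4, n_signal = 2, seed = 5)
  eff <- effect_config(image_noise_sd = 0)
  template <- csfproxy:::baseline_template(atlas)
  rec0 <- list(subject_id = "s0", session_id = "ses-01", severity = 0)
  v0 <- render_volume(rec0, atlas, eff, seed = 1)
  expect_equal(v0$data, template, tolerance = 1e-12)

  sig <- atlas$labels > 0 &
    array(atlas$signal_flags[pmax(atlas$labels, 1L)], dim = dim(atlas$labels))
  nonsig <- atlas$labels > 0 & !sig
  v1 <- render_volume(list(subject_id = "a", session_id = "s", severity = 1),
                      atlas, eff, seed = 1)
  v2 <- render_volume(list(subject_id = "a", session_id = "s", severity = 2),
                      atlas, eff, seed = 1)
  expect_lt(mean(v2$data[sig]), mean(v1$data[sig]))
  expect_equal(mean(v2$data[nonsig]), mean(v1$data[nonsig]), tolerance = 1e-12)

  # seed determinism with noise on
  effn <- effect_config()
  va <- render_volume(rec0, atlas, effn, seed = 9)
  vb <- render_volume(rec0, atlas, effn, seed = 9)
  expect_identical(va$data, vb$data)
})

test_that("generate_dataset corrupts the requested fraction and round-trips", {
  ds <- small_dataset()  # 40 subjects, qc_fail_fraction = 0.1
  expect_identical(sum(ds$records$qc_corrupted), 4L)
  zeroed <- vapply(ds$volumes, function(v) all(v$data[, , 1:20] == 0), logical(1))
  expect_identical(which(zeroed), which(ds$records$qc_corrupted))

  clean <- generate_dataset(3, qc_fail_fraction = 0, seed = 11,
                            grid_dims = c(16L, 16L, 16L), n_rois = 3,
                            n_signal = 1)
  expect_false(any(vapply(clean$volumes,
                          function(v) all(v$data[, , 1:8] == 0), logical(1))))

  # same seed -> byte-identical phenotype CSV
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(2, seed = 7, grid_dims = c(16L, 16L, 16L)), d1)
  write_dataset(generate_dataset(2, seed = 7, grid_dims = c(16L, 16L, 16L)), d2)
  expect_identical(readBin(file.path(d1, "phenotypes.csv"), "raw", 1e6),
                   readBin(file.path(d2, "phenotypes.csv"), "raw", 1e6))
})
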