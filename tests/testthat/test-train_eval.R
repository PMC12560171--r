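make_records <- function(n_per_group, sessions = 1L) {
  rec <- data.frame(
    subject_id = rep(sprintf("s%03d", seq_len(4 * n_per_group)), each = sessions),
    group = rep(rep(c("CN", "sMCI", "pMCI", "AD"), each = n_per_group),
                each = sessions),
    stringsAsFactors = FALSE
  )
  rec$session_id <- paste0("ses-", sequence(rep(sessions, 4 * n_per_group)))
  rec
}

test_that("monte_carlo_splits partitions subjects without leakage", {
  rec <- make_records(20)
  s1 <- monte_carlo_splits(rec, n_repetitions = 3, seed = 9)
  s2 <- monte_carlo_splits(rec, n_repetitions = 3, seed = 9)
  expect_identical(s1, s2)
  for (sp in s1) {
    expect_length(intersect(sp$train, sp$val), 0L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_length(intersect(sp$val, sp$test), 0L)
    expect_setequal(c(sp$train, sp$val, sp$test), unique(rec$subject_id))
  }
})

test_that("splits are stratified with exact rounded counts", {
  rec <- data.frame(subject_id = sprintf("s%03d", 1:200),
                    group = rep(c("CN", "AD"), each = 100))
  sp <- monte_carlo_splits(rec, n_repetitions = 5,
                           fractions = c(train = 0.7, val = 0.1, test = 0.2),
                           seed = 4)
  for (s in sp) {
    test_groups <- rec$group[rec$subject_id %in% s$test]
    expect_identical(sum(test_groups == "CN"), 20L)
    expect_identical(sum(test_groups == "AD"), 20L)
    expect_length(s$val, 20L)
    expect_length(s$train, 140L)
  }
})

test_that("multi-session subjects stay in one partition", {
  rec <- make_records(10, sessions = 3L)
  sp <- monte_carlo_splits(rec, n_repetitions = 2, seed = 2)[[1]]
  for (sid in unique(rec$subject_id)) {
    hits <- c(sid %in% sp$train, sid %in% sp$val, sid %in% sp$test)
    expect_identical(sum(hits), 1L)
  }
  # session rows of one subject all resolve to the same partition
  expect_identical(nrow(unique(rec[rec$subject_id %in% sp$test,
                                   c("subject_id", "group")])),
                   length(sp$test))
})

test_that("undersized strata fail loudly", {
  rec <- data.frame(subject_id = c("a", "b", "c", "d"),
                    group = c("CN", "CN", "CN", "AD"))
  expect_error(monte_carlo_splits(rec, n_repetitions = 1, seed = 1),
               "stratum AD")
})

test_that("regression metrics match their closed forms", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_identical(unlist(m), c(mae = 0, mse = 0, ev = 1, r2 = 1))

  # predicting the target mean: r2 and ev both exactly 0
  m2 <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_identical(m2$r2, 0)
  expect_identical(m2$ev, 0)

  # direct evaluation: e = (-1, -1, 3), SST = 32/3
  m3 <- regression_metrics(c(0, 0, 4), c(1, 1, 1))
  expect_equal(m3$mae, 5 / 3, tolerance = 1e-12)
  expect_equal(m3$mse, 11 / 3, tolerance = 1e-12)
  expect_equal(m3$r2, -1 / 32, tolerance = 1e-12)
  expect_equal(m3$ev, 0, tolerance = 1e-12)

  const <- regression_metrics(c(2, 2, 2), c(1, 2, 3))
  expect_true(is.na(const$r2) && is.na(const$ev))
  expect_equal(const$mae, 2 / 3, tolerance = 1e-12)
})

test_that("r2 never exceeds ev", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    y <- rnorm(n)
    p <- rnorm(n, mean = sample(c(-2, 0, 2), 1))
    m <- regression_metrics(y, p)
    expect_lte(m$r2, m$ev + 1e-12)
  }
})

test_that("the plateau scheduler decays and stops at the mandated epochs", {
  cfg <- train_config(scheduler_patience = 7, early_stop_patience = 20,
                      learning_rate = 0.001, scheduler_factor = 0.5)
  # improvement for 3 epochs, then a hard plateau
  metrics <- c(0.1, 0.2, 0.3, rep(0.3, 30))
  h <- simulate_plateau_schedule(metrics, cfg)
  # first decay after 7 plateau epochs (epoch 10), second 7 later (epoch 17)
  expect_identical(h$epoch[h$reduced], c(10L, 17L))
  expect_equal(h$lr[10], 0.0005)
  expect_equal(h$lr[17], 0.00025)
  # early stop exactly 20 epochs after the last improvement
  expect_identical(nrow(h), 23L)
  expect_true(h$stopped[23])

  # a single injected plateau of exactly scheduler_patience epochs:
  # the rate halves exactly once, at the rule-mandated epoch
  m2 <- c(0.1, 0.2, rep(0.2, 7), 0.4, 0.5)
  h2 <- simulate_plateau_schedule(m2, cfg)
  expect_identical(h2$epoch[h2$reduced], 9L)
  expect_equal(h2$lr[nrow(h2)], 0.0005)
})

test_that("train_regressor recovers a planted linear signal", {
  # target is an exact linear function of the signal-ROI mean: a correctly
  # wired network and training loop must fit it almost perfectly
  atlas <- make_atlas(c(16L, 16L, 16L), n_rois = 3, n_signal = 1, seed = 21)
  eff <- effect_config(image_noise_sd = 0.01)
  set.seed(77)
  sev <- runif(60, 0, 2.5)
  volumes <- lapply(seq_along(sev), function(i) {
    render_volume(list(subject_id = sprintf("p%02d", i), session_id = "ses-01",
                       severity = sev[i]), atlas, eff, seed = 100 + i)
  })
  roi_mean <- vapply(volumes, function(v) mean(v$data[atlas$labels == 1]),
                     numeric(1))
  y <- 1200 - 500 * roi_mean
  fit <- train_regressor(mrinet(tiny_config(), seed = 13), volumes, y,
                         train_idx = 1:44, val_idx = 45:52,
                         train_config(max_epochs = 60, batch_size = 8,
                                      learning_rate = 0.003, seed = 3))
  expect_gte(fit$best_val_r2, 0.9)
  pred <- mrinet_predict(fit$model, volumes[53:60])$pred[, 1]
  expect_gte(regression_metrics(y[53:60], pred)$r2, 0.8)
  # history bookkeeping is consistent with the checkpointing rule
  expect_identical(fit$best_epoch,
                   fit$history$epoch[which.max(fit$history$val_r2)])
})

test_that("training halts early on a hopeless target and reproduces exactly", {
  set.seed(5)
  volumes <- lapply(1:20, function(i) random_volume(c(16L, 16L, 16L), i))
  y <- rnorm(20)  # pure noise target
  tc <- train_config(max_epochs = 40, early_stop_patience = 6,
                     batch_size = 4, seed = 8)
  f1 <- train_regressor(mrinet(tiny_config(), seed = 2), volumes, y,
                        1:14, 15:18, tc)
  expect_true(f1$stopped_early)
  expect_lt(nrow(f1$history), 40L)
  f2 <- train_regressor(mrinet(tiny_config(), seed = 2), volumes, y,
                        1:14, 15:18, tc)
  expect_identical(f1$history, f2$history)
})
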