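test_that("forward passes are deterministic and shaped per config", {
  net <- mrinet(tiny_config(), seed = 3)
  v <- random_volume(c(16L, 16L, 16L), 1)
  o1 <- forward_single(net, v)
  o2 <- forward_single(net, v)
  expect_identical(o1, o2)
  expect_length(o1$latent, 64L)   # latent = first fully connected layer width

  mo <- mrinet(tiny_config(n_heads = 3L), seed = 3)
  m1 <- forward_multi(mo, v)
  expect_named(m1$predictions, c("abeta", "ptau", "tau"))
  expect_length(unlist(m1$latents), 3L * 64L)

  expect_error(forward_single(net, random_volume(c(8L, 8L, 8L), 1)),
               "input dims")
})

test_that("a fresh net maps the zero volume to the final-layer bias", {
  # zero-initialized hidden bias and batch-norm shift keep every activation
  # at zero for a zero input, so the prediction is exactly b2
  net <- mrinet(tiny_config(), seed = 5)
  z <- array(0, c(16L, 16L, 16L))
  expect_identical(forward_single(net, z)$prediction, net$heads[[1]]$b2)
  net$heads[[1]]$b2 <- 3.75
  expect_identical(forward_single(net, z)$prediction, 3.75)
})

test_that("multi-output heads are independent given the shared backbone", {
  mo <- mrinet(tiny_config(n_heads = 3L), seed = 11)
  v <- random_volume(c(16L, 16L, 16L), 2)
  base <- forward_multi(mo, v)
  perturbed <- mo
  perturbed$heads[[2]]$W1 <- perturbed$heads[[2]]$W1 + 0.5
  perturbed$heads[[3]]$W2 <- perturbed$heads[[3]]$W2 - 0.25
  after <- forward_multi(perturbed, v)
  expect_identical(after$predictions[["abeta"]], base$predictions[["abeta"]])
  expect_identical(after$latents$abeta, base$latents$abeta)
  expect_false(identical(after$predictions[["ptau"]], base$predictions[["ptau"]]))
})

test_that("im2col and col2im are adjoint linear maps", {
  # <im2col(x), P> == <x, col2im(P)> for random x, P: the defining property
  # of the convolution gradient
  set.seed(7)
  for (dims in list(c(4L, 5L, 6L), c(6L, 4L, 4L))) {
    for (C in c(1L, 3L)) {
      x <- array(rnorm(prod(dims) * C), dim = c(dims, C))
      P <- csfproxy:::im2col3d(as.numeric(x), dims[1], dims[2], dims[3], C)
      G <- matrix(rnorm(length(P)), nrow(P), ncol(P))
      lhs <- sum(P * G)
      rhs <- sum(as.numeric(x) *
                   csfproxy:::col2im3d(G, dims[1], dims[2], dims[3], C))
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("backprop matches finite differences on a tiny multi-output net", {
  cfg <- mrinet_config(conv_channels = c(3L, 4L), head_hidden = 5L,
                       n_heads = 3L, input_dims = c(8L, 8L, 8L))
  net <- mrinet(cfg, seed = 3)
  set.seed(42)
  xs <- lapply(1:4, function(i) array(runif(512), dim = c(8, 8, 8)))
  Y <- matrix(rnorm(12), 4, 3)
  loss_fn <- function(model) {
    fw <- csfproxy:::net_forward(model, xs, train = TRUE, keep_cache = TRUE)
    err <- fw$pred - Y
    list(loss = sum(colMeans(err^2)) / 3, fw = fw, dpred = (2 * err / 4) / 3)
  }
  l0 <- loss_fn(net)
  bw <- csfproxy:::net_backward(l0$fw$model, l0$fw$cache, l0$dpred,
                                train = TRUE, want_input_grad = TRUE)
  fd <- function(set, get, analytic) {
    p <- get(net)
    num <- p * 0
    for (i in seq_along(p)) {
      up <- p; up[i] <- p[i] + 1e-5
      dn <- p; dn[i] <- p[i] - 1e-5
      num[i] <- (loss_fn(set(net, up))$loss - loss_fn(set(net, dn))$loss) / 2e-5
    }
    expect_lt(max(abs(analytic - num)) / (max(abs(num)) + 1e-8), 1e-5)
  }
  fd(function(m, p) { m$conv[[1]]$W[1:6] <- p; m },
     function(m) m$conv[[1]]$W[1:6], bw$grads$conv[[1]]$W[1:6])
  fd(function(m, p) { m$conv[[2]]$gamma <- p; m },
     function(m) m$conv[[2]]$gamma, bw$grads$conv[[2]]$gamma)
  fd(function(m, p) { m$heads[[2]]$W1[1:5] <- p; m },
     function(m) m$heads[[2]]$W1[1:5], bw$grads$heads[[2]]$W1[1:5])
  fd(function(m, p) { m$heads[[3]]$W2[] <- p; m },
     function(m) as.numeric(m$heads[[3]]$W2), as.numeric(bw$grads$heads[[3]]$W2))

  # gradient w.r.t. the input volume (evaluation mode, the attribution path)
  fe <- csfproxy:::net_forward(net, xs[1], train = FALSE, keep_cache = TRUE)
  dp <- matrix(c(1, 0, 0), 1, 3)
  bwe <- csfproxy:::net_backward(net, fe$cache, dp, train = FALSE,
                                 want_input_grad = TRUE)
  f0 <- function(x1) csfproxy:::net_forward(net, list(x1), train = FALSE)$pred[1, 1]
  idx <- sample(512, 5)
  num <- sapply(idx, function(i) {
    a <- xs[[1]]; a[i] <- a[i] + 1e-5
    b <- xs[[1]]; b[i] <- b[i] - 1e-5
    (f0(a) - f0(b)) / 2e-5
  })
  expect_lt(max(abs(bwe$input_grads[[1]][idx] - num)) / (max(abs(num)) + 1e-8),
            1e-6)
})

test_that("checkpoints round-trip through save/load", {
  net <- mrinet(tiny_config(), seed = 9)
  net$target_stats <- list(mean = 1000, sd = 400)
  path <- withr::local_tempfile(fileext = ".rds")
  save_mrinet(net, path)
  back <- load_mrinet(path)
  expect_identical(back$conv, net$conv)
  expect_identical(back$target_stats, net$target_stats)
  v <- random_volume(c(16L, 16L, 16L), 4)
  expect_identical(forward_single(net, v), forward_single(back, v))
})
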