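make_toy <- function(n = 20, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = rnorm(n) + sep * y, f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("random forest reports its size and separates separable data", {
  toy <- make_toy()
  fit <- pd_rf(toy$x, toy$y, seed = 2)
  expect_s3_class(fit, "pd_rf")
  expect_equal(fit$n_trees, 50L)
  expect_equal(fit$forest$ntree, 50)
  p <- predict(fit, toy$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(compute_auroc(p, toy$y), 1.0)
})

test_that("random forest rejects single-class training and bad schemas", {
  toy <- make_toy()
  expect_error(pd_rf(toy$x, rep(1L, 20)), "each class")
  fit <- pd_rf(toy$x, toy$y)
  bad <- toy$x
  colnames(bad) <- c("a", "b")
  expect_error(predict(fit, bad), "schema")
})

test_that("label-permuted training yields chance-level out-of-bag error", {
  oobs <- vapply(1:10, function(i) {
    set.seed(100 + i)
    toy <- make_toy(n = 40, sep = 3, seed = 100 + i)
    yperm <- sample(toy$y)
    pd_rf(toy$x, yperm, seed = i)$oob_error
  }, 0)
  expect_lt(abs(mean(oobs) - 0.5), 0.2)
})

test_that("model handles serialize and reload to identical predictions", {
  toy <- make_toy()
  fit <- pd_rf(toy$x, toy$y, seed = 5)
  f <- tempfile(fileext = ".rds")
  saveRDS(fit, f)
  fit2 <- readRDS(f)
  expect_identical(predict(fit, toy$x), predict(fit2, toy$x))

  set.seed(2)
  x <- array(rnorm(40 * 96 * 2), c(40, 96, 2))
  y <- rep(c(0L, 1L), 20)
  for (i in which(y == 1)) x[i, , 1] <- x[i, , 1] + sin(2 * pi * 5 * (1:96) / 62.5)
  sp <- cnn_spec(conv_kernels = c(8, 4), conv_filters = c(4, 8),
                 pool_sizes = c(2, 4), dense_units = c(8, 8),
                 epochs = 2, seed = 3)
  cfit <- pd_cnn(x, y, sp)
  saveRDS(cfit, f)
  cfit2 <- readRDS(f)
  expect_identical(predict(cfit, x), predict(cfit2, x))
})

test_that("the network builder reports the reference architecture", {
  arch <- build_cnn(cnn_spec(), 312, 6)
  layers <- arch$layers
  conv <- layers[layers$type == "conv1d_relu", ]
  expect_equal(conv$kernel, c(32, 16))
  expect_equal(conv$units, c(16, 32))
  pool <- layers[layers$type == "maxpool", ]
  expect_equal(pool$kernel, c(4, 6))
  dense <- layers[layers$type == "dense_relu_dropout", ]
  expect_equal(dense$units, c(32, 32))
  expect_equal(cnn_spec()$dropout, 0.5)
  out <- layers[layers$type == "dense_softmax", ]
  expect_equal(out$units, 2)
  # closed-form parameter sum for this input shape
  expect_equal(arch$total_params,
               (32 * 6 * 16 + 16) + (16 * 16 * 32 + 32) +
                 ((312 %/% 4 %/% 6) * 32 * 32 + 32) + (32 * 32 + 32) +
                 (32 * 2 + 2))
  expect_error(build_cnn(cnn_spec(pool_sizes = c(100, 100)), 312, 6),
               "pooled length")
})

test_that("parameter counts match the closed-form layer sum for random configs", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:12, 2)
    f <- sample(2:10, 2)
    p <- sample(2:4, 2)
    d <- sample(4:16, 2)
    n_in <- sample(80:200, 1)
    c_in <- sample(2:8, 1)
    t1 <- n_in %/% p[1]
    t2 <- t1 %/% p[2]
    if (t2 < 1) next
    expected <- (k[1] * c_in * f[1] + f[1]) +
      (k[2] * f[1] * f[2] + f[2]) +
      (t2 * f[2] * d[1] + d[1]) + (d[1] * d[2] + d[2]) +
      (d[2] * 2 + 2)
    arch <- build_cnn(cnn_spec(conv_kernels = k, conv_filters = f,
                               pool_sizes = p, dense_units = d), n_in, c_in)
    expect_equal(arch$total_params, expected)
  }
})

test_that("the network learns separable tremor clips end to end", {
  set.seed(5)
  n <- 160
  x <- array(rnorm(n * 312 * 6, 0, 0.1), c(n, 312, 6))
  y <- rep(c(0L, 1L), each = n / 2)
  tt <- (0:311) / 62.5
  for (i in which(y == 1)) {
    f <- runif(1, 4, 6)
    x[i, , 1] <- x[i, , 1] + 0.4 * sin(2 * pi * f * tt + runif(1) * 2 * pi)
    x[i, , 4] <- x[i, , 4] + 0.4 * sin(2 * pi * f * tt)
  }
  fit <- pd_cnn(x, y, cnn_spec(epochs = 12, seed = 1))
  p <- predict(fit, x)
  expect_gte(compute_auroc(p, y), 0.95)

  pm <- predict(fit, x, type = "matrix")
  expect_lt(max(abs(rowSums(pm) - 1)), 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict(fit, x[1:2, , , drop = FALSE]),
                   predict(fit, x[1:2, , , drop = FALSE]))
  expect_error(predict(fit, x[, 1:100, , drop = FALSE]), "shape")
  expect_error(pd_cnn(x, rep(0L, n)), "both classes")
})

test_that("label-permuted network training scores at chance on held-out clips", {
  sp <- cnn_spec(conv_kernels = c(8, 4), conv_filters = c(4, 8),
                 pool_sizes = c(2, 4), dense_units = c(8, 8),
                 epochs = 4, batch_size = 32)
  aucs <- vapply(1:5, function(s) {
    set.seed(400 + s)
    n <- 80
    x <- array(rnorm(n * 96 * 2, 0, 0.1), c(n, 96, 2))
    y <- rep(c(0L, 1L), n / 2)
    for (i in which(y == 1)) x[i, , 1] <- x[i, , 1] +
        0.4 * sin(2 * pi * 5 * (1:96) / 62.5)
    yp <- sample(y)
    tr <- 1:(n / 2)
    sp$seed <- s
    fit <- pd_cnn(x[tr, , , drop = FALSE], yp[tr], sp)
    compute_auroc(predict(fit, x[-tr, , , drop = FALSE]), yp[-tr])
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
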