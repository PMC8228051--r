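test_that("pretraining produces the configured weight-shape chain", {
  X <- matrix(runif(600), ncol = 6)
  m <- pretrain(X, c(60, 60, 60), train_opts(0.01, 100, 1, seed = 31))
  expect_identical(lapply(m$layers, function(l) dim(l$W)),
                   list(c(60L, 6L), c(60L, 60L), c(60L, 60L)))
  expect_equal(m$softmax_W, matrix(0, 2, 60))
  expect_error(dbn_model(list(rbm_params(6, 10), rbm_params(9, 4))),
               "does not match")
})

test_that("each layer trains on the previous layer's hidden probabilities", {
  X <- matrix(runif(300), ncol = 6)
  opts <- train_opts(0.05, 10, 2)
  m <- withr::with_seed(32, pretrain(X, c(5, 4), opts))
  manual <- withr::with_seed(32, {
    l1 <- train_rbm(X, 5, opts)
    l2 <- train_rbm(hidden_conditional(l1, X), 4, opts)
    list(l1, l2)
  })
  expect_identical(m$layers, manual)
})

test_that("forward_features composes the per-layer conditionals", {
  set.seed(33)
  m <- random_dbn(c(6, 5, 4, 3))
  X <- matrix(runif(30), ncol = 6)
  a <- hidden_conditional(m$layers[[1]], X)
  a <- hidden_conditional(m$layers[[2]], a)
  a <- hidden_conditional(m$layers[[3]], a)
  out <- forward_features(m, X)
  expect_equal(out, a)
  expect_true(all(out > 0 & out < 1))
  m1 <- dbn_model(m$layers[1])
  expect_equal(forward_features(m1, X), hidden_conditional(m$layers[[1]], X))
})

test_that("fine-tuning gradients match central finite differences", {
  set.seed(34)
  m <- random_dbn(c(6, 4, 3))          # 6-4-3-2 network
  X <- matrix(runif(8 * 6), 8, 6)
  y <- rep(c(0L, 1L), 4)
  g <- vegdbn:::dbn_loss_grads(m, X, y)
  eps <- 1e-6
  fd_check <- function(get, set, analytic) {
    theta <- get(m)
    for (i in sample(seq_along(theta), min(6, length(theta)))) {
      up <- theta; up[i] <- up[i] + eps
      dn <- theta; dn[i] <- dn[i] - eps
      fd <- (vegdbn:::dbn_loss_grads(set(m, up), X, y)$loss -
               vegdbn:::dbn_loss_grads(set(m, dn), X, y)$loss) / (2 * eps)
      expect_equal(as.vector(analytic)[i], fd, tolerance = 1e-5)
    }
  }
  fd_check(function(m) m$softmax_W, function(m, v) { m$softmax_W[] <- v; m },
           g$g_softmax_W)
  fd_check(function(m) m$softmax_b, function(m, v) { m$softmax_b <- v; m },
           g$g_softmax_b)
  fd_check(function(m) m$layers[[1]]$W,
           function(m, v) { m$layers[[1]]$W[] <- v; m }, g$g_W[[1]])
  fd_check(function(m) m$layers[[2]]$W,
           function(m, v) { m$layers[[2]]$W[] <- v; m }, g$g_W[[2]])
  fd_check(function(m) m$layers[[1]]$c,
           function(m, v) { m$layers[[1]]$c <- as.numeric(v); m }, g$g_c[[1]])
})

test_that("fine_tune with zero learning rate is the identity", {
  set.seed(35)
  m <- random_dbn(c(6, 4))
  d <- pixel_dataset(matrix(runif(60), ncol = 6), rep(c(0L, 1L), 5))
  m2 <- fine_tune(m, d, fine_tune_opts(0, 5, 2, seed = 36))
  attr(m2, "loss_history") <- NULL
  expect_equal(m2, m, ignore_attr = TRUE)
})

test_that("fine-tuning reaches the separable limit on noiseless scenes", {
  sc <- tiny_scene(48, 48, prevalence = 0.6, noise_sd = 0, seed = 37)
  d <- extract_features(sc)
  m <- pretrain(d$features, 20, train_opts(0.01, 100, 1, seed = 38))
  m <- fine_tune(m, d, fine_tune_opts(0.01, 100, 20, seed = 39))
  acc <- mean(predict(m, d$features)$labels == d$labels)
  expect_gte(acc, 0.99)
  hist <- attr(m, "loss_history")
  expect_lte(hist[length(hist)], hist[1])
})

test_that("predict normalizes probabilities and breaks ties toward class 0", {
  set.seed(40)
  m <- random_dbn(c(6, 4))
  X <- matrix(runif(60), ncol = 6)
  out <- predict(m, X)
  expect_equal(rowSums(out$prob), rep(1, 10), tolerance = 1e-9)
  expect_identical(out$labels, unname(apply(out$prob, 1, which.max) - 1L))
  # zero-initialized softmax: uniform probabilities, tie -> class 0
  m0 <- dbn_model(list(rbm_params(6, 4, seed = 41)))
  out0 <- predict(m0, X)
  expect_true(all(out0$prob == 0.5))
  expect_identical(out0$labels, rep(0L, 10))
})

test_that("classification maps use the red/green palette consistently", {
  sc <- tiny_scene(12, 9, seed = 42)
  m <- dbn_model(list(rbm_params(6, 4, seed = 43)))
  m$softmax_b <- c(-5, 5)              # predicts vegetation everywhere
  map <- classify_scene(m, sc)
  expect_identical(dim(map), c(9L, 12L, 3L))
  expect_true(all(map[, , 1] == 255L & map[, , 2] == 0L & map[, , 3] == 0L))
  # spot-check: pixel colour agrees with predict on that pixel's features
  set.seed(44)
  m2 <- random_dbn(c(6, 5))
  map2 <- classify_scene(m2, sc)
  d <- extract_features(sc)
  i <- 4; j <- 11
  lab <- predict(m2, d$features[(i - 1) * 12 + j, ])$labels
  expect_identical(map2[i, j, 1], if (lab == 1L) 255L else 0L)
})

test_that("the stacked joint normalizes and reduces to the RBM joint at depth 1", {
  set.seed(45)
  p <- random_params(3, 2)
  m1 <- dbn_model(list(p))
  ex <- exact_distribution(p)
  v <- c(1, 0, 1); h <- c(1, 0)
  iv <- which(apply(ex$v_states, 1, function(s) all(s == v)))
  ih <- which(apply(ex$h_states, 1, function(s) all(s == h)))
  expect_equal(dbn_joint(m1, v, list(h)), ex$prob[iv, ih], tolerance = 1e-12)

  # 3-3-2 toy: total mass over all states is 1
  m <- dbn_model(list(random_params(3, 3), random_params(3, 2)))
  s3 <- vegdbn:::binary_states(3)
  s2 <- vegdbn:::binary_states(2)
  total <- 0
  for (i in seq_len(8)) for (j in seq_len(8)) for (k in seq_len(4)) {
    pr <- dbn_joint(m, s3[i, ], list(s3[j, ], s2[k, ]))
    expect_gte(pr, 0); expect_lte(pr, 1)
    total <- total + pr
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("models survive a JSON serialization round trip", {
  set.seed(46)
  m <- random_dbn(c(6, 5, 3))
  path <- file.path(withr::local_tempdir(), "model.json")
  save_dbn(m, path)
  back <- load_dbn(path)
  expect_equal(back, m)
  X <- matrix(runif(30), ncol = 6)
  expect_identical(predict(back, X), predict(m, X))
})
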