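test_that("activation functions match their definitions", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(2.5), 2.5)
  expect_equal(relu(c(-3, 0.5)), c(0, 0.5))
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(800), 1)          # stable at large |x|
  expect_equal(sigmoid(-800), 0)
  x <- c(-5, -0.3, 0, 2, 40)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
})

test_that("convolution layer detects a perfect motif and matches the oracle", {
  X <- one_hot_encode("ACGTACGT")
  W <- array(0, dim = c(6, 4, 2))
  W[, , 1] <- one_hot_encode("ACGTAC")   # kernel = motif indicator
  Yc <- conv1d_forward(X, W, c(0, 0))
  expect_equal(Yc[1, 1], 6)              # full match at position 0
  expect_equal(nrow(Yc), 8)              # output length stays L
  expect_equal(Yc[, 2], rep(0, 8))       # zero kernel, zero bias -> ReLU(0)

  set.seed(21)
  for (i in 1:10) {
    L <- sample(10:30, 1); M <- sample(2:5, 1); F <- sample(1:4, 1)
    X <- one_hot_encode(rand_seq(L, with_ambiguity = TRUE))
    W <- array(rnorm(M * 4 * F), dim = c(M, 4, F))
    b <- rnorm(F)
    expect_equal(conv1d_forward(X, W, b), oracle_conv(X, W, b),
                 tolerance = 1e-12)
  }
})

test_that("max pooling windows, remainders and oracle agreement", {
  Y <- matrix(c(1, 3, 2, 5, 4, 6), ncol = 1)
  expect_equal(maxpool1d(Y, 3, 3), matrix(c(3, 6), ncol = 1))
  expect_equal(maxpool1d(matrix(2, 7, 2), 3, 3), matrix(2, 2, 2))
  expect_error(maxpool1d(matrix(1, 2, 1), 3, 3), "shorter")
  set.seed(8)
  for (i in 1:10) {
    L <- sample(6:40, 1); S1 <- sample(2:4, 1); S2 <- sample(1:4, 1)
    Y <- matrix(rnorm(L * 3), L, 3)
    expect_identical(maxpool1d(Y, S1, S2), oracle_maxpool(Y, S1, S2))
  }
  # pooled length for the four group lengths with S1 = S2 = 3
  for (L in c(400, 800, 1200, 1800))
    expect_equal(pooled_length(network_config(L = L)), L %/% 3)
})

test_that("batch normalization at inference follows the running-moment formula", {
  bn_id <- list(scale = rep(1, 3), shift = rep(0, 3),
                mean = rep(0, 3), var = rep(1, 3))
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(batchnorm_inference(x, bn_id, 0), x)
  bn <- list(scale = c(2, 1, 0.5), shift = c(1, -1, 0),
             mean = c(0.3, 0, -2), var = c(1.5, 0.2, 1))
  expect_equal(batchnorm_inference(bn$mean, bn, 1e-3), bn$shift)
  set.seed(13)
  x <- matrix(rnorm(24), 8, 3)
  expect_equal(batchnorm_inference(x, bn, 1e-3), oracle_bn(x, bn, 1e-3))
})

test_that("dropout contract: identity cases and empirical drop fraction", {
  x <- matrix(rnorm(20), 5, 4)
  d0 <- dropout_train(x, 0)
  expect_identical(d0$values, x)
  expect_true(all(d0$mask == 1))
  di <- dropout_train(x, 0.7, mode = "infer")
  expect_identical(di$values, x)
  expect_error(dropout_train(x, 1), "P must be")

  withr::with_seed(5, {
    big <- matrix(1, 100, 100)
    dp <- dropout_train(big, 0.3)
    frac <- mean(dp$values == 0)
    expect_lt(abs(frac - 0.3), 0.02)
    kept <- dp$values[dp$values != 0]
    expect_true(all(abs(kept - 1 / 0.7) < 1e-12))  # inverted-dropout rescale
  })
})

test_that("global average pooling and dense layers match their formulas", {
  expect_equal(global_avg_pool(matrix(2, 7, 3)), rep(2, 3))
  Y <- matrix(0, 5, 2); Y[3, 1] <- 10
  expect_equal(global_avg_pool(Y), c(2, 0))
  expect_error(global_avg_pool(matrix(numeric(0), 0, 3)), "empty")

  expect_equal(dense_forward(1:3, matrix(0, 2, 3), c(0, 0), "relu"), c(0, 0))
  expect_equal(dense_forward(1:3, rep(0, 3), 0, "sigmoid"), 0.5)
  set.seed(17)
  x <- rnorm(6); W <- matrix(rnorm(24), 4, 6); b <- rnorm(4)
  expect_equal(dense_forward(x, W, b, "relu"), oracle_dense(x, W, b, "relu"),
               tolerance = 1e-12)
})

test_that("composed forward pass: degenerate weights, determinism, range", {
  cfg <- network_config(L = 60, F = 4, R = 4)
  w <- init_weights(cfg, seed = 1)
  w$conv_W[] <- 0; w$dense1_W[] <- 0; w$dense2_W[] <- 0
  X <- one_hot_encode(rand_seq(60))
  expect_equal(forward(cfg, w, X)$score, 0.5)

  w2 <- withr::with_seed(2, rand_weights(cfg))
  s1 <- forward(cfg, w2, X)$score
  s2 <- forward(cfg, w2, X)$score
  expect_identical(s1, s2)
  expect_true(s1 > 0 && s1 < 1)

  tr <- forward(cfg, w2, X, trace = TRUE)$trace
  expect_equal(dim(tr$Y_C), c(60, 4))
  expect_equal(dim(tr$Y_M), c(20, 4))
  expect_true(all(tr$Y_C >= 0))
  expect_true(all(tr$y_D1 >= 0))
})

test_that("compiled batch scoring agrees with the R forward pass on all variants", {
  set.seed(33)
  seqs <- vapply(1:6, function(i) rand_seq(sample(150:200, 1),
                                           with_ambiguity = TRUE), "")
  for (v in c("full", "no_maxpool", "no_dropout", "no_globalpool", "no_bn")) {
    cfg <- network_config(L = 200, F = 6, R = 5, variant = v)
    w <- rand_weights(cfg)
    got <- phagelife:::.score_batch(seqs, cfg, w)
    want <- vapply(seqs, function(s)
      forward(cfg, w, one_hot_encode(s, 200))$score, numeric(1),
      USE.NAMES = FALSE)
    expect_equal(got, want, tolerance = 1e-12, label = v)
  }
  cfgk <- network_config(L = 200, variant = "kmer4", R = 5)
  wk <- rand_weights(cfgk)
  feats <- t(vapply(seqs, kmer_frequencies, numeric(256), k = 4,
                    USE.NAMES = FALSE))
  got <- phagelife:::.score_batch(feats, cfgk, wk)
  want <- apply(feats, 1, function(x) forward(cfgk, wk, x)$score)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("variant layer stacks drop exactly the stated component", {
  full <- build_variant(network_config(L = 400))
  expect_equal(full, c("conv1d", "maxpool", "bn1", "dropout",
                       "global_avg_pool", "dense1", "bn2", "dense2"))
  expect_length(full, 8)
  expect_equal(setdiff(full, build_variant(network_config(L = 400, variant = "no_dropout"))),
               "dropout")
  expect_equal(setdiff(full, build_variant(network_config(L = 400, variant = "no_maxpool"))),
               "maxpool")
  expect_equal(build_variant(network_config(L = 400, variant = "no_bn")),
               setdiff(full, c("bn1", "bn2")))
  ngp <- build_variant(network_config(L = 400, variant = "no_globalpool"))
  expect_true("flatten" %in% ngp && !"global_avg_pool" %in% ngp)
  expect_equal(build_variant(network_config(L = 400, variant = "kmer4")),
               c("kmer_input", "dense1", "bn2", "dense2"))
  # kmer4 dense input dimension is 4^4
  wk <- init_weights(network_config(L = 400, variant = "kmer4"), seed = 1)
  expect_equal(ncol(wk$dense1_W), 256)
  expect_error(network_config(L = 400, variant = "convnet"), "arg")
})

test_that("no_dropout inference equals full inference for equal weights", {
  cfg_full <- network_config(L = 120, F = 5, R = 4)
  cfg_nd <- network_config(L = 120, F = 5, R = 4, variant = "no_dropout")
  w <- withr::with_seed(9, rand_weights(cfg_full))
  X <- one_hot_encode(rand_seq(120))
  expect_equal(forward(cfg_full, w, X)$score, forward(cfg_nd, w, X)$score)
})

test_that("weight archives round trip and reject bad files", {
  cfg <- network_config(L = 400, F = 8, R = 8)
  w <- init_weights(cfg, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_weights(w, cfg, path)
  back <- load_weights(path)
  expect_equal(back$weights, w)
  expect_equal(back$config, cfg)

  garbage <- tempfile()
  writeLines("not a weight archive", garbage)
  expect_error(load_weights(garbage), "corrupted")

  wrong <- tempfile(fileext = ".rds")
  saveRDS(list(format_version = 99L, config = cfg, weights = w), wrong)
  expect_error(load_weights(wrong), "version mismatch")
})
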