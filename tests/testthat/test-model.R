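# Architecture geometry, training behavior, and inference contracts of
# the 1-D convolutional classifier.

test_that("row counts propagate 14 -> 7 -> 3 -> 2 -> 1 at the defaults", {
  expect_equal(convStackRows(cnnConfig(), k = 7), c(14, 7, 3, 2, 1))
  # unpadded first conv, padded second conv, floor pooling throughout
  expect_equal(convStackRows(cnnConfig(ncl = 1), k = 7), c(14, 7, 3))
  expect_equal(convStackRows(cnnConfig(), k = 9), c(18, 9, 4, 2, 1))
})

test_that("a stack that collapses to zero rows is a configuration error", {
  expect_error(convStackRows(cnnConfig(), k = 1), "POOL layer 1")
  expect_error(convStackRows(cnnConfig(ncl = 3), k = 7), "POOL layer 3")
  expect_error(buildModel(cnnConfig(ncl = 3), k = 7), "POOL layer 3")
})

test_that("parameter count matches the closed form", {
  for (cfg in list(cnnConfig(), cnnConfig(ncl = 1, nfl = 2, ncn = 12,
                                          nfn = 24))) {
    for (k in c(7L, 9L)) {
      mod <- buildModel(cfg, k = k, nF = 12, seed = 1)
      expect_equal(
        sum(vapply(mod@weights,
                   function(l) length(l$W) + length(l$b), 0)),
        countParameters(cfg, k, 12))
    }
  }
})

test_that("identical seeds give identical initial parameters", {
  a <- buildModel(cnnConfig(), k = 7, seed = 42)
  b <- buildModel(cnnConfig(), k = 7, seed = 42)
  c <- buildModel(cnnConfig(), k = 7, seed = 43)
  expect_identical(a@weights, b@weights)
  expect_false(identical(a@weights, c@weights))
})

test_that("untrained outputs are probabilities for any input", {
  mod <- buildModel(cnnConfig(), k = 7, seed = 2)
  withr::with_seed(8, X <- array(rnorm(20 * 14 * 12), c(20, 14, 12)))
  p <- predictProba(mod, X)
  expect_length(p, 20L)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("first-layer activations are spatially local (window locality)", {
  mod <- buildModel(cnnConfig(), k = 7, seed = 3)
  withr::with_seed(9, X <- array(rnorm(1 * 14 * 12), c(1, 14, 12)))
  base <- driverCNN:::.cnnForward(mod@weights, X, cache = TRUE)
  for (j in c(1L, 4L, 7L)) {
    Xz <- X
    Xz[, setdiff(seq_len(14), c(2L * j - 1L, 2L * j)), ] <- 0
    act <- driverCNN:::.cnnForward(mod@weights, Xz, cache = TRUE)
    # window j's first-layer activation is untouched by zeroing the rest
    expect_equal(act$caches[[1]]$convA[1, j, ],
                 base$caches[[1]]$convA[1, j, ])
  }
})

test_that("gradients match numerical differentiation", {
  # small architecture so central differences stay cheap and stable
  cfg <- cnnConfig(ncn = 3, nfn = 4)
  mod <- buildModel(cfg, k = 7, nF = 5, seed = 11)
  withr::with_seed(12, {
    X <- array(rnorm(6 * 14 * 5), c(6, 14, 5))
    y <- rep(c(1, 0), 3)
  })
  layers <- mod@weights
  fw <- driverCNN:::.cnnForward(layers, X, cache = TRUE)
  grads <- driverCNN:::.cnnBackward(layers, fw$caches, X, fw$p, y)
  lossAt <- function(lay) driverCNN:::.bceLoss(
    driverCNN:::.cnnForward(lay, X)$p, y)
  eps <- 1e-6
  withr::with_seed(13, {
    for (li in seq_along(layers)) {
      idx <- sample.int(length(layers[[li]]$W), 3)
      for (i in idx) {
        up <- layers; up[[li]]$W[i] <- up[[li]]$W[i] + eps
        dn <- layers; dn[[li]]$W[i] <- dn[[li]]$W[i] - eps
        expect_equal(grads[[li]]$W[i],
                     (lossAt(up) - lossAt(dn)) / (2 * eps),
                     tolerance = 1e-4)
      }
      up <- layers; up[[li]]$b[1] <- up[[li]]$b[1] + eps
      dn <- layers; dn[[li]]$b[1] <- dn[[li]]$b[1] - eps
      expect_equal(unname(grads[[li]]$b[1]),
                   (lossAt(up) - lossAt(dn)) / (2 * eps),
                   tolerance = 1e-4)
    }
  })
})

test_that("training separates a separable toy set and keeps finite loss", {
  toy <- separableTensors()
  mod <- buildModel(cnnConfig(), k = 7, seed = 4)
  tr <- trainModel(mod, toy$X, toy$y,
                   trainConfig(maxEpochs = 200, valFraction = 0, seed = 5))
  p <- predictProba(tr, toy$X)
  expect_true(all((p > 0.5) == (toy$y == 1)))    # training accuracy 1.0
  expect_true(min(p[toy$y == 1]) > max(p[toy$y == 0]))
  expect_true(all(is.finite(tr@history$train_loss)))
  expect_true(tr@trained)
})

test_that("training is reproducible and rejects single-class data", {
  toy <- separableTensors()
  tc <- trainConfig(maxEpochs = 30, seed = 7)
  a <- trainModel(buildModel(cnnConfig(), 7, seed = 1), toy$X, toy$y, tc)
  b <- trainModel(buildModel(cnnConfig(), 7, seed = 1), toy$X, toy$y, tc)
  expect_identical(a@weights, b@weights)
  expect_identical(a@history, b@history)
  expect_error(
    trainModel(buildModel(cnnConfig(), 7, seed = 1),
               toy$X, rep(1, length(toy$y)), tc),
    "both classes")
})

test_that("inference is deterministic and batching-invariant", {
  toy <- separableTensors(n = 10)
  mod <- buildModel(cnnConfig(), k = 7, seed = 6)
  pAll <- predictProba(mod, toy$X)
  expect_identical(predictProba(mod, toy$X), pAll)
  # scoring in two chunks gives the same values
  pChunks <- c(predictProba(mod, toy$X[1:3, , , drop = FALSE]),
               predictProba(mod, toy$X[4:10, , , drop = FALSE]))
  expect_equal(unname(pChunks), unname(pAll))
  # duplicated input rows score identically
  dup <- toy$X[c(1, 1, 2), , , drop = FALSE]
  pd <- predictProba(mod, dup)
  expect_equal(pd[1], pd[2])
  # shape mismatch is rejected
  expect_error(predictProba(mod, array(0, c(2, 6, 12))), "does not match")
})

test_that("models round-trip through the YAML checkpoint", {
  toy <- separableTensors()
  tr <- trainModel(buildModel(cnnConfig(ncn = 4, nfn = 6), 7, seed = 9),
                   toy$X, toy$y,
                   trainConfig(maxEpochs = 20, seed = 10))
  tf <- tempfile(fileext = ".yaml")
  saveModel(tr, tf)
  back <- loadModel(tf)
  expect_equal(predictProba(back, toy$X), predictProba(tr, toy$X),
               tolerance = 1e-9)
  expect_identical(back@config, tr@config)
})
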