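# Downsampling, ROC/AUC, cross-validation bookkeeping, grid search,
# learning curves, and bagged ranking.

test_that("downsampleSets builds balanced seeded sets from the unknowns", {
  drivers <- sprintf("D%02d", 1:37)
  unknown <- sprintf("U%03d", 1:500)
  sets <- downsampleSets(drivers, unknown, nSets = 5, seed = 3)
  expect_length(sets, 5L)
  for (s in sets) {
    expect_equal(nrow(s), 74L)
    expect_equal(sum(s$label == 1), 37L)
    expect_equal(sum(s$label == 0), 37L)
    expect_false(anyDuplicated(s$gene_id) > 0)
    expect_true(all(s$gene_id[s$label == 0] %in% unknown))
    expect_identical(s$gene_id[s$label == 1], drivers)
  }
  again <- downsampleSets(drivers, unknown, nSets = 5, seed = 3)
  expect_identical(sets, again)
  other <- downsampleSets(drivers, unknown, nSets = 5, seed = 4)
  expect_false(identical(sets, other))
  expect_error(downsampleSets(drivers, sprintf("U%03d", 1:10), seed = 1),
               "at least as many")
  expect_error(downsampleSets(drivers, c(unknown, drivers[1]), seed = 1),
               "both driver and unknown")
})

test_that("rocAuc handles the worked example, separation, and symmetry", {
  expect_equal(rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))$auc, 0.75)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(1.0, 0.9, 0.1, 0.0))$auc, 1.0)
  withr::with_seed(17, {
    for (i in 1:10) {
      y <- rbinom(30, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(30), 2)            # rounding forces ties
      expect_equal(rocAuc(y, s)$auc + rocAuc(y, -s)$auc, 1.0,
                   tolerance = 1e-12)
    }
  })
  expect_error(rocAuc(c(1, 1), c(0.5, 0.2)), "both classes")
  expect_error(rocAuc(c(1, 0), c(NaN, 0.2)), "finite")
})

test_that("rocAuc equals the Mann-Whitney pair statistic, with ties", {
  withr::with_seed(23, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
      s <- sample(round(runif(n, 0, 1), 1))  # heavy ties
      expect_equal(rocAuc(y, s)$auc, aucOracle(y, s), tolerance = 1e-12)
    }
  })
})

test_that("rocAuc curve geometry is a valid ROC and matches pROC", {
  withr::with_seed(29, {
    y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
    s <- runif(40)
  })
  r <- rocAuc(y, s)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0), all(diff(r$tpr) >= 0))
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(
                 y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))),
               tolerance = 1e-12)
})

# -- a small prepared cohort reused by the protocol tests ---------------
smallCohort <- local({
  cohort <- simulateCohort(simulationConfig(
    nGenes = 60L, nDrivers = 10L, nSamples = 30L, seed = 19))
  prepareCohort(cohort$records, cohort$expression, cohort$drivers, k = 7)
})
fastTc <- trainConfig(maxEpochs = 8L, patience = 8L, seed = 1L)

test_that("crossValidate books one AUC per set x repeat with no leakage", {
  sets <- downsampleSets(smallCohort$drivers, smallCohort$unknown,
                         nSets = 2, seed = 5)
  cv <- crossValidate(smallCohort$features, smallCohort$network, sets,
                      tc = fastTc, folds = 5, repeats = 2, seed = 9)
  expect_equal(nrow(cv$perRun), 2 * 2)
  expect_equal(cv$meanAuc, mean(cv$perRun$auc))
  expect_length(cv$runs, 4L)
  for (run in cv$runs) {
    expect_equal(sort(unique(run$foldId)), 1:5)
    expect_false(any(is.na(run$scores)))     # every gene scored exactly once
    # every training partition saw both classes
    for (f in 1:5)
      expect_equal(sort(unique(run$label[run$foldId != f])), c(0L, 1L))
  }
  # bit-identical reruns under the same seed
  cv2 <- crossValidate(smallCohort$features, smallCohort$network, sets,
                       tc = fastTc, folds = 5, repeats = 2, seed = 9)
  expect_identical(cv$perRun, cv2$perRun)
  expect_identical(cv$runs, cv2$runs)
})

test_that("gridSearch is exhaustive, marks infeasible combos, returns argmax", {
  sets <- downsampleSets(smallCohort$drivers, smallCohort$unknown,
                         nSets = 1, seed = 5)
  grid <- list(ncl = c(2L, 3L), nfl = 1L, ncn = 4L, nfn = 6L, k = 7L)
  gs <- gridSearch(smallCohort$features, smallCohort$expression, sets,
                   grid = grid, tc = fastTc, folds = 3, repeats = 1,
                   seed = 2)
  expect_equal(nrow(gs$table), 2L)              # grid cardinality
  expect_true(is.na(gs$table$meanAuc[gs$table$ncl == 3]))  # 7->3->2->1->0
  expect_equal(gs$best$config$ncl, 2L)
  valid <- gs$table$meanAuc[!is.na(gs$table$meanAuc)]
  expect_true(all(gs$best$meanAuc >= valid))
  # singleton grid returns that configuration
  gs1 <- gridSearch(smallCohort$features, smallCohort$expression, sets,
                    grid = list(ncl = 1L, nfl = 1L, ncn = 4L, nfn = 6L,
                                k = 5L),
                    tc = fastTc, folds = 3, repeats = 1, seed = 2)
  expect_equal(nrow(gs1$table), 1L)
  expect_equal(gs1$best$k, 5L)
})

test_that("learningCurve uses nested sizes up to the full 80% split", {
  sets <- downsampleSets(smallCohort$drivers, smallCohort$unknown,
                         nSets = 1, seed = 5)
  lc <- learningCurve(smallCohort$features, smallCohort$network,
                      sets[[1]], trainFraction = 0.8,
                      config = cnnConfig(ncn = 4, nfn = 6),
                      tc = fastTc, seed = 3)
  expect_equal(max(lc$n_train), round(0.8 * nrow(sets[[1]])))
  expect_true(all(diff(lc$n_train) > 0))
  expect_true(all(lc$auc >= 0 & lc$auc <= 1, na.rm = TRUE))
  lc2 <- learningCurve(smallCohort$features, smallCohort$network,
                       sets[[1]], trainFraction = 0.8,
                       config = cnnConfig(ncn = 4, nfn = 6),
                       tc = fastTc, seed = 3)
  expect_identical(lc, lc2)                     # seed-deterministic
})

test_that("rankUnknown averages per-model probabilities and sorts", {
  genes <- sprintf("u%02d", 1:6)
  withr::with_seed(33, X <- array(rnorm(6 * 14 * 12), c(6, 14, 12),
                                  dimnames = list(genes, NULL, NULL)))
  models <- lapply(1:3, function(s)
    buildModel(cnnConfig(ncn = 4, nfn = 6), k = 7, seed = s))
  rk <- rankUnknown(models, X)
  probs <- sapply(models, function(m) predictProba(m, X))
  expected <- rowMeans(probs)
  expect_equal(rk$mean_probability,
               unname(sort(expected, decreasing = TRUE)))
  expect_identical(rk$gene[1], names(which.max(expected)))
  expect_equal(rk$rank, 1:6)
  # one model: ranking by that model's probabilities
  rk1 <- rankUnknown(models[1], X)
  expect_equal(rk1$mean_probability,
               unname(sort(probs[, 1], decreasing = TRUE)))
})
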