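# FPKM -> TPM -> filtered log2-TPM and the kNN similarity network.

test_that("fpkmToTpm rescales each sample to one million", {
  m <- matrix(c(2, 3, 5), ncol = 1,
              dimnames = list(c("A", "B", "C"), "s1"))
  tpm <- fpkmToTpm(ExpressionMatrix(m, "FPKM"))
  expect_equal(unname(exprValues(tpm)[, 1]), c(2e5, 3e5, 5e5))
  expect_identical(exprUnit(tpm), "TPM")
  # independent per-column oracle on two samples of different composition
  m2 <- matrix(c(1, 1, 2, 10, 30, 60), ncol = 2,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tpm2 <- exprValues(fpkmToTpm(ExpressionMatrix(m2, "FPKM")))
  for (j in 1:2)
    expect_equal(unname(tpm2[, j]), unname(m2[, j] / sum(m2[, j]) * 1e6))
  expect_equal(unname(colSums(tpm2)), c(1e6, 1e6), tolerance = 1e-9)
})

test_that("fpkmToTpm is idempotent on TPM and rejects all-zero samples", {
  withr::with_seed(5, {
    m <- matrix(rexp(60), 6, 10,
                dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
  })
  once <- fpkmToTpm(ExpressionMatrix(m, "FPKM"))
  twice <- fpkmToTpm(once)
  expect_equal(exprValues(twice), exprValues(once), tolerance = 1e-12)
  m[, 3] <- 0
  expect_error(fpkmToTpm(ExpressionMatrix(m, "FPKM")), "s3")
})

test_that("preprocessExpression applies zeroing, log2, and the 10% filter", {
  # TPM 0.9 -> 0 after zeroing; TPM 1.0 -> log2(2) = 1
  m <- matrix(c(0.9, 0.3, 1.5,          # nonzero in 1/3 after zeroing
                1.0, 2.0, 3.0), nrow = 2, byrow = TRUE,
              dimnames = list(c("low", "hi"), c("s1", "s2", "s3")))
  em <- ExpressionMatrix(m, "TPM")
  out <- preprocessExpression(em, minExpressedFraction = 0.5)
  expect_false("low" %in% geneIds(out))   # nonzero in 1/3 < 0.5
  expect_equal(unname(exprValues(out)["hi", "s1"]), log2(1 + 1))
  expect_identical(exprUnit(out), "LOG2_TPM")
})

test_that("survivor set equals an independent per-row recount", {
  withr::with_seed(21, {
    raw <- matrix(rexp(50 * 20, rate = 1 / 3), 50, 20,
                  dimnames = list(sprintf("g%02d", 1:50),
                                  sprintf("s%02d", 1:20)))
  })
  tpm <- fpkmToTpm(ExpressionMatrix(raw, "FPKM"))
  out <- preprocessExpression(tpm, 0.10)
  # oracle: recount expressed fractions directly from the TPM values
  v <- exprValues(tpm)
  v[v < 1] <- 0
  keep <- rownames(v)[rowSums(v > 0) / ncol(v) >= 0.10]
  expect_identical(geneIds(out), keep)
  expect_equal(exprValues(out), log2(v[keep, ] + 1))
})

test_that("pearsonSimilarity matches the closed form and flags degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(pearsonSimilarity(x, x), 1.0)
  expect_equal(pearsonSimilarity(x, -x), -1.0)
  expect_equal(as.numeric(pearsonSimilarity(x, c(1, 2, 4))),
               9 / (2 * sqrt(21)), tolerance = 1e-12)
  flat <- pearsonSimilarity(c(2, 2, 2), x)
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
  expect_error(pearsonSimilarity(1:3, 1:4), "length")
})

test_that("pearson is symmetric and scale/shift invariant", {
  withr::with_seed(31, {
    for (i in 1:20) {
      x <- rnorm(8); y <- rnorm(8)
      a <- runif(1, -3, 3); b <- runif(1, -5, 5)
      if (abs(a) < 1e-3) a <- 1
      expect_equal(pearsonSimilarity(x, y), pearsonSimilarity(y, x))
      expect_equal(as.numeric(pearsonSimilarity(a * x + b, y)),
                   sign(a) * as.numeric(pearsonSimilarity(x, y)),
                   tolerance = 1e-10)
    }
  })
})

test_that("kNN lists match an exhaustive all-pairs sort, k in {3,7,9}", {
  em <- randomLogExpression(30, 15, seed = 71)
  v <- exprValues(em)
  genes <- rownames(v)
  for (k in c(3L, 7L, 9L)) {
    net <- buildKnnNetwork(em, k = k)
    for (g in genes) {
      pcc <- sapply(setdiff(genes, g),
                    function(h) cor(v[g, ], v[h, ]))
      ord <- names(pcc)[order(-pcc, names(pcc))]
      expect_identical(unname(net@neighbors[g, ]), ord[seq_len(k)])
      expect_equal(unname(net@weights[g, ]),
                   unname(pcc[ord[seq_len(k)]]), tolerance = 1e-12)
    }
  }
})

test_that("duplicate profiles tie and resolve by ascending symbol", {
  base <- c(1, 2, 3, 5, 8)
  v <- rbind(g1 = base, g2 = base + 10, g3 = 2 * base, g4 = -base)
  colnames(v) <- sprintf("s%d", 1:5)
  net <- buildKnnNetwork(ExpressionMatrix(v, "LOG2_TPM"), k = 2)
  expect_identical(unname(net@neighbors["g1", ]), c("g2", "g3"))
  expect_equal(unname(net@weights["g1", ]), c(1, 1))
  # every list excludes self and has length k
  expect_true(all(net@neighbors != rownames(net@neighbors)[row(net@neighbors)]))
  expect_equal(ncol(net@neighbors), 2L)
})

test_that("network is invariant to gene row order and k bounds are checked", {
  em <- randomLogExpression(12, 10, seed = 13)
  net <- buildKnnNetwork(em, k = 4)
  withr::with_seed(5, perm <- sample.int(12))
  emPerm <- ExpressionMatrix(exprValues(em)[perm, ], "LOG2_TPM")
  netPerm <- buildKnnNetwork(emPerm, k = 4)
  g <- geneIds(em)
  expect_identical(net@neighbors[g, ], netPerm@neighbors[g, ])
  expect_error(buildKnnNetwork(em, k = 12), "smaller than the gene count")
})

test_that("zero-variance genes warn and correlate 0 with everything", {
  em <- randomLogExpression(10, 8, seed = 3)
  v <- exprValues(em)
  v["g005", ] <- 7
  expect_warning(net <- buildKnnNetwork(ExpressionMatrix(v, "LOG2_TPM"),
                                        k = 3),
                 "zero-variance")
  # the flat gene's own list carries weight 0 everywhere, and any edge
  # pointing at it has weight 0, so callers can drop it cleanly
  expect_equal(unname(net@weights["g005", ]), rep(0, 3))
  points_at <- net@neighbors == "g005"
  expect_true(all(net@weights[points_at] == 0))
})

test_that("truncateNetwork keeps rank-order prefixes; edge TSV round-trips", {
  em <- randomLogExpression(15, 12, seed = 77)
  net7 <- buildKnnNetwork(em, k = 7)
  net3 <- truncateNetwork(net7, 3)
  expect_identical(net3@neighbors, net7@neighbors[, 1:3])
  expect_identical(buildKnnNetwork(em, k = 3)@neighbors, net3@neighbors)
  tf <- tempfile(fileext = ".tsv")
  writeNetwork(net3, tf)
  edges <- read.delim(tf)
  expect_equal(nrow(edges), 15 * 3)
  expect_identical(edges$neighbor[edges$gene == "g001"],
                   unname(net3@neighbors["g001", ]))
})
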