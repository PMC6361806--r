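# The 1-D convolutional driver-gene classifier.
#
# The architecture uses filter size = pool size = stride = 2 throughout,
# so convolution windows never overlap: a CONV layer is a reshape of row
# pairs followed by one matrix multiply, and max pooling is a pairwise
# maximum.  That makes an exact forward/backward pass a few dense matrix
# operations, which is all a net of ~3k parameters needs; training and
# the Adam optimizer are implemented here directly on that structure.

#' CNN architecture configuration
#'
#' Defaults are the grid-search optimum for this model family: 2 CONV-POOL
#' blocks with 24 filters each, 1 fully-connected layer with 48 nodes, and
#' filter/pool/stride sizes of 2.  The first CONV layer is unpadded
#' ("valid"); later CONV layers are zero-padded at the bottom so they emit
#' \code{ceiling(rows / 2)} rows.
#'
#' @param ncl number of CONV-POOL blocks.
#' @param nfl number of fully-connected layers.
#' @param ncn filters per CONV layer.
#' @param nfn nodes per fully-connected layer.
#' @param filterSize,poolSize,convStride,poolStride layer geometry; this
#'   implementation supports the published geometry (all equal to 2).
#' @param padFirst whether to zero-pad the first CONV layer (default
#'   FALSE; later CONV layers are always padded).
#' @return a named list.
#' @export
cnnConfig <- function(ncl = 2L, nfl = 1L, ncn = 24L, nfn = 48L,
                      filterSize = 2L, poolSize = 2L, convStride = 2L,
                      poolStride = 2L, padFirst = FALSE) {
  stopifnot(ncl >= 1L, nfl >= 1L, ncn >= 1L, nfn >= 1L)
  if (any(c(filterSize, poolSize, convStride, poolStride) != 2L))
    stop("this implementation supports filter/pool/stride sizes of 2",
         call. = FALSE)
  list(ncl = as.integer(ncl), nfl = as.integer(nfl), ncn = as.integer(ncn),
       nfn = as.integer(nfn), filterSize = 2L, poolSize = 2L,
       convStride = 2L, poolStride = 2L, padFirst = isTRUE(padFirst))
}

#' Training configuration
#'
#' @param learningRate Adam step size.
#' @param maxEpochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience, in epochs without improvement
#'   of the monitored loss.
#' @param valFraction fraction of the training set held out to monitor
#'   early stopping (falls back to the training loss when the set is too
#'   small to split).
#' @param seed RNG seed controlling the validation split, shuffling, and
#'   any weight re-initialization; fixing it makes training reproducible.
#' @return a named list.
#' @export
trainConfig <- function(learningRate = 1e-3, maxEpochs = 300L,
                        batchSize = 16L, patience = 25L,
                        valFraction = 0.1, seed = 1L) {
  stopifnot(learningRate > 0, maxEpochs >= 1L, batchSize >= 1L,
            patience >= 1L, valFraction >= 0, valFraction < 1)
  list(optimizer = "adam", learningRate = learningRate,
       maxEpochs = as.integer(maxEpochs), batchSize = as.integer(batchSize),
       patience = as.integer(patience), valFraction = valFraction,
       seed = as.integer(seed))
}

#' Row counts through the CONV-POOL stack
#'
#' Starting from the 2k input rows, each CONV halves the row count
#' (\code{floor} when unpadded, \code{ceiling} when zero-padded) and each
#' max-pool takes \code{floor(rows / 2)} (an incomplete trailing window is
#' dropped).  Errors when any layer would emit zero rows.
#'
#' @param config a [cnnConfig()] list.
#' @param k neighbor count of the input tensors.
#' @return integer vector of row counts: input, then after every CONV and
#'   every POOL, e.g. \code{c(14, 7, 3, 2, 1)} for the defaults at k = 7.
#' @export
convStackRows <- function(config, k) {
  rows <- 2L * as.integer(k)
  out <- rows
  for (l in seq_len(config$ncl)) {
    pad <- if (l == 1L) config$padFirst else TRUE
    rows <- if (pad) as.integer(ceiling(rows / 2)) else rows %/% 2L
    if (rows < 1L)
      stop("CONV layer ", l, " would emit 0 rows; reduce ncl or ",
           "increase k", call. = FALSE)
    out <- c(out, rows)
    rows <- rows %/% 2L
    if (rows < 1L)
      stop("POOL layer ", l, " would emit 0 rows; reduce ncl or ",
           "increase k", call. = FALSE)
    out <- c(out, rows)
  }
  out
}

#' Closed-form parameter count
#'
#' @inheritParams convStackRows
#' @param nF feature dimension of the input tensors.
#' @return total number of trainable weights and biases.
#' @export
countParameters <- function(config, k, nF = 12L) {
  rows <- convStackRows(config, k)
  cIn <- as.integer(nF)
  total <- 0L
  for (l in seq_len(config$ncl)) {
    total <- total + (2L * cIn) * config$ncn + config$ncn
    cIn <- config$ncn
  }
  flat <- rows[length(rows)] * config$ncn
  fIn <- flat
  for (l in seq_len(config$nfl)) {
    total <- total + fIn * config$nfn + config$nfn
    fIn <- config$nfn
  }
  total + fIn + 1L
}

#' Build an untrained classifier
#'
#' Validates that the CONV-POOL stack keeps at least one row, then
#' initializes weights (He-scaled normals for ReLU layers, smaller
#' normals for the sigmoid head, zero biases) under the given seed; two
#' builds with identical arguments produce identical parameters.
#'
#' @inheritParams countParameters
#' @param seed RNG seed for the weight initialization.
#' @return an untrained [DriverCNN-class].
#' @export
buildModel <- function(config = cnnConfig(), k = 7L, nF = 12L, seed = 1L) {
  k <- as.integer(k); nF <- as.integer(nF)
  rows <- convStackRows(config, k)  # errors on collapse
  withr::with_seed(as.integer(seed), {
    layers <- list()
    cIn <- nF
    for (l in seq_len(config$ncl)) {
      fanIn <- 2L * cIn
      layers[[length(layers) + 1L]] <- list(
        kind = "conv",
        pad = if (l == 1L) config$padFirst else TRUE,
        W = matrix(stats::rnorm(fanIn * config$ncn, sd = sqrt(2 / fanIn)),
                   fanIn, config$ncn),
        b = rep(0, config$ncn))
      cIn <- config$ncn
    }
    fIn <- rows[length(rows)] * config$ncn
    for (l in seq_len(config$nfl)) {
      layers[[length(layers) + 1L]] <- list(
        kind = "fc",
        W = matrix(stats::rnorm(fIn * config$nfn, sd = sqrt(2 / fIn)),
                   fIn, config$nfn),
        b = rep(0, config$nfn))
      fIn <- config$nfn
    }
    layers[[length(layers) + 1L]] <- list(
      kind = "out",
      W = matrix(stats::rnorm(fIn, sd = sqrt(1 / fIn)), fIn, 1L),
      b = 0)
  })
  new("DriverCNN", config = config, k = k, nF = nF, weights = layers,
      history = data.frame(), trained = FALSE)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass over a batch array X (n x rows x channels).  With
# cache = TRUE also returns per-layer intermediates for backprop.
.cnnForward <- function(layers, X, cache = FALSE) {
  n <- dim(X)[1L]
  caches <- if (cache) vector("list", length(layers)) else NULL
  A <- X
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$kind == "conv") {
      R <- dim(A)[2L]; C <- dim(A)[3L]
      if (lay$pad) {
        outR <- as.integer(ceiling(R / 2))
        need <- 2L * outR
        if (need > R) {
          Ap <- array(0, c(n, need, C))
          Ap[, seq_len(R), ] <- A
          A <- Ap
        }
      } else outR <- R %/% 2L
      use <- 2L * outR
      Xa <- A[, seq(1L, use, by = 2L), , drop = FALSE]
      Xb <- A[, seq(2L, use, by = 2L), , drop = FALSE]
      X2 <- cbind(matrix(Xa, n * outR, C), matrix(Xb, n * outR, C))
      Z <- sweep(X2 %*% lay$W, 2L, lay$b, "+")
      Am <- pmax(Z, 0)
      Fc <- ncol(lay$W)
      convA <- array(Am, c(n, outR, Fc))
      # max-pool, window 2 stride 2, incomplete trailing window dropped
      poolR <- outR %/% 2L
      A1 <- convA[, seq(1L, 2L * poolR, by = 2L), , drop = FALSE]
      A2 <- convA[, seq(2L, 2L * poolR, by = 2L), , drop = FALSE]
      mask <- A1 >= A2  # ties resolve to the earlier row
      P <- pmax(A1, A2)
      if (cache)
        caches[[li]] <- list(inR = R, padded = lay$pad, convR = outR,
                             poolR = poolR, X2 = X2, relu = Z > 0,
                             mask = mask, convA = convA)
      A <- P
    } else {
      if (is.array(A) && length(dim(A)) == 3L)
        A <- matrix(A, n, dim(A)[2L] * dim(A)[3L])
      Z <- sweep(A %*% lay$W, 2L, lay$b, "+")
      if (lay$kind == "fc") {
        out <- pmax(Z, 0)
        if (cache) caches[[li]] <- list(Ain = A, relu = Z > 0)
        A <- out
      } else {
        p <- .sigmoid(drop(Z))
        if (cache) caches[[li]] <- list(Ain = A)
        return(list(p = p, caches = caches))
      }
    }
  }
  stop("network has no output layer")  # nocov
}

.bceLoss <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Gradients of the mean binary cross-entropy w.r.t. all parameters.
.cnnBackward <- function(layers, caches, X, p, y) {
  n <- dim(X)[1L]
  grads <- vector("list", length(layers))
  dZ <- matrix((p - y) / n, ncol = 1L)  # sigmoid + BCE shortcut
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    ch <- caches[[li]]
    if (lay$kind %in% c("out", "fc")) {
      if (lay$kind == "fc") dZ <- dZ * ch$relu
      grads[[li]] <- list(W = crossprod(ch$Ain, dZ), b = colSums(dZ))
      dZ <- dZ %*% t(lay$W)  # gradient w.r.t. this layer's input
    } else {
      Fc <- ncol(lay$W)
      # dZ arrives as gradient w.r.t. the flattened pool output
      dP <- array(dZ, c(n, ch$poolR, Fc))
      dConv <- array(0, c(n, ch$convR, Fc))
      if (ch$poolR > 0L) {
        odd <- seq(1L, 2L * ch$poolR, by = 2L)
        even <- odd + 1L
        dConv[, odd, ] <- dP * ch$mask
        dConv[, even, ] <- dP * !ch$mask
      }
      dZm <- matrix(dConv, n * ch$convR, Fc) * ch$relu
      grads[[li]] <- list(W = crossprod(ch$X2, dZm), b = colSums(dZm))
      dX2 <- dZm %*% t(lay$W)
      C <- ncol(dX2) %/% 2L
      dXa <- array(dX2[, seq_len(C), drop = FALSE], c(n, ch$convR, C))
      dXb <- array(dX2[, C + seq_len(C), drop = FALSE], c(n, ch$convR, C))
      padR <- 2L * ch$convR
      dIn <- array(0, c(n, max(padR, ch$inR), C))
      dIn[, seq(1L, padR, by = 2L), ] <- dXa
      dIn[, seq(2L, padR, by = 2L), ] <- dXb
      dIn <- dIn[, seq_len(ch$inR), , drop = FALSE]  # strip padding rows
      dZ <- matrix(dIn, n, ch$inR * C)
    }
  }
  grads
}

# One Adam step over all layer parameters; state carries first/second
# moments and the step counter.
.adamStep <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (li in seq_along(layers)) {
    for (par in c("W", "b")) {
      g <- grads[[li]][[par]]
      m <- beta1 * state$m[[li]][[par]] + (1 - beta1) * g
      v <- beta2 * state$v[[li]][[par]] + (1 - beta2) * g * g
      state$m[[li]][[par]] <- m
      state$v[[li]][[par]] <- v
      layers[[li]][[par]] <- layers[[li]][[par]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(layers = layers, state = state)
}

.adamInit <- function(layers) {
  zero <- lapply(layers, function(l)
    list(W = array(0, dim(l$W)), b = rep(0, length(l$b))))
  list(t = 0L, m = zero, v = zero)
}

# Coerce the accepted tensor inputs to one n x 2k x nF batch array.
.asTensorArray <- function(x, k, nF) {
  if (methods::is(x, "FeatureTensor"))
    x <- list(x)
  if (is.list(x) && all(vapply(x, methods::is, TRUE, "FeatureTensor"))) {
    arr <- array(NA_real_, c(length(x), 2L * k, nF),
                 dimnames = list(vapply(x, function(t) t@geneId, ""),
                                 NULL, NULL))
    for (i in seq_along(x)) arr[i, , ] <- tensorValues(x[[i]])
    x <- arr
  }
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("tensors must be a FeatureTensor, a list of them, or an ",
         "n x 2k x n_f array", call. = FALSE)
  if (dim(x)[2L] != 2L * k || dim(x)[3L] != nF)
    stop(sprintf("tensor shape %d x %d does not match the model's %d x %d",
                 dim(x)[2L], dim(x)[3L], 2L * k, nF), call. = FALSE)
  x
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam, minibatched and shuffled each
#' epoch, monitoring a held-out validation split for early stopping and
#' restoring the best-scoring weights.  Fully deterministic given the
#' model's initialization seed and \code{tc$seed}.
#'
#' @param model an untrained (or trained) [DriverCNN-class].
#' @param tensors input tensors: an n x 2k x n_f array from
#'   [buildTensorSet()], a list of [FeatureTensor-class] objects, or one
#'   tensor.
#' @param labels numeric 0/1 vector, one per tensor; both classes must be
#'   present.
#' @param tc a [trainConfig()] list.
#' @return the trained [DriverCNN-class]; per-epoch losses are in
#'   \code{@history}.
#' @export
trainModel <- function(model, tensors, labels, tc = trainConfig()) {
  X <- .asTensorArray(tensors, model@k, model@nF)
  y <- as.numeric(labels)
  n <- dim(X)[1L]
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  layers <- model@weights
  withr::with_seed(tc$seed, {
    nVal <- floor(tc$valFraction * n)
    if (nVal >= 1L && n - nVal >= 2L) {
      valIdx <- sort(sample.int(n, nVal))
    } else valIdx <- integer()
    trIdx <- setdiff(seq_len(n), valIdx)
    Xtr <- X[trIdx, , , drop = FALSE]
    ytr <- y[trIdx]
    state <- .adamInit(layers)
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    hist <- vector("list", tc$maxEpochs)
    for (epoch in seq_len(tc$maxEpochs)) {
      ord <- sample.int(length(trIdx))
      starts <- seq(1L, length(ord), by = tc$batchSize)
      for (s in starts) {
        bi <- ord[s:min(s + tc$batchSize - 1L, length(ord))]
        Xb <- Xtr[bi, , , drop = FALSE]
        fw <- .cnnForward(layers, Xb, cache = TRUE)
        grads <- .cnnBackward(layers, fw$caches, Xb, fw$p, ytr[bi])
        upd <- .adamStep(layers, grads, state, tc$learningRate)
        layers <- upd$layers
        state <- upd$state
      }
      trLoss <- .bceLoss(.cnnForward(layers, Xtr)$p, ytr)
      if (length(valIdx)) {
        valLoss <- .bceLoss(
          .cnnForward(layers, X[valIdx, , , drop = FALSE])$p, y[valIdx])
      } else valLoss <- NA_real_
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = trLoss,
                                  val_loss = valLoss)
      monitored <- if (length(valIdx)) valLoss else trLoss
      if (monitored < best$loss - 1e-9) {
        best <- list(loss = monitored, layers = layers, epoch = epoch)
      } else if (epoch - best$epoch >= tc$patience) break
    }
  })
  model@weights <- best$layers
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model@trained <- TRUE
  model
}

#' Predict driver probabilities
#'
#' Applies the trained network to input tensors; inference is
#' deterministic, side-effect free, and independent of how the inputs are
#' batched.
#'
#' @param model a trained [DriverCNN-class].
#' @param tensors tensors in any form accepted by [trainModel()].
#' @return numeric vector of probabilities in \code{[0, 1]}, named by gene
#'   when the input carries gene names, in input order.
#' @export
predictProba <- function(model, tensors) {
  X <- .asTensorArray(tensors, model@k, model@nF)
  p <- .cnnForward(model@weights, X)$p
  names(p) <- dimnames(X)[[1L]]
  p
}

#' Save / load a model as a self-describing YAML file
#'
#' The file holds the architecture configuration, input geometry, and all
#' layer weights; [loadModel()] reconstructs an identical predictor.
#'
#' @param model a [DriverCNN-class].
#' @param path output file path.
#' @return \code{path} invisibly (for \code{saveModel}); the restored
#'   [DriverCNN-class] (for \code{loadModel}).
#' @export
saveModel <- function(model, path) {
  ser <- list(
    config = model@config, k = model@k, nF = model@nF,
    trained = model@trained,
    layers = lapply(model@weights, function(l) {
      out <- list(kind = l$kind, dimW = dim(l$W),
                  W = as.numeric(l$W), b = as.numeric(l$b))
      if (!is.null(l$pad)) out$pad <- l$pad
      out
    }))
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ser <- yaml::read_yaml(path)
  layers <- lapply(ser$layers, function(l) {
    out <- list(kind = l$kind,
                W = matrix(as.numeric(l$W), l$dimW[[1L]], l$dimW[[2L]]),
                b = as.numeric(l$b))
    if (!is.null(l$pad)) out$pad <- l$pad
    out
  })
  cfg <- ser$config
  cfg[c("ncl", "nfl", "ncn", "nfn", "filterSize", "poolSize",
        "convStride", "poolStride")] <-
    lapply(cfg[c("ncl", "nfl", "ncn", "nfn", "filterSize", "poolSize",
                 "convStride", "poolStride")], as.integer)
  new("DriverCNN", config = cfg, k = as.integer(ser$k),
      nF = as.integer(ser$nF), weights = layers,
      history = data.frame(), trained = isTRUE(ser$trained))
}
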