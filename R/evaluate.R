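# Evaluation protocol: balanced downsampling of passengers, repeated
# 10-fold cross-validation with pooled held-out scores, ROC/AUC, grid
# search, learning curves, and bagged ranking of unlabeled genes.

#' Balanced driver/passenger sets by downsampling
#'
#' Pairs the full driver list with \code{nSets} independent uniform draws
#' (without replacement within a draw) of equally many unlabeled genes,
#' treated as passengers.  Averaging predictions over the sets later
#' (bagging) mitigates the chance that an undiscovered driver lands among
#' the sampled negatives.
#'
#' @param drivers character vector of driver gene symbols (label 1).
#' @param unknownGenes character vector of candidate passenger symbols,
#'   disjoint from \code{drivers} and at least as many.
#' @param nSets number of balanced sets (default 5).
#' @param seed RNG seed; the draws are fully determined by it.
#' @return list of \code{nSets} data.frames with columns \code{gene_id}
#'   and \code{label}, each carrying a \code{provenance} attribute
#'   (set index and seed).
#' @export
downsampleSets <- function(drivers, unknownGenes, nSets = 5L, seed = 1L) {
  drivers <- unique(as.character(drivers))
  unknownGenes <- unique(as.character(unknownGenes))
  overlap <- intersect(drivers, unknownGenes)
  if (length(overlap))
    stop("genes in both driver and unknown lists: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  if (length(unknownGenes) < length(drivers))
    stop("need at least as many unknown genes (", length(unknownGenes),
         ") as drivers (", length(drivers), ")", call. = FALSE)
  stopifnot(nSets >= 1L)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nSets), function(i) {
      neg <- sample(unknownGenes, length(drivers))
      out <- data.frame(
        gene_id = c(drivers, neg),
        label = rep(c(1L, 0L), each = length(drivers)),
        stringsAsFactors = FALSE)
      attr(out, "provenance") <- list(set = i, seed = as.integer(seed))
      out
    })
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct scores as thresholds (predict positive when score
#' >= threshold), producing FPR/TPR pairs from (0, 0) to (1, 1); tied
#' scores move both rates at once, giving diagonal segments.  The AUC is
#' the trapezoidal area, which equals the Mann-Whitney statistic
#' P(score+ > score-) + P(tie)/2.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores finite numeric vector of the same length.
#' @return list with \code{thresholds}, \code{fpr}, \code{tpr} (each of
#'   length n_distinct + 1, starting above the maximum score) and
#'   \code{auc}.
#' @examples
#' rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))$auc  # 0.75
#' @export
rocAuc <- function(labels, scores) {
  y <- as.numeric(labels)
  stopifnot(length(y) == length(scores))
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  nPos <- sum(y == 1)
  nNeg <- sum(y == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  grp <- !duplicated(ss)                 # one threshold per distinct score
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  last <- c(which(grp)[-1L] - 1L, length(ss))  # last index of each group
  thr <- c(Inf, ss[grp])
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

#' Write ROC points as TSV
#' @param roc a [rocAuc()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRoc <- function(roc, path) {
  utils::write.table(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shuffle genes into folds, retrying (with the current RNG stream) until
# every training partition holds both classes, up to maxRetries.
.foldAssignment <- function(y, folds, maxRetries = 20L) {
  n <- length(y)
  for (try in seq_len(maxRetries)) {
    foldId <- sample(rep(seq_len(folds), length.out = n))
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(y[foldId != f])) == 2L, TRUE))
    if (ok) return(foldId)
    message("fold split left a single-class training partition; ",
            "re-shuffling (attempt ", try, ")")
  }
  stop("could not produce two-class training partitions after ",
       maxRetries, " shuffles", call. = FALSE)
}

# Train on all folds but f, score fold f; returns held-out scores pooled
# over folds.  The feature scaler is fit within training folds only.
.runOneCv <- function(set, features, network, config, tc, folds) {
  genes <- set$gene_id
  y <- set$label
  foldId <- .foldAssignment(y, folds)
  scores <- rep(NA_real_, length(genes))
  for (f in seq_len(folds)) {
    trIdx <- which(foldId != f)
    teIdx <- which(foldId == f)
    if (!length(teIdx)) next
    scaler <- fitScaler(features[genes[trIdx], , drop = FALSE])
    Xtr <- buildTensorSet(genes[trIdx], features, network, scaler)
    Xte <- buildTensorSet(genes[teIdx], features, network, scaler)
    buildSeed <- sample.int(2147483646L, 1L)
    tcf <- tc
    tcf$seed <- sample.int(2147483646L, 1L)
    model <- buildModel(config, k = netK(network), nF = ncol(features),
                        seed = buildSeed)
    model <- trainModel(model, Xtr, y[trIdx], tcf)
    scores[teIdx] <- predictProba(model, Xte)
  }
  list(scores = scores, foldId = foldId)
}

#' Repeated k-fold cross-validation over the downsampled sets
#'
#' For every balanced set and repeat: shuffle the genes into \code{folds}
#' groups, train on folds-1 groups and score the held-out group, pool the
#' held-out scores of one run into a single ROC curve, and report that
#' run's AUC.  The headline number is the mean over all sets x repeats.
#' Feature scaling and model fitting happen inside training folds only, so
#' no information about a held-out gene's features or label reaches its
#' scorer.
#'
#' @param features genes x 12 matrix from [mutationFeatures()] (must cover
#'   all set genes and their network neighbors).
#' @param network a [SimilarityNetwork-class]; its k fixes the model input.
#' @param sets list of balanced sets from [downsampleSets()].
#' @param config a [cnnConfig()] list.
#' @param tc a [trainConfig()] list (its seed is superseded by the run
#'   stream derived from \code{seed}).
#' @param folds fold count (default 10).
#' @param repeats repetitions of the whole CV per set (default 5).
#' @param seed RNG seed determining every shuffle, split and training run.
#' @return list with \code{meanAuc}, \code{perRun} (data.frame: set,
#'   repeat index, auc; \code{nSets * repeats} rows) and \code{runs}
#'   (per-run fold assignments and pooled scores, for auditing).
#' @export
crossValidate <- function(features, network, sets, config = cnnConfig(),
                          tc = trainConfig(), folds = 10L, repeats = 5L,
                          seed = 1L) {
  stopifnot(folds >= 2L, repeats >= 1L)
  perRun <- list()
  runs <- list()
  withr::with_seed(as.integer(seed), {
    for (s in seq_along(sets)) {
      for (r in seq_len(repeats)) {
        run <- .runOneCv(sets[[s]], features, network, config, tc, folds)
        auc <- rocAuc(sets[[s]]$label, run$scores)$auc
        perRun[[length(perRun) + 1L]] <-
          data.frame(set = s, rep = r, auc = auc)
        runs[[length(runs) + 1L]] <-
          list(set = s, rep = r, foldId = run$foldId, scores = run$scores,
               gene_id = sets[[s]]$gene_id, label = sets[[s]]$label)
      }
    }
  })
  perRun <- do.call(rbind, perRun)
  list(meanAuc = mean(perRun$auc), perRun = perRun, runs = runs)
}

#' Exhaustive grid search over architecture and neighborhood size
#'
#' Evaluates every combination of \code{ncl}, \code{nfl}, \code{ncn},
#' \code{nfn} and \code{k} by [crossValidate()] and returns the argmax of
#' the mean AUC, with ties broken by the smaller parameter count.
#' Combinations whose CONV-POOL stack collapses to zero rows for the
#' given k are recorded with \code{NA} AUC and excluded from the argmax,
#' keeping one row per grid point.
#'
#' @param features genes x 12 feature matrix.
#' @param expression an [ExpressionMatrix-class] (unit \code{"LOG2_TPM"})
#'   from which the kNN network is built once at the largest k and
#'   truncated per grid point.
#' @param sets balanced sets from [downsampleSets()].
#' @param grid named list with numeric vectors \code{ncl}, \code{nfl},
#'   \code{ncn}, \code{nfn}, \code{k}; defaults are the published search
#'   space.
#' @param tc a [trainConfig()] list.
#' @param folds,repeats,seed as in [crossValidate()].
#' @return list with \code{best} (list: config, k, meanAuc) and
#'   \code{table} (one row per combination, with mean AUC and parameter
#'   count).
#' @export
gridSearch <- function(features, expression, sets,
                       grid = list(ncl = c(1L, 2L, 3L, 4L),
                                   nfl = c(1L, 2L, 3L),
                                   ncn = c(12L, 24L, 48L),
                                   nfn = c(24L, 48L, 96L),
                                   k = c(3L, 5L, 7L, 9L, 11L, 13L, 15L)),
                       tc = trainConfig(), folds = 10L, repeats = 5L,
                       seed = 1L) {
  stopifnot(all(c("ncl", "nfl", "ncn", "nfn", "k") %in% names(grid)),
            all(lengths(grid) >= 1L))
  combos <- expand.grid(ncl = grid$ncl, nfl = grid$nfl, ncn = grid$ncn,
                        nfn = grid$nfn, k = grid$k,
                        KEEP.OUT.ATTRS = FALSE)
  maxK <- max(combos$k)
  fullNet <- buildKnnNetwork(expression, k = maxK)
  nF <- ncol(features)
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- cnnConfig(ncl = combos$ncl[i], nfl = combos$nfl[i],
                     ncn = combos$ncn[i], nfn = combos$nfn[i])
    kq <- as.integer(combos$k[i])
    feasible <- !inherits(try(convStackRows(cfg, kq), silent = TRUE),
                          "try-error")
    if (feasible) {
      net <- truncateNetwork(fullNet, kq)
      cv <- crossValidate(features, net, sets, cfg, tc, folds = folds,
                          repeats = repeats, seed = seed)
      res[[i]] <- data.frame(combos[i, ], meanAuc = cv$meanAuc,
                             nParams = countParameters(cfg, kq, nF))
    } else {
      res[[i]] <- data.frame(combos[i, ], meanAuc = NA_real_,
                             nParams = NA_integer_)
    }
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  valid <- which(!is.na(tab$meanAuc))
  if (!length(valid))
    stop("no feasible grid combination", call. = FALSE)
  best <- valid[order(-tab$meanAuc[valid], tab$nParams[valid])][1L]
  list(best = list(config = cnnConfig(ncl = tab$ncl[best],
                                      nfl = tab$nfl[best],
                                      ncn = tab$ncn[best],
                                      nfn = tab$nfn[best]),
                   k = as.integer(tab$k[best]),
                   meanAuc = tab$meanAuc[best]),
       table = tab)
}

#' Learning curve on a fixed held-out split
#'
#' Holds out \code{1 - trainFraction} of the genes as a fixed test set,
#' then trains on nested subsamples of the remaining genes and reports the
#' test AUC per training size.  The largest size is the full training
#' split.  Subsamples containing a single class are skipped with a
#' message.
#'
#' @param features genes x 12 feature matrix.
#' @param network a [SimilarityNetwork-class].
#' @param set one balanced set (data.frame \code{gene_id}, \code{label}).
#' @param trainFraction fraction used for training (default 0.8).
#' @param sizes training sizes to evaluate; default: 5 evenly spaced
#'   sizes from 10 up to the full training split.
#' @param config,tc,seed as in [crossValidate()].
#' @return data.frame with columns \code{n_train} and \code{auc} (NA for
#'   skipped sizes).
#' @export
learningCurve <- function(features, network, set, trainFraction = 0.8,
                          sizes = NULL, config = cnnConfig(),
                          tc = trainConfig(), seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  n <- nrow(set)
  out <- NULL
  withr::with_seed(as.integer(seed), {
    nTrain <- round(trainFraction * n)
    for (try in seq_len(20L)) {
      perm <- sample.int(n)
      teIdx <- perm[(nTrain + 1L):n]
      if (length(unique(set$label[teIdx])) == 2L) break
      if (try == 20L) stop("could not draw a two-class test split",
                           call. = FALSE)
    }
    trPool <- perm[seq_len(nTrain)]  # fixed order: nested subsamples
    if (is.null(sizes))
      sizes <- unique(round(seq(min(10L, nTrain), nTrain, length.out = 5L)))
    sizes <- sort(unique(pmin(as.integer(sizes), nTrain)))
    rows <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      trIdx <- trPool[seq_len(sizes[i])]
      if (length(unique(set$label[trIdx])) < 2L) {
        message("training subsample of size ", sizes[i],
                " has a single class; skipped")
        rows[[i]] <- data.frame(n_train = sizes[i], auc = NA_real_)
        next
      }
      scaler <- fitScaler(features[set$gene_id[trIdx], , drop = FALSE])
      Xtr <- buildTensorSet(set$gene_id[trIdx], features, network, scaler)
      Xte <- buildTensorSet(set$gene_id[teIdx], features, network, scaler)
      model <- buildModel(config, k = netK(network), nF = ncol(features),
                          seed = sample.int(2147483646L, 1L))
      tcf <- tc
      tcf$seed <- sample.int(2147483646L, 1L)
      model <- trainModel(model, Xtr, set$label[trIdx], tcf)
      auc <- rocAuc(set$label[teIdx], predictProba(model, Xte))$auc
      rows[[i]] <- data.frame(n_train = sizes[i], auc = auc)
    }
    out <- do.call(rbind, rows)
  })
  out
}

#' Bag models over the balanced sets
#'
#' Trains one classifier per balanced set on all of that set's genes
#' (scaler fit on the same genes).  The resulting models are averaged by
#' [rankUnknown()] when scoring unlabeled genes.
#'
#' @inheritParams crossValidate
#' @return list with \code{models} (one [DriverCNN-class] per set) and
#'   \code{scalers} (the matching [FeatureScaler-class] objects).
#' @export
trainBaggedModels <- function(features, network, sets,
                              config = cnnConfig(), tc = trainConfig(),
                              seed = 1L) {
  models <- vector("list", length(sets))
  scalers <- vector("list", length(sets))
  withr::with_seed(as.integer(seed), {
    for (s in seq_along(sets)) {
      set <- sets[[s]]
      scalers[[s]] <- fitScaler(features[set$gene_id, , drop = FALSE])
      X <- buildTensorSet(set$gene_id, features, network, scalers[[s]])
      model <- buildModel(config, k = netK(network), nF = ncol(features),
                          seed = sample.int(2147483646L, 1L))
      tcf <- tc
      tcf$seed <- sample.int(2147483646L, 1L)
      models[[s]] <- trainModel(model, X, set$label, tcf)
    }
  })
  list(models = models, scalers = scalers)
}

#' Rank unlabeled genes by bagged driver probability
#'
#' Scores every unlabeled gene with each per-set model, averages the
#' probabilities, and sorts descending (ties broken by ascending symbol).
#'
#' @param models list of trained [DriverCNN-class] objects.
#' @param tensors one n x 2k x n_f array used for all models, or a list of
#'   such arrays (one per model, e.g. when each model carries its own
#'   scaler); gene symbols must be in the array dimension names.
#' @return data.frame with columns \code{rank}, \code{gene},
#'   \code{mean_probability}.
#' @export
rankUnknown <- function(models, tensors) {
  stopifnot(length(models) >= 1L)
  if (!is.list(tensors) || is.array(tensors))
    tensors <- rep(list(tensors), length(models))
  stopifnot(length(tensors) == length(models))
  probs <- vapply(seq_along(models),
                  function(i) predictProba(models[[i]], tensors[[i]]),
                  numeric(dim(tensors[[1L]])[1L]))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  genes <- dimnames(tensors[[1L]])[[1L]]
  meanP <- rowMeans(probs)
  ord <- order(-meanP, genes)
  data.frame(rank = seq_along(genes), gene = genes[ord],
             mean_probability = meanP[ord], row.names = NULL)
}
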