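# End-to-end wiring: raw cohort inputs -> features + network -> balanced
# sets -> cross-validated AUC or bagged ranking.

#' Prepare a cohort for classification
#'
#' Runs the full preprocessing chain: hypermutated-sample filtering on the
#' mutation records, mutation feature extraction, FPKM to TPM conversion,
#' expression filtering, intersection of the gene universes (only genes
#' with both mutation features and surviving expression are kept), and
#' kNN network construction on the intersected expression matrix.  The
#' driver list is split into the labeled positives present in the cohort
#' and the remaining "unknown" genes that serve as candidate passengers.
#'
#' @param records mutation record data.frame ([readMAF()] output).
#' @param expression an [ExpressionMatrix-class] with unit \code{"FPKM"}
#'   (or already \code{"TPM"}).
#' @param drivers character vector of known driver symbols.
#' @param k neighbor count for the similarity network (default 7).
#' @param hypermutatedThreshold QC threshold on variants per sample
#'   (default 1000).
#' @param minExpressedFraction expression filter threshold (default 0.10).
#' @return list with \code{features} (genes x 12 matrix),
#'   \code{network} ([SimilarityNetwork-class]), \code{drivers} (labeled
#'   positives present in the cohort), \code{unknown} (all other cohort
#'   genes), \code{expression} (filtered log2-TPM matrix restricted to the
#'   cohort genes) and \code{nFilteredRecords}.
#' @export
prepareCohort <- function(records, expression, drivers, k = 7L,
                          hypermutatedThreshold = 1000L,
                          minExpressedFraction = 0.10) {
  nBefore <- nrow(records)
  records <- filterHypermutated(records, hypermutatedThreshold)
  features <- mutationFeatures(records)
  tpm <- fpkmToTpm(expression)
  log2tpm <- preprocessExpression(tpm, minExpressedFraction)
  common <- intersect(rownames(features), geneIds(log2tpm))
  if (length(common) <= k)
    stop("only ", length(common), " genes have both mutation and ",
         "expression data; need more than k = ", k, call. = FALSE)
  features <- features[common, , drop = FALSE]
  expr <- ExpressionMatrix(
    exprValues(log2tpm)[common, , drop = FALSE], "LOG2_TPM")
  network <- buildKnnNetwork(expr, k = k)
  drv <- intersect(drivers, common)
  if (!length(drv))
    stop("no labeled driver gene survives preprocessing", call. = FALSE)
  list(features = features, network = network, drivers = sort(drv),
       unknown = sort(setdiff(common, drv)), expression = expr,
       nFilteredRecords = nBefore - nrow(records))
}

#' Cross-validated evaluation of a prepared cohort
#'
#' Draws \code{nSets} balanced driver/passenger sets and runs repeated
#' k-fold cross-validation ([crossValidate()]) on them.
#'
#' @param cohort a [prepareCohort()] result.
#' @param nSets number of downsampled balanced sets (default 5).
#' @param folds,repeats cross-validation geometry (defaults 10 and 5).
#' @param config a [cnnConfig()] list.
#' @param tc a [trainConfig()] list.
#' @param seed RNG seed for downsampling and every CV run.
#' @param permuteLabels if TRUE, replaces the driver list by an
#'   equally-sized random draw from the whole gene universe before
#'   downsampling — a label-permutation null whose AUC should hover
#'   around 0.5.
#' @return the [crossValidate()] result, plus the \code{sets} used.
#' @export
evaluateCohort <- function(cohort, nSets = 5L, folds = 10L, repeats = 5L,
                           config = cnnConfig(), tc = trainConfig(),
                           seed = 1L, permuteLabels = FALSE) {
  drivers <- cohort$drivers
  unknown <- cohort$unknown
  if (permuteLabels) {
    universe <- c(drivers, unknown)
    withr::with_seed(as.integer(seed) + 131071L, {
      drivers <- sort(sample(universe, length(drivers)))
    })
    unknown <- setdiff(universe, drivers)
  }
  sets <- downsampleSets(drivers, unknown, nSets = nSets, seed = seed)
  cv <- crossValidate(cohort$features, cohort$network, sets,
                      config = config, tc = tc, folds = folds,
                      repeats = repeats, seed = seed)
  cv$sets <- sets
  cv
}

#' Rank a cohort's unlabeled genes by bagged driver probability
#'
#' Trains one model per balanced set on all of that set's genes, scores
#' every unknown gene with each model (each using its own training-set
#' scaler), and ranks by the average probability.
#'
#' @inheritParams evaluateCohort
#' @return list with \code{ranking} (data.frame rank / gene /
#'   mean_probability), \code{models} and \code{sets}.
#' @export
rankCohort <- function(cohort, nSets = 5L, config = cnnConfig(),
                       tc = trainConfig(), seed = 1L) {
  sets <- downsampleSets(cohort$drivers, cohort$unknown, nSets = nSets,
                         seed = seed)
  bag <- trainBaggedModels(cohort$features, cohort$network, sets,
                           config = config, tc = tc, seed = seed)
  tensors <- lapply(bag$scalers, function(sc)
    buildTensorSet(cohort$unknown, cohort$features, cohort$network, sc))
  ranking <- rankUnknown(bag$models, tensors)
  list(ranking = ranking, models = bag$models, sets = sets)
}
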