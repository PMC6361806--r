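# Per-gene CNN input construction: feature scaling and the interleaved
# 2k x n_f matrix of a gene and its ranked neighbors.

#' Fit a per-feature standardization scaler
#'
#' Learns column means and standard deviations from the training genes'
#' feature matrix.  Features with zero spread get scale 1, so constant
#' columns standardize to zero.  Fit the scaler on training folds only and
#' apply it to held-out genes to avoid information leaking across folds.
#'
#' @param features numeric matrix, genes x features (>= 2 rows).
#' @return a [FeatureScaler-class].
#' @export
fitScaler <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need >= 2 training genes to fit a scaler", call. = FALSE)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl == 0] <- 1
  new("FeatureScaler", center = ctr, scale = scl)
}

#' Apply a fitted scaler
#' @param scaler a [FeatureScaler-class].
#' @param features numeric matrix or vector of raw feature values.
#' @return standardized values, same shape as the input.
#' @export
applyScaler <- function(scaler, features) {
  if (is.null(dim(features)))
    return((features - scaler@center) / scaler@scale)
  sweep(sweep(as.matrix(features), 2L, scaler@center, "-"),
        2L, scaler@scale, "/")
}

#' Identity scaler
#'
#' A scaler that leaves features untouched; convenient for layout tests
#' and for feeding pre-scaled matrices.
#' @param nF feature dimension.
#' @return a [FeatureScaler-class] with center 0 and scale 1.
#' @export
identityScaler <- function(nF = 12L) {
  new("FeatureScaler", center = rep(0, nF), scale = rep(1, nF))
}

#' Build the 2k x n_f input matrix for one gene
#'
#' Interleaves the center gene's scaled feature vector with its k
#' neighbors' vectors in descending-correlation order:
#' \code{[x_i, x_s1, x_i, x_s2, ..., x_i, x_sk]}.  With convolution filter
#' size 2 and stride 2, first-layer window j then covers exactly the pair
#' (center gene, j-th neighbor), which is what lets the filters compare a
#' gene with each of its most similar genes.
#'
#' @param gene center gene symbol.
#' @param features numeric matrix, genes x n_f, row names = symbols; must
#'   contain the gene and all its neighbors.
#' @param network a [SimilarityNetwork-class].
#' @param scaler a fitted [FeatureScaler-class] (see [fitScaler()]).
#' @return a [FeatureTensor-class] with \code{2 * netK(network)} rows.
#' @export
buildTensor <- function(gene, features, network, scaler) {
  if (!gene %in% rownames(features))
    stop("gene '", gene, "' has no feature vector", call. = FALSE)
  nbs <- network@neighbors[gene, ]
  missing <- setdiff(nbs, rownames(features))
  if (length(missing))
    stop("neighbor(s) of '", gene, "' lack feature vectors: ",
         paste(missing, collapse = ", "), call. = FALSE)
  k <- netK(network)
  nF <- ncol(features)
  xi <- applyScaler(scaler, features[gene, ])
  xs <- applyScaler(scaler, features[nbs, , drop = FALSE])
  vals <- matrix(NA_real_, 2L * k, nF)
  vals[seq(1L, 2L * k, by = 2L), ] <- rep(xi, each = k)
  vals[seq(2L, 2L * k, by = 2L), ] <- xs
  colnames(vals) <- colnames(features)
  new("FeatureTensor", geneId = gene, values = vals, k = k,
      nF = as.integer(nF))
}

#' Build input matrices for many genes as one array
#'
#' Stacks [buildTensor()] outputs into an n x 2k x n_f array (dimension
#' names carry the gene symbols), the batch format the classifier
#' consumes.
#'
#' @param genes character vector of center genes.
#' @inheritParams buildTensor
#' @return numeric array with dim \code{c(length(genes), 2k, n_f)}.
#' @export
buildTensorSet <- function(genes, features, network, scaler) {
  k <- netK(network)
  nF <- ncol(features)
  out <- array(NA_real_, c(length(genes), 2L * k, nF),
               dimnames = list(genes, NULL, colnames(features)))
  for (i in seq_along(genes))
    out[i, , ] <- tensorValues(
      buildTensor(genes[i], features, network, scaler))
  out
}
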