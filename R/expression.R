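# Expression preprocessing (FPKM -> TPM -> filtered log2-TPM) and the
# PCC-based k-nearest-neighbor gene similarity network.

#' Read a gene expression TSV
#'
#' Genes in rows (first column holds symbols), samples in columns (header
#' row holds barcodes).
#'
#' @param path TSV file path.
#' @param unit unit tag of the stored values (default \code{"FPKM"}).
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path, unit = "FPKM") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L)
    stop("expression table needs a gene column plus >= 1 sample column",
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  ExpressionMatrix(m, unit)
}

#' Write an expression matrix as TSV
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  df <- data.frame(gene = geneIds(x), exprValues(x),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per-sample rescaling \code{TPM[g, s] = FPKM[g, s] / sum_g' FPKM[g', s]
#' * 1e6}, so every sample column sums to one million.  Already-TPM input
#' passes through the same rescale, which is a fixed point.
#'
#' @param x an [ExpressionMatrix-class] with unit \code{"FPKM"} (or
#'   \code{"TPM"}, on which the operation is idempotent).
#' @return an [ExpressionMatrix-class] with unit \code{"TPM"}.
#' @examples
#' m <- matrix(c(2, 3, 5), ncol = 1,
#'             dimnames = list(c("A", "B", "C"), "s1"))
#' exprValues(fpkmToTpm(ExpressionMatrix(m, "FPKM")))
#' @export
fpkmToTpm <- function(x) {
  if (!exprUnit(x) %in% c("FPKM", "TPM"))
    stop("fpkmToTpm expects FPKM (or TPM) input, got ", exprUnit(x),
         call. = FALSE)
  v <- exprValues(x)
  cs <- colSums(v)
  bad <- cs <= 0
  if (any(bad))
    stop("sample(s) with all-zero expression: ",
         paste(colnames(v)[bad], collapse = ", "), call. = FALSE)
  ExpressionMatrix(sweep(v, 2L, cs, "/") * 1e6, "TPM")
}

#' Filter and log-transform a TPM matrix
#'
#' Three steps: (1) TPM values below 1 are treated as unreliable and set
#' to 0; (2) the \code{log2(TPM + 1)} transform is applied; (3) genes with
#' a nonzero value in fewer than \code{minExpressedFraction} of samples
#' are removed.  Surviving genes keep their input order.
#'
#' @param x an [ExpressionMatrix-class] with unit \code{"TPM"}.
#' @param minExpressedFraction minimum fraction of samples in which a gene
#'   must be expressed (default 0.10).
#' @return an [ExpressionMatrix-class] with unit \code{"LOG2_TPM"}.
#' @export
preprocessExpression <- function(x, minExpressedFraction = 0.10) {
  if (exprUnit(x) != "TPM")
    stop("preprocessExpression expects TPM input, got ", exprUnit(x),
         call. = FALSE)
  stopifnot(minExpressedFraction > 0, minExpressedFraction <= 1)
  v <- exprValues(x)
  v[v < 1] <- 0
  v <- log2(v + 1)
  frac <- rowMeans(v > 0)
  ExpressionMatrix(v[frac >= minExpressedFraction, , drop = FALSE],
                   "LOG2_TPM")
}

#' Pearson correlation of two expression profiles
#'
#' Plain Pearson correlation across samples.  When either profile has zero
#' variance the coefficient is undefined (0/0); this returns 0 there and
#' attaches the attribute \code{degenerate = TRUE} so callers can drop
#' such genes.
#'
#' @param ei,ej numeric vectors of equal length (>= 2 samples).
#' @return correlation in \code{[-1, 1]}, with attribute
#'   \code{degenerate} when a zero-variance profile was seen.
#' @export
pearsonSimilarity <- function(ei, ej) {
  if (length(ei) != length(ej))
    stop("profiles have different lengths (", length(ei), " vs ",
         length(ej), ")", call. = FALSE)
  stopifnot(length(ei) >= 2L)
  if (stats::sd(ei) == 0 || stats::sd(ej) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(ei, ej)
}

# Full gene-gene PCC matrix; zero-variance rows correlate 0 with
# everything (with a warning) instead of propagating NA.
.pccMatrix <- function(v) {
  sds <- apply(v, 1L, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance gene profile(s); their ",
            "correlations are set to 0", call. = FALSE)
  p <- suppressWarnings(stats::cor(t(v)))
  p[degenerate, ] <- 0
  p[, degenerate] <- 0
  p
}

#' Build the k-nearest-neighbor co-expression network
#'
#' Connects every gene to the k genes with the largest Pearson correlation
#' to it (self excluded), computed on the preprocessed log2-TPM values.
#' Ties at the k-th correlation are broken by ascending gene symbol, which
#' makes the network invariant to gene row order.  The network is directed:
#' each gene owns its ranked list.
#'
#' @param x an [ExpressionMatrix-class], normally unit \code{"LOG2_TPM"}.
#' @param k neighbor count (default 7, the recommended setting for
#'   cohorts without their own grid search).
#' @return a [SimilarityNetwork-class].
#' @export
buildKnnNetwork <- function(x, k = 7L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  v <- exprValues(x)
  genes <- rownames(v)
  n <- length(genes)
  if (k >= n)
    stop("k (", k, ") must be smaller than the gene count (", n, ")",
         call. = FALSE)
  p <- .pccMatrix(v)
  nb <- matrix(NA_character_, n, k, dimnames = list(genes, NULL))
  w <- matrix(NA_real_, n, k, dimnames = list(genes, NULL))
  symOrder <- order(genes)  # ascending-symbol permutation for tie-break
  for (i in seq_len(n)) {
    pc <- p[i, ]
    pc[i] <- -Inf
    ord <- symOrder[order(-pc[symOrder])]  # stable: desc pcc, asc symbol
    top <- ord[seq_len(k)]
    nb[i, ] <- genes[top]
    w[i, ] <- pc[top]
  }
  new("SimilarityNetwork", k = k, neighbors = nb, weights = w)
}

#' Restrict a network to a smaller k
#'
#' Keeps each gene's top \code{k} neighbors; the ranked lists for a
#' smaller k are prefixes of the larger-k lists.
#'
#' @param network a [SimilarityNetwork-class].
#' @param k new neighbor count, \code{<= netK(network)}.
#' @return a [SimilarityNetwork-class] with neighbor count \code{k}.
#' @export
truncateNetwork <- function(network, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= netK(network))
  new("SimilarityNetwork", k = k,
      neighbors = network@neighbors[, seq_len(k), drop = FALSE],
      weights = network@weights[, seq_len(k), drop = FALSE])
}

#' Write a network as a 3-column edge TSV
#'
#' Columns \code{gene}, \code{neighbor}, \code{pcc}; neighbors grouped per
#' gene in rank order.
#'
#' @param network a [SimilarityNetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path) {
  genes <- geneIds(network)
  k <- netK(network)
  df <- data.frame(gene = rep(genes, each = k),
                   neighbor = as.vector(t(network@neighbors)),
                   pcc = as.vector(t(network@weights)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
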