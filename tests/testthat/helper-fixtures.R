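# Shared fixture builders: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal mutation record data.frame in the package's internal layout.
makeRecords <- function(classes, codons = NULL, genes = "G1",
                        samples = NULL, proteinChanges = NULL) {
  n <- length(classes)
  if (is.null(codons)) codons <- rep(NA_integer_, n)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  if (is.null(proteinChanges)) proteinChanges <- rep(NA_character_, n)
  data.frame(gene_id = rep_len(genes, n),
             sample_id = rep_len(samples, n),
             variant_class = factor(classes, levels = variantClasses()),
             codon_position = as.integer(codons),
             protein_change = proteinChanges,
             stringsAsFactors = FALSE)
}

# Write a GDC-flavoured MAF file and return its path.
writeMafFile <- function(df, path = tempfile(fileext = ".maf.tsv"),
                         comment = TRUE) {
  con <- file(path, "w")
  if (comment) writeLines("#version gdc-1.0", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  path
}

# Random expression matrix on the log2 scale, wrapped as LOG2_TPM.
randomLogExpression <- function(nGenes, nSamples, seed) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(nGenes * nSamples, mean = 5, sd = 2),
                nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%03d", seq_len(nSamples))))
    v[v < 0] <- 0
  })
  ExpressionMatrix(v, "LOG2_TPM")
}

# Independent direct-summation oracle for the normalized entropy,
# written against the formula, not the implementation.
entropyOracle <- function(counts) {
  counts <- counts[counts > 0]
  m <- sum(counts)
  if (m <= 1) return(0)
  acc <- 0
  for (k in counts) {
    p <- k / m
    acc <- acc - p * log2(p)
  }
  acc / log2(m)
}

# Brute-force all-pairs AUC: P(score+ > score-) + P(tie)/2.
aucOracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Small feature matrix keyed by gene symbol for tensor tests.
randomFeatures <- function(genes, nF = 12L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(genes) * nF), length(genes), nF,
                dimnames = list(genes, featureNames()[seq_len(nF)]))
  })
  m
}

# Tiny training setup reused by model tests: separable tensors.
separableTensors <- function(n = 8L, k = 7L, nF = 12L) {
  X <- array(0, c(n, 2L * k, nF))
  half <- n %/% 2L
  X[seq_len(half), , ] <- 1
  list(X = X, y = rep(c(1, 0), c(half, n - half)))
}
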