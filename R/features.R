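# The 12 per-gene mutation features: class fractions, pseudocounted
# ratios, and the two normalized entropies.

INACTIVATING_CLASSES <- c("nonsense", "lost_start", "lost_stop",
                          "splice_site")

#' Feature names in canonical order
#'
#' The fixed order of the 12 mutation features: the eight class fractions,
#' the two ratio features, then the two normalized entropies.
#' @return character vector of length 12.
#' @export
featureNames <- function() FEATURE_NAMES

.normalizedEntropy <- function(counts) {
  counts <- counts[counts > 0]
  m <- sum(counts)
  if (m <= 1) return(0)
  p <- counts / m
  -sum(p * log2(p)) / log2(m)
}

#' Normalized missense position entropy
#'
#' Shannon entropy of the distribution of a gene's missense mutations over
#' codons, normalized by \code{log2(m)} where m is the total missense
#' count, so that a uniform spread over codons scores 1 and a single
#' hotspot scores 0.  With m <= 1 the normalizer vanishes and the entropy
#' is defined as 0 (one mutation carries no positional information).
#'
#' @param codonCounts named or unnamed non-negative integer vector of
#'   missense counts per codon.
#' @return entropy in \code{[0, 1]}.
#' @examples
#' missensePositionEntropy(c(1, 1, 1, 1))   # uniform -> 1
#' missensePositionEntropy(c(5))            # single hotspot -> 0
#' @export
missensePositionEntropy <- function(codonCounts) {
  if (any(codonCounts < 0)) stop("codon counts must be >= 0", call. = FALSE)
  .normalizedEntropy(codonCounts)
}

# Bin labels for the total mutation entropy.  Missense: one bin per codon
# (records without a codon each get their own bin); silent: one bin per
# distinct silent change, keyed by codon when available, else by the raw
# protein-change string, else per record; inactivating classes share one
# pooled bin; frameshift/inframe indels and unrecognized classes get one
# bin per class.
.entropyBins <- function(records) {
  cls <- as.character(records$variant_class)
  n <- length(cls)
  key <- character(n)
  perRecord <- sprintf("rec#%d", seq_len(n))
  codon <- records$codon_position
  pchg <- records$protein_change
  if (is.null(pchg)) pchg <- rep(NA_character_, n)
  isMis <- cls == "missense"
  key[isMis] <- ifelse(!is.na(codon[isMis]),
                       sprintf("missense@%d", codon[isMis]),
                       perRecord[isMis])
  isSil <- cls == "silent"
  key[isSil] <- ifelse(!is.na(codon[isSil]),
                       sprintf("silent@%d", codon[isSil]),
                       ifelse(!is.na(pchg[isSil]) & nzchar(pchg[isSil]),
                              paste0("silent:", pchg[isSil]),
                              perRecord[isSil]))
  isInact <- cls %in% INACTIVATING_CLASSES
  key[isInact] <- "inactivating"
  rest <- !(isMis | isSil | isInact)
  key[rest] <- cls[rest]
  key
}

#' Normalized total mutation entropy
#'
#' Shannon entropy over mutation bins, normalized by \code{log2(m)} with m
#' the gene's total mutation count.  Missense mutations are binned by
#' codon, distinct silent mutations get their own bins, the inactivating
#' classes (nonsense, lost start/stop, splice site) are pooled into a
#' single bin, and each remaining class forms one bin.  0 when m <= 1.
#'
#' @param records mutation record data.frame for one gene.
#' @return entropy in \code{[0, 1]}.
#' @export
mutationEntropy <- function(records) {
  if (nrow(records) == 0L) return(0)
  .normalizedEntropy(table(.entropyBins(records)))
}

#' Twelve mutation features for one gene
#'
#' Computes the canonical 12-feature vector from a gene's mutation records:
#' eight class fractions (with lost start and lost stop pooled), the
#' missense-to-silent and non-silent-to-silent ratios with add-one
#' pseudocounts, and the two normalized entropies.  The recurrent missense
#' fraction counts missense mutations at codons hit by at least two
#' missense mutations across the cohort's samples.  Records with an
#' unrecognized class count toward the total (fraction denominators) but
#' toward no named fraction, and are excluded from the non-silent count.
#'
#' @param records mutation record data.frame for a single gene (>= 1 row).
#' @return named numeric vector of length 12 in [featureNames()] order.
#' @examples
#' rec <- data.frame(
#'   gene_id = "G", sample_id = paste0("S", 1:8),
#'   variant_class = factor(rep(c("missense", "silent", "nonsense"),
#'                              c(4, 2, 2)),
#'                          levels = driverCNN::variantClasses()),
#'   codon_position = c(7L, 7L, 30L, 45L, NA, NA, NA, NA),
#'   protein_change = NA_character_)
#' featureVector(rec)
#' @export
featureVector <- function(records) {
  m <- nrow(records)
  if (m == 0L)
    stop("featureVector requires at least one mutation record",
         call. = FALSE)
  cls <- as.character(records$variant_class)
  nOf <- function(what) sum(cls %in% what)
  nSilent <- nOf("silent")
  nMissense <- nOf("missense")
  misCodons <- records$codon_position[cls == "missense"]
  codonTab <- table(misCodons[!is.na(misCodons)])
  recurrent <- sum(codonTab[codonTab >= 2L])
  nonSilent <- nOf(setdiff(VARIANT_CLASSES, c("silent", "other")))
  out <- c(
    silent_fraction = nSilent / m,
    nonsense_fraction = nOf("nonsense") / m,
    splice_site_fraction = nOf("splice_site") / m,
    missense_fraction = nMissense / m,
    recurrent_missense_fraction = recurrent / m,
    frameshift_indel_fraction = nOf("frameshift_indel") / m,
    inframe_indel_fraction = nOf("inframe_indel") / m,
    lost_start_stop_fraction = nOf(c("lost_start", "lost_stop")) / m,
    missense_to_silent = (nMissense + 1) / (nSilent + 1),
    non_silent_to_silent = (nonSilent + 1) / (nSilent + 1),
    normalized_missense_position_entropy =
      missensePositionEntropy(as.numeric(codonTab)),
    normalized_mutation_entropy = mutationEntropy(records)
  )
  out[FEATURE_NAMES]
}

#' Internal variant class vocabulary
#' @return character vector of recognized variant classes.
#' @export
variantClasses <- function() VARIANT_CLASSES

#' Per-gene feature matrix for a cohort
#'
#' Applies [featureVector()] to every gene with at least one mutation
#' record, returning a genes x 12 matrix (row names are gene symbols,
#' columns in [featureNames()] order).
#'
#' @param records mutation record data.frame (typically [readMAF()] output
#'   after [filterHypermutated()]).
#' @return numeric matrix, genes x 12.
#' @export
mutationFeatures <- function(records) {
  records <- records[!is.na(records$gene_id) & nzchar(records$gene_id), ,
                     drop = FALSE]
  genes <- sort(unique(records$gene_id))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(FEATURE_NAMES),
                dimnames = list(genes, FEATURE_NAMES))
  idx <- split(seq_len(nrow(records)), records$gene_id)
  for (g in genes)
    out[g, ] <- featureVector(records[idx[[g]], , drop = FALSE])
  out
}

#' Write a per-gene feature table as TSV
#'
#' One header row, gene symbol first, then the 12 features in canonical
#' order, printed with full double precision.
#'
#' @param features matrix from [mutationFeatures()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  df <- data.frame(gene = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene feature table written by [writeFeatureTable()]
#' @param path TSV path.
#' @return numeric matrix, genes x 12.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(c("gene", FEATURE_NAMES), names(df))
  if (length(miss))
    stop("feature table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, FEATURE_NAMES, drop = FALSE])
  rownames(m) <- df$gene
  m
}
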