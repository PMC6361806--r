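# MAF-style mutation table parsing and sample-level QC.

# GDC MAF Variant_Classification vocabulary -> internal variant classes.
# Unrecognized strings fall through to "other" (kept in the record list;
# they count toward mutation totals but toward no named fraction).
.VARIANT_CLASS_MAP <- c(
  "Silent"                 = "silent",
  "Missense_Mutation"      = "missense",
  "Nonsense_Mutation"      = "nonsense",
  "Splice_Site"            = "splice_site",
  "Frame_Shift_Del"        = "frameshift_indel",
  "Frame_Shift_Ins"        = "frameshift_indel",
  "In_Frame_Del"           = "inframe_indel",
  "In_Frame_Ins"           = "inframe_indel",
  "Translation_Start_Site" = "lost_start",
  "Nonstop_Mutation"       = "lost_stop"
)

.mapVariantClass <- function(x) {
  cls <- unname(.VARIANT_CLASS_MAP[x])
  cls[is.na(cls)] <- "other"
  factor(cls, levels = VARIANT_CLASSES)
}

# First codon number of a "p.<aa><number>..." protein change, NA otherwise.
.parseCodon <- function(proteinChange) {
  hit <- grepl("^p\\.[A-Za-z*]+[0-9]+", proteinChange)
  num <- suppressWarnings(
    as.integer(sub("^p\\.[A-Za-z*]+([0-9]+).*$", "\\1", proteinChange)))
  ifelse(hit, num, NA_integer_)
}

#' Read a MAF-style somatic mutation table
#'
#' Parses a tab-delimited mutation annotation table into one record per
#' variant.  Required columns: \code{Hugo_Symbol},
#' \code{Tumor_Sample_Barcode}, \code{Variant_Classification}.  The codon
#' position is taken from \code{HGVSp_Short} when it matches a
#' \code{p.<aa><number>...} pattern, else from a leading integer in
#' \code{Protein_position}; it is NA when neither is available.  Lines
#' starting with \code{#} are treated as comments; extra columns are
#' ignored.
#'
#' @param path path to the tab-delimited file.
#' @return data.frame of mutation records with columns \code{gene_id},
#'   \code{sample_id}, \code{variant_class} (factor over the internal
#'   class vocabulary), \code{codon_position} (integer, NA allowed) and
#'   \code{protein_change} (raw string, NA allowed).
#' @examples
#' maf <- data.frame(Hugo_Symbol = "TP53", Tumor_Sample_Barcode = "S1",
#'                   Variant_Classification = "Missense_Mutation",
#'                   HGVSp_Short = "p.R175H")
#' tf <- tempfile(fileext = ".maf.tsv")
#' write.table(maf, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readMAF(tf)
#' @export
readMAF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                "Variant_Classification")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("MAF is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("MAF file '", path, "' has no data rows", call. = FALSE)
    return(emptyMutationRecords())
  }
  pc <- rep(NA_character_, nrow(tab))
  if ("HGVSp_Short" %in% names(tab)) pc <- as.character(tab[["HGVSp_Short"]])
  pc[!is.na(pc) & !nzchar(pc)] <- NA_character_
  codon <- .parseCodon(ifelse(is.na(pc), "", pc))
  if ("Protein_position" %in% names(tab)) {
    fallback <- suppressWarnings(
      as.integer(sub("^([0-9]+).*$", "\\1",
                     as.character(tab[["Protein_position"]]))))
    codon[is.na(codon)] <- fallback[is.na(codon)]
  }
  codon[!is.na(codon) & codon < 1L] <- NA_integer_
  data.frame(gene_id = as.character(tab[["Hugo_Symbol"]]),
             sample_id = as.character(tab[["Tumor_Sample_Barcode"]]),
             variant_class = .mapVariantClass(
               as.character(tab[["Variant_Classification"]])),
             codon_position = codon,
             protein_change = pc,
             stringsAsFactors = FALSE)
}

#' @rdname readMAF
#' @export
emptyMutationRecords <- function() {
  data.frame(gene_id = character(), sample_id = character(),
             variant_class = factor(character(), levels = VARIANT_CLASSES),
             codon_position = integer(), protein_change = character(),
             stringsAsFactors = FALSE)
}

#' Remove hypermutated samples
#'
#' Drops every record belonging to a sample that carries strictly more than
#' \code{threshold} intragenic somatic variants (records with a non-empty
#' gene symbol).  Samples at exactly the threshold are retained.  Record
#' order is preserved, and the filter is idempotent.
#'
#' @param records mutation record data.frame as returned by [readMAF()].
#' @param threshold integer, default 1000 variants per sample.
#' @return filtered record data.frame.
#' @export
filterHypermutated <- function(records, threshold = 1000L) {
  stopifnot(threshold >= 1L)
  if (nrow(records) == 0L) return(records)
  intragenic <- !is.na(records$gene_id) & nzchar(records$gene_id)
  counts <- table(records$sample_id[intragenic])
  hyper <- names(counts)[counts > threshold]
  out <- records[!(records$sample_id %in% hyper), , drop = FALSE]
  rownames(out) <- NULL
  out
}
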