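# Seeded synthetic cohorts: MAF-style mutation catalogs with planted
# driver signal (codon hotspots, elevated missense share) and FPKM
# expression with correlated blocks, so the whole pipeline is testable
# without downloads.

.MAF_CLASS_OUT <- c(silent = "Silent", missense = "Missense_Mutation",
                    nonsense = "Nonsense_Mutation",
                    splice_site = "Splice_Site",
                    frameshift_indel = "Frame_Shift_Del",
                    inframe_indel = "In_Frame_Del",
                    lost_start = "Translation_Start_Site",
                    lost_stop = "Nonstop_Mutation",
                    other = "Unknown")

#' Synthetic cohort configuration
#'
#' Defaults describe a desk-scale cohort: 300 genes, 30 drivers, 60 tumor
#' samples — small enough for minutes-scale cross-validation yet large
#' enough for stable AUC estimates.  Driver genes receive extra missense
#' mutations, a fraction \code{hotspotConcentration} of which pile onto a
#' single hotspot codon (low positional entropy); passengers mutate at a
#' background rate with the background class mix and uniform codons (high
#' entropy).  Expression is generated from per-block latent factors, with
#' drivers co-assigned to a few blocks so their network neighborhoods are
#' enriched for other drivers.
#'
#' @param nGenes,nDrivers,nSamples cohort dimensions.
#' @param hotspotConcentration fraction of a driver's missense mutations
#'   placed on its hotspot codon.
#' @param driverMissenseRate expected missense mutations per driver gene.
#' @param passengerMutationRate expected mutations per passenger gene
#'   (all classes); drivers draw their non-missense mutations at the
#'   corresponding non-missense share of this rate.
#' @param classMix background probabilities over variant classes (named,
#'   must sum to 1).
#' @param nCorrelatedBlocks number of co-expression blocks.
#' @param blockNoiseSd per-gene expression noise around the block factor,
#'   on the log2 scale.
#' @param nDriverBlocks how many blocks the drivers are packed into.
#' @param geneLengthCodons codon count per gene (uniform positions are
#'   drawn from it).
#' @param nHypermutated number of injected hypermutated samples (0 by
#'   default; used to exercise the QC filter).
#' @param hypermutatedVariants variants per injected hypermutated sample.
#' @param seed RNG seed; the cohort is fully reproducible from the
#'   configuration.
#' @return named list of class \code{simulation_config}.
#' @export
simulationConfig <- function(nGenes = 300L, nDrivers = 30L, nSamples = 60L,
                             hotspotConcentration = 0.8,
                             driverMissenseRate = 20,
                             passengerMutationRate = 8,
                             classMix = c(silent = 0.30, missense = 0.50,
                                          nonsense = 0.04,
                                          splice_site = 0.03,
                                          frameshift_indel = 0.06,
                                          inframe_indel = 0.03,
                                          lost_start = 0.005,
                                          lost_stop = 0.005,
                                          other = 0.03),
                             nCorrelatedBlocks = 10L, blockNoiseSd = 0.5,
                             nDriverBlocks = 3L, geneLengthCodons = 500L,
                             nHypermutated = 0L,
                             hypermutatedVariants = 1500L, seed = 1L) {
  stopifnot(nDrivers < nGenes, nSamples >= 2L,
            hotspotConcentration >= 0, hotspotConcentration <= 1,
            driverMissenseRate > 0, passengerMutationRate > 0,
            abs(sum(classMix) - 1) < 1e-8,
            all(names(classMix) %in% VARIANT_CLASSES),
            nCorrelatedBlocks >= 1L, blockNoiseSd >= 0,
            nDriverBlocks >= 1L, nDriverBlocks <= nCorrelatedBlocks)
  structure(list(nGenes = as.integer(nGenes),
                 nDrivers = as.integer(nDrivers),
                 nSamples = as.integer(nSamples),
                 hotspotConcentration = hotspotConcentration,
                 driverMissenseRate = driverMissenseRate,
                 passengerMutationRate = passengerMutationRate,
                 classMix = classMix,
                 nCorrelatedBlocks = as.integer(nCorrelatedBlocks),
                 blockNoiseSd = blockNoiseSd,
                 nDriverBlocks = as.integer(nDriverBlocks),
                 geneLengthCodons = as.integer(geneLengthCodons),
                 nHypermutated = as.integer(nHypermutated),
                 hypermutatedVariants = as.integer(hypermutatedVariants),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.simGeneNames <- function(config) sprintf("G%04d", seq_len(config$nGenes))

.simSampleNames <- function(config) sprintf("S%03d", seq_len(config$nSamples))

# Amino-acid letters for cosmetic protein-change strings.
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.proteinChange <- function(codons, silent = FALSE) {
  ref <- sample(.AA, length(codons), replace = TRUE)
  alt <- ifelse(rep_len(silent, length(codons)), ref,
                sample(.AA, length(codons), replace = TRUE))
  sprintf("p.%s%d%s", ref, codons, alt)
}

#' Simulate a MAF-style mutation catalog with planted driver signal
#'
#' Driver genes draw Poisson missense counts at
#' \code{driverMissenseRate}, a share \code{hotspotConcentration} of which
#' lands on one hotspot codon, plus background non-missense mutations;
#' passenger genes draw Poisson counts at \code{passengerMutationRate}
#' with the background class mix and uniform codon positions.  Optionally
#' injects hypermutated samples (each with
#' \code{hypermutatedVariants} > 1000 variants) to exercise the QC
#' filter.  Fully deterministic given the configuration.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{records} (mutation record data.frame),
#'   \code{drivers} (character vector of planted driver symbols),
#'   \code{hotspots} (named integer vector of driver hotspot codons).
#' @export
simulateMutations <- function(config) {
  genes <- .simGeneNames(config)
  samples <- .simSampleNames(config)
  mix <- config$classMix
  pMis <- unname(mix["missense"])
  mixNoMis <- mix[names(mix) != "missense"]
  mixNoMis <- mixNoMis / sum(mixNoMis)
  out <- NULL
  withr::with_seed(config$seed, {
    drivers <- sort(sample(genes, config$nDrivers))
    isDriver <- genes %in% drivers
    hotspots <- stats::setNames(
      sample.int(config$geneLengthCodons, config$nDrivers, replace = TRUE),
      drivers)
    recs <- vector("list", config$nGenes)
    for (i in seq_along(genes)) {
      g <- genes[i]
      if (isDriver[i]) {
        nMis <- stats::rpois(1L, config$driverMissenseRate)
        nBg <- stats::rpois(1L, config$passengerMutationRate * (1 - pMis))
        clsBg <- sample(names(mixNoMis), nBg, replace = TRUE,
                        prob = mixNoMis)
        cls <- c(rep("missense", nMis), clsBg)
        codon <- rep(NA_integer_, length(cls))
        if (nMis > 0L) {
          atHot <- stats::runif(nMis) < config$hotspotConcentration
          codon[seq_len(nMis)] <- ifelse(
            atHot, hotspots[g],
            sample.int(config$geneLengthCodons, nMis, replace = TRUE))
        }
      } else {
        nTot <- stats::rpois(1L, config$passengerMutationRate)
        cls <- sample(names(mix), nTot, replace = TRUE, prob = mix)
        codon <- rep(NA_integer_, length(cls))
        isMis <- cls == "missense"
        codon[isMis] <- sample.int(config$geneLengthCodons, sum(isMis),
                                   replace = TRUE)
      }
      if (!length(cls)) { recs[[i]] <- NULL; next }
      isSil <- cls == "silent"
      codon[isSil] <- sample.int(config$geneLengthCodons, sum(isSil),
                                 replace = TRUE)
      pchg <- rep(NA_character_, length(cls))
      hasCodon <- !is.na(codon)
      pchg[hasCodon] <- .proteinChange(codon[hasCodon],
                                       silent = isSil[hasCodon])
      recs[[i]] <- data.frame(
        gene_id = g,
        sample_id = sample(samples, length(cls), replace = TRUE),
        variant_class = factor(cls, levels = VARIANT_CLASSES),
        codon_position = codon, protein_change = pchg,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    if (config$nHypermutated > 0L) {
      hyp <- vector("list", config$nHypermutated)
      for (h in seq_len(config$nHypermutated)) {
        nv <- config$hypermutatedVariants
        cls <- sample(names(mix), nv, replace = TRUE, prob = mix)
        codon <- ifelse(cls %in% c("missense", "silent"),
                        sample.int(config$geneLengthCodons, nv,
                                   replace = TRUE),
                        NA_integer_)
        pchg <- rep(NA_character_, nv)
        hasCodon <- !is.na(codon)
        pchg[hasCodon] <- .proteinChange(codon[hasCodon],
                                         silent = cls[hasCodon] == "silent")
        hyp[[h]] <- data.frame(
          gene_id = sample(genes, nv, replace = TRUE),
          sample_id = sprintf("HYPER%02d", h),
          variant_class = factor(cls, levels = VARIANT_CLASSES),
          codon_position = codon, protein_change = pchg,
          stringsAsFactors = FALSE)
      }
      records <- rbind(records, do.call(rbind, hyp))
    }
    rownames(records) <- NULL
    out <- list(records = records, drivers = drivers, hotspots = hotspots)
  })
  out
}

#' Simulate block-correlated FPKM expression
#'
#' Genes are partitioned into \code{nCorrelatedBlocks} blocks sharing a
#' per-sample latent factor; a gene's log2 expression is its baseline plus
#' the block factor plus Gaussian noise of sd \code{blockNoiseSd}, then
#' exponentiated to FPKM-like non-negative values.  Driver genes are
#' packed into the first \code{nDriverBlocks} blocks, so their
#' nearest-neighbor lists are enriched for fellow drivers.
#'
#' @param config a [simulationConfig()].
#' @param drivers character vector of driver symbols (from
#'   [simulateMutations()]); defaults to none, giving a label-free block
#'   structure.
#' @return an [ExpressionMatrix-class] with unit \code{"FPKM"}.
#' @export
simulateExpression <- function(config, drivers = character()) {
  genes <- .simGeneNames(config)
  samples <- .simSampleNames(config)
  out <- NULL
  withr::with_seed(config$seed + 1L, {
    block <- integer(config$nGenes)
    names(block) <- genes
    isDriver <- genes %in% drivers
    block[isDriver] <- rep_len(seq_len(config$nDriverBlocks),
                               sum(isDriver))
    block[!isDriver] <- rep_len(seq_len(config$nCorrelatedBlocks),
                                sum(!isDriver))
    z <- matrix(stats::rnorm(config$nCorrelatedBlocks * config$nSamples),
                config$nCorrelatedBlocks, config$nSamples)
    mu <- stats::runif(config$nGenes, 1, 6)
    eps <- matrix(stats::rnorm(config$nGenes * config$nSamples,
                               sd = config$blockNoiseSd),
                  config$nGenes, config$nSamples)
    log2e <- mu + z[block, , drop = FALSE] + eps
    v <- 2^log2e
    dimnames(v) <- list(genes, samples)
    out <- ExpressionMatrix(v, "FPKM")
  })
  out
}

#' Simulate a full cohort
#'
#' Runs [simulateMutations()] and [simulateExpression()] under one
#' configuration.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{records}, \code{drivers}, \code{hotspots},
#'   \code{expression} and the \code{config}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  mut <- simulateMutations(config)
  expr <- simulateExpression(config, mut$drivers)
  c(mut, list(expression = expr, config = config))
}

#' Write a simulated cohort as plain-text fixtures
#'
#' Writes \code{mutations.maf.tsv} (MAF-style, GDC column vocabulary),
#' \code{expression.fpkm.tsv}, \code{drivers.txt} (one symbol per line)
#' and \code{config.yaml}.  The mutation and expression files round-trip
#' losslessly through [readMAF()] and [readExpression()].
#'
#' @param cohort a [simulateCohort()] result.
#' @param outDir output directory (created if missing).
#' @return named character vector of the written file paths.
#' @export
writeFixture <- function(cohort, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir))
    stop("cannot create output directory: ", outDir, call. = FALSE)
  paths <- c(mutations = file.path(outDir, "mutations.maf.tsv"),
             expression = file.path(outDir, "expression.fpkm.tsv"),
             drivers = file.path(outDir, "drivers.txt"),
             config = file.path(outDir, "config.yaml"))
  rec <- cohort$records
  maf <- data.frame(
    Hugo_Symbol = rec$gene_id,
    Tumor_Sample_Barcode = rec$sample_id,
    Variant_Classification =
      unname(.MAF_CLASS_OUT[as.character(rec$variant_class)]),
    HGVSp_Short = ifelse(is.na(rec$protein_change), "",
                         rec$protein_change),
    stringsAsFactors = FALSE)
  utils::write.table(maf, paths[["mutations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeExpression(cohort$expression, paths[["expression"]])
  writeLines(cohort$drivers, paths[["drivers"]])
  cfg <- unclass(cohort$config)
  cfg$classMix <- as.list(cfg$classMix)
  yaml::write_yaml(cfg, paths[["config"]])
  paths
}

#' Read a driver gene list (one symbol per line)
#' @param path text file path.
#' @return character vector of symbols, blanks dropped.
#' @export
readDriverList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
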