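#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end granges
#' @importFrom IRanges IRanges reduce findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

VALID_ALLELES <- c("A", "C", "G", "T", "N")

#' Genotype panel for a set of inbred strains
#'
#' A \code{StrainPanel} holds single-allele SNP calls for a panel of fully
#' homozygous (inbred) strains.  It extends
#' \linkS4class{RangedSummarizedExperiment}: rows are SNPs with genomic
#' coordinates in \code{rowRanges} (1-based positions, \code{rsID} as row
#' names), columns are strains, and the single assay \code{"calls"} is a
#' character matrix with entries in \code{A, C, G, T, N} (\code{N} =
#' missing).  Because the strains are inbred, one allele letter per strain
#' suffices; heterozygous input is rejected at construction.
#'
#' @slot . inherits all slots from \code{RangedSummarizedExperiment}.
#' @seealso \code{\link{StrainPanel}} (constructor),
#'   \code{\link{readGenotypes}}, \code{\link{simulatePanel}}
#' @exportClass StrainPanel
setClass("StrainPanel", contains = "RangedSummarizedExperiment")

.validStrainPanel <- function(object) {
    msg <- character(0)
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    calls <- SummarizedExperiment::assay(object, "calls")
    if (!is.character(calls))
        msg <- c(msg, "assay 'calls' must be a character matrix")
    else {
        bad <- !(calls %in% VALID_ALLELES)
        if (any(bad))
            msg <- c(msg, sprintf("invalid allele symbol(s): %s",
                paste(unique(calls[bad])[seq_len(min(3, sum(bad)))],
                      collapse = ", ")))
        ## biallelic after dropping N
        nAllele <- apply(calls, 1L, function(x)
            length(unique(x[x != "N"])))
        if (any(nAllele > 2))
            msg <- c(msg, sprintf("%d SNP(s) have more than 2 non-N alleles",
                                  sum(nAllele > 2)))
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        byChr <- split(GenomicRanges::start(rr),
                       as.character(GenomicRanges::seqnames(rr)))
        mono <- vapply(byChr, function(p) all(diff(p) > 0), logical(1))
        if (!all(mono))
            msg <- c(msg,
                "positions must be strictly increasing within chromosome")
    }
    if (is.null(rownames(object)) && nrow(object) > 0)
        msg <- c(msg, "SNPs must be named (rsID)")
    if (length(msg)) msg else TRUE
}
setValidity("StrainPanel", .validStrainPanel)

#' Per-animal phenotype table
#'
#' Long-form records of animal-level trait measurements for an inbred strain
#' survey, together with a trait dictionary (units and transform hints) and a
#' log of applied exclusions.  Records carry an \code{excluded} flag with a
#' \code{reason} (for example \code{"tail_climb"} in the tail suspension
#' test); \code{\link{applyExclusions}} removes flagged records and fills the
#' exclusion log.
#'
#' @slot records data.frame with columns \code{strain}, \code{animal_id},
#'   \code{trait}, \code{value}, \code{excluded} (logical), \code{reason}.
#' @slot traits data.frame with columns \code{name}, \code{units},
#'   \code{transform}.
#' @slot exclusionLog data.frame of per-strain, per-trait exclusion counts.
#' @seealso \code{\link{PhenoTable}}, \code{\link{readPhenotypes}}
#' @exportClass PhenoTable
setClass("PhenoTable",
    representation(records = "data.frame", traits = "data.frame",
                   exclusionLog = "data.frame"))

.validPhenoTable <- function(object) {
    msg <- character(0)
    rec <- object@records
    need <- c("strain", "animal_id", "trait", "value", "excluded", "reason")
    if (!all(need %in% names(rec)))
        return(sprintf("records must have columns %s",
                       paste(need, collapse = ", ")))
    key <- paste(rec$strain, rec$animal_id, rec$trait)
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate (strain, animal_id, trait) record")
    tr <- object@traits
    if (!all(c("name", "units") %in% names(tr)))
        msg <- c(msg, "traits must have columns name, units")
    else {
        pct <- tr$name[tr$units %in% c("percent", "%")]
        v <- rec$value[rec$trait %in% pct]
        v <- v[!is.na(v)]
        if (length(v) && (any(v < 0) || any(v > 100)))
            msg <- c(msg, "percent-unit trait values must lie in [0, 100]")
        if (any(!rec$trait %in% tr$name))
            msg <- c(msg, "every trait in records must be declared in traits")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PhenoTable", .validPhenoTable)

#' Genome-scan parameters
#'
#' Tuning knobs for the sliding-window haplotype scan.  Defaults mirror the
#' standard testing conditions of in-silico haplotype association mapping on
#' classical inbred panels: 3-SNP windows, a window enters the ANOVA only if
#' it has at least 2 haplotype groups with at least 5 member strains each,
#' relatedness weighting with similarity exponent 3, base-10 log transform of
#' the phenotype, and a reporting floor of \eqn{-\log_{10}p = 2.5}.
#'
#' @slot windowSize integer, SNPs per window.
#' @slot minHaplotypes integer, minimum qualifying haplotype groups.
#' @slot minMembers integer, minimum strains per qualifying group.
#' @slot weightScheme \code{"estimate3"} (similarity-power weights) or
#'   \code{"uniform"}.
#' @slot weightExponent integer exponent of the similarity-power scheme.
#' @slot logTransform \code{"log10"}, \code{"natural"} or \code{"none"}.
#' @slot reportThreshold numeric, \eqn{-\log_{10}p} floor for verbose output.
#' @slot logPCap numeric, score assigned when the within-group sum of
#'   squares is numerically zero.
#' @seealso \code{\link{ScanParams}}, \code{\link{genomeScan}}
#' @exportClass ScanParams
setClass("ScanParams",
    representation(windowSize = "integer", minHaplotypes = "integer",
                   minMembers = "integer", weightScheme = "character",
                   weightExponent = "integer", logTransform = "character",
                   reportThreshold = "numeric", logPCap = "numeric"),
    prototype(windowSize = 3L, minHaplotypes = 2L, minMembers = 5L,
              weightScheme = "estimate3", weightExponent = 3L,
              logTransform = "log10", reportThreshold = 2.5, logPCap = 50))

.validScanParams <- function(object) {
    msg <- character(0)
    if (object@windowSize < 1L) msg <- c(msg, "windowSize must be >= 1")
    if (object@minHaplotypes < 2L) msg <- c(msg, "minHaplotypes must be >= 2")
    if (object@minMembers < 1L) msg <- c(msg, "minMembers must be >= 1")
    if (!object@weightScheme %in% c("uniform", "estimate3"))
        msg <- c(msg, sprintf("unknown weight scheme '%s'",
                              object@weightScheme))
    if (!object@logTransform %in% c("log10", "natural", "none"))
        msg <- c(msg, sprintf("unknown log transform '%s'",
                              object@logTransform))
    if (object@logPCap <= 0) msg <- c(msg, "logPCap must be positive")
    if (length(msg)) msg else TRUE
}
setValidity("ScanParams", .validScanParams)

#' Parameters of the permutation gFWER calibration
#'
#' @slot B integer, number of phenotype permutations.
#' @slot k integer, order-statistic index: the calibration records the k-th
#'   largest scan score per permutation, controlling the probability of k or
#'   more false positives (the generalized family-wise error rate).
#' @slot alphaLevels numeric vector of target error rates.
#' @slot seed integer random seed for the permutation stream.
#' @seealso \code{\link{GfwerParams}}, \code{\link{calibrateGfwer}}
#' @exportClass GfwerParams
setClass("GfwerParams",
    representation(B = "integer", k = "integer", alphaLevels = "numeric",
                   seed = "integer"),
    prototype(B = 1000L, k = 10L, alphaLevels = c(0.05, 0.1), seed = 1L))

.validGfwerParams <- function(object) {
    msg <- character(0)
    if (object@B < 1L) msg <- c(msg, "B must be >= 1")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (any(object@alphaLevels <= 0) || any(object@alphaLevels >= 1))
        msg <- c(msg, "alpha levels must lie in (0, 1)")
    if (length(msg)) msg else TRUE
}
setValidity("GfwerParams", .validGfwerParams)

#' Permutation null distribution of the k-th largest scan score
#'
#' Result of \code{\link{calibrateGfwer}}: the k-th largest \eqn{-\log_{10}p}
#' of each permuted genome scan, and the raw-score thresholds that hold the
#' generalized family-wise error rate at each requested alpha.
#'
#' @slot nullKthScores numeric vector of length \code{B}.
#' @slot params the \linkS4class{GfwerParams} used.
#' @slot thresholds named numeric vector, one raw \eqn{-\log_{10}p} threshold
#'   per alpha level.
#' @slot shortScans integer, permutations in which fewer than k windows were
#'   scored (their statistic is the smallest scored score).
#' @seealso \code{\link{adjustedP}}, \code{\link{mergeLoci}}
#' @exportClass GfwerCalibration
setClass("GfwerCalibration",
    representation(nullKthScores = "numeric", params = "GfwerParams",
                   thresholds = "numeric", shortScans = "integer"),
    prototype(shortScans = 0L))

.validGfwerCalibration <- function(object) {
    msg <- character(0)
    if (length(object@nullKthScores) != object@params@B)
        msg <- c(msg, "nullKthScores must have length B")
    a <- object@params@alphaLevels
    th <- object@thresholds[as.character(a)]
    if (length(th) > 1 && !anyNA(th) &&
        !all(diff(th[order(a)]) <= 1e-12))
        msg <- c(msg, "thresholds must be non-increasing in alpha")
    if (length(msg)) msg else TRUE
}
setValidity("GfwerCalibration", .validGfwerCalibration)

#' Synthetic strain-panel simulation settings
#'
#' Configuration for the generator that emulates the statistical structure a
#' haplotype scan on classical inbred strains assumes: chromosomes tiled into
#' ancestral haplotype blocks, clusters of closely related strains (clades)
#' that reuse their founder's block assignments, SNP spacing around a target
#' density, optionally one or more planted QTL windows whose carrier/
#' non-carrier bipartition shifts strain means, and animal-level noise scaled
#' to a target broad-sense heritability.
#'
#' @slot nStrains,nClades,nChromosomes,snpsPerChromosome integer counts.
#' @slot cladeSizes integer vector summing to \code{nStrains}.
#' @slot meanSnpSpacing mean inter-SNP distance in bp.
#' @slot blockLengthMean mean ancestral-block length in bp (geometric).
#' @slot nAncestralHaplotypes integer, distinct ancestral haplotypes per
#'   block.
#' @slot cladeShareProb probability a clade member reuses its founder's
#'   block assignment rather than drawing independently.
#' @slot qtlSpecs list of planted QTLs, each a list with elements
#'   \code{chromosome}, \code{windowIndex}, \code{carrierStrains},
#'   \code{effectSize}.
#' @slot targetH2 target broad-sense heritability in [0, 1].
#' @slot strainSD standard deviation of the strain-level random genetic
#'   effect (phenotype units).
#' @slot nAnimalsPerStrain integer range \code{c(min, max)}.
#' @slot tailclimbProb per-strain tail-climb exclusion probability (scalar
#'   recycled, or named per-strain vector).
#' @slot seed master RNG seed; per-stage streams are derived from it.
#' @seealso \code{\link{SimConfig}}, \code{\link{simulatePanel}}
#' @exportClass SimConfig
setClass("SimConfig",
    representation(nStrains = "integer", nClades = "integer",
                   cladeSizes = "integer", nChromosomes = "integer",
                   snpsPerChromosome = "integer", meanSnpSpacing = "numeric",
                   blockLengthMean = "numeric",
                   nAncestralHaplotypes = "integer",
                   cladeShareProb = "numeric", qtlSpecs = "list",
                   targetH2 = "numeric", strainSD = "numeric",
                   nAnimalsPerStrain = "integer", tailclimbProb = "numeric",
                   seed = "integer"))

.validSimConfig <- function(object) {
    msg <- character(0)
    cnt <- c(nStrains = object@nStrains, nClades = object@nClades,
             nChromosomes = object@nChromosomes,
             snpsPerChromosome = object@snpsPerChromosome,
             nAncestralHaplotypes = object@nAncestralHaplotypes)
    if (any(cnt < 1L))
        msg <- c(msg, sprintf("counts must be >= 1 (%s)",
            paste(names(cnt)[cnt < 1L], collapse = ", ")))
    if (sum(object@cladeSizes) != object@nStrains)
        msg <- c(msg, "clade sizes must sum to nStrains")
    if (length(object@cladeSizes) != object@nClades)
        msg <- c(msg, "cladeSizes must have length nClades")
    if (object@meanSnpSpacing <= 0)
        msg <- c(msg, "meanSnpSpacing must be positive")
    if (object@targetH2 < 0 || object@targetH2 > 1)
        msg <- c(msg, "targetH2 must lie in [0, 1]")
    if (length(object@nAnimalsPerStrain) != 2L ||
        any(object@nAnimalsPerStrain < 1L) ||
        diff(object@nAnimalsPerStrain) < 0L)
        msg <- c(msg, "nAnimalsPerStrain must be an increasing range of counts")
    if (any(object@tailclimbProb < 0) || any(object@tailclimbProb >= 1))
        msg <- c(msg, "tailclimbProb must lie in [0, 1)")
    if (object@cladeShareProb < 0 || object@cladeShareProb > 1)
        msg <- c(msg, "cladeShareProb must lie in [0, 1]")
    for (q in object@qtlSpecs) {
        if (!all(c("chromosome", "windowIndex", "carrierStrains",
                   "effectSize") %in% names(q))) {
            msg <- c(msg, "each QTL spec needs chromosome, windowIndex, carrierStrains, effectSize")
            next
        }
        nc <- length(q$carrierStrains)
        if (nc < 1L || nc >= object@nStrains)
            msg <- c(msg, "QTL carrier set must be a non-empty proper subset of strains")
        nw <- object@snpsPerChromosome - 3L + 1L
        if (q$windowIndex < 1L || q$windowIndex > nw)
            msg <- c(msg, "QTL windowIndex outside the chromosome's window range")
        if (q$chromosome < 1L || q$chromosome > object@nChromosomes)
            msg <- c(msg, "QTL chromosome out of range")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)

#' Ground truth of a simulated panel
#'
#' @slot plantedQtls list of planted QTL descriptions (carriers, window,
#'   effect size, and the window's genomic interval once placed).
#' @slot cladeAssignment named integer vector, strain to clade id.
#' @slot realizedH2 realized broad-sense heritability from the generating
#'   variance components (NA until phenotypes are simulated).
#' @slot strainGeneticValues named numeric vector of strain genetic values.
#' @seealso \code{\link{simulatePanel}}, \code{\link{simulatePhenotypes}}
#' @exportClass TruthRecord
setClass("TruthRecord",
    representation(plantedQtls = "list", cladeAssignment = "integer",
                   realizedH2 = "numeric", strainGeneticValues = "numeric"),
    prototype(realizedH2 = NA_real_))

.validTruthRecord <- function(object) {
    msg <- character(0)
    if (!is.na(object@realizedH2) &&
        (object@realizedH2 < 0 || object@realizedH2 > 1))
        msg <- c(msg, "realizedH2 must lie in [0, 1]")
    if (length(object@cladeAssignment) &&
        is.null(names(object@cladeAssignment)))
        msg <- c(msg, "cladeAssignment must be named by strain")
    if (length(msg)) msg else TRUE
}
setValidity("TruthRecord", .validTruthRecord)
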