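#' Scan parameter constructor
#'
#' @param windowSize SNPs per sliding window (default 3).
#' @param minHaplotypes minimum number of haplotype groups that must reach
#'   \code{minMembers} strains for a window to be scored (default 2).
#' @param minMembers minimum strains per qualifying haplotype group
#'   (default 5).
#' @param weightScheme \code{"estimate3"} (default) or \code{"uniform"}.
#' @param weightExponent integer exponent of the similarity-power weighting
#'   (default 3).
#' @param logTransform phenotype transform applied before scanning:
#'   \code{"log10"} (default), \code{"natural"} or \code{"none"}.
#' @param reportThreshold \eqn{-\log_{10}p} floor for verbose reporting
#'   (default 2.5); windows below it are summarized, not listed.
#' @param logPCap score assigned when the within-group sum of squares is
#'   numerically zero (default 50).
#' @return a \linkS4class{ScanParams}.
#' @export
ScanParams <- function(windowSize = 3L, minHaplotypes = 2L, minMembers = 5L,
                       weightScheme = "estimate3", weightExponent = 3L,
                       logTransform = "log10", reportThreshold = 2.5,
                       logPCap = 50) {
    new("ScanParams", windowSize = as.integer(windowSize),
        minHaplotypes = as.integer(minHaplotypes),
        minMembers = as.integer(minMembers),
        weightScheme = weightScheme,
        weightExponent = as.integer(weightExponent),
        logTransform = logTransform,
        reportThreshold = reportThreshold, logPCap = logPCap)
}

#' gFWER parameter constructor
#'
#' @param B number of permutations (default 1000).
#' @param k order-statistic index (default 10): control of the probability
#'   of k or more false-positive windows.
#' @param alphaLevels target error rates (default 0.05 and 0.1).
#' @param seed RNG seed for the permutation stream.
#' @return a \linkS4class{GfwerParams}.
#' @export
GfwerParams <- function(B = 1000L, k = 10L, alphaLevels = c(0.05, 0.1),
                        seed = 1L) {
    new("GfwerParams", B = as.integer(B), k = as.integer(k),
        alphaLevels = as.numeric(alphaLevels), seed = as.integer(seed))
}

setMethod("show", "ScanParams", function(object) {
    cat(sprintf(
        "ScanParams: window=%d SNPs, filter >=%d groups of >=%d strains,\n",
        object@windowSize, object@minHaplotypes, object@minMembers))
    cat(sprintf("  weights=%s (exponent %d), transform=%s, report floor=%.2f\n",
        object@weightScheme, object@weightExponent, object@logTransform,
        object@reportThreshold))
})

setMethod("show", "GfwerParams", function(object) {
    cat(sprintf("GfwerParams: B=%d permutations, k=%d, alpha=%s, seed=%d\n",
        object@B, object@k,
        paste(object@alphaLevels, collapse = "/"), object@seed))
})

#' Accessors for GfwerCalibration
#'
#' \code{nullScores} returns the permutation null distribution of the k-th
#' largest scan score; \code{gfwerThresholds} the raw \eqn{-\log_{10}p}
#' thresholds per alpha level.
#'
#' @param x a \linkS4class{GfwerCalibration}.
#' @return numeric vector.
#' @name GfwerCalibration-accessors
#' @aliases nullScores gfwerThresholds
NULL

#' @rdname GfwerCalibration-accessors
#' @export
setMethod("nullScores", "GfwerCalibration", function(x) x@nullKthScores)

#' @rdname GfwerCalibration-accessors
#' @export
setMethod("gfwerThresholds", "GfwerCalibration", function(x) x@thresholds)

setMethod("show", "GfwerCalibration", function(object) {
    cat(sprintf("GfwerCalibration: B=%d, k=%d\n",
        object@params@B, object@params@k))
    for (a in names(object@thresholds))
        cat(sprintf("  alpha=%s: raw -log10(p) >= %.3f\n", a,
                    object@thresholds[[a]]))
    if (object@shortScans > 0L)
        cat(sprintf("  %d permutation(s) scored fewer than k windows\n",
                    object@shortScans))
})
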