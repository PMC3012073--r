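## Permutation calibration of the generalized family-wise error rate:
## null distribution of the k-th largest scan score, adjusted p values, and
## raw -log10(p) thresholds per target alpha.

#' Scan scores for many phenotype vectors at once
#'
#' Runs the haplotype window scan for each column of a phenotype matrix
#' against one fixed panel.  Haplotype groupings, the filter and the strain
#' weights do not depend on the phenotype, so they are computed once and
#' shared — this is the engine behind permutation calibration and
#' simulation studies.
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param valueMatrix numeric matrix, strains x replicates; row names must
#'   cover the panel's strains.  Values are on the raw scale; the transform
#'   in \code{params} is applied per column.
#' @param params a \linkS4class{ScanParams}.
#' @param weights optional precomputed \code{\link{strainWeights}} result.
#' @return numeric matrix of \eqn{-\log_{10}p} scores, windows x replicates
#'   (\code{NA} rows for filtered windows), ordered as
#'   \code{\link{hapWindows}}.
#' @export
scanScores <- function(panel, valueMatrix, params = ScanParams(),
                       weights = NULL) {
    strains <- strainNames(panel)
    if (is.null(rownames(valueMatrix)))
        stop("valueMatrix must have strain row names")
    if (!all(strains %in% rownames(valueMatrix)))
        stop("valueMatrix must cover every strain of the panel")
    Y <- valueMatrix[strains, , drop = FALSE]
    Y <- apply(Y, 2L, function(col)
        .transformValues(stats::setNames(col, strains),
                         params@logTransform))
    if (is.null(weights))
        weights <- strainWeights(panel, params@weightScheme,
                                 params@weightExponent)
    cache <- .scanCache(panel, params)
    .scanMany(cache, Y, weights$weights[strains], params@logPCap)$logP
}

## k-th largest of the scored (non-NA) values of one column; if fewer than
## k windows were scored, fall back to the smallest scored value.
.kthLargest <- function(x, k) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    s <- sort(x, decreasing = TRUE)
    if (length(s) >= k) s[k] else s[length(s)]
}

#' Permutation gFWER calibration
#'
#' For each of \code{B} permutations the strain phenotype values are
#' shuffled across strain labels (genotypes fixed), the full genome scan is
#' recomputed, and the k-th largest \eqn{-\log_{10}p} is recorded.  The raw
#' threshold for level \eqn{\alpha} is the
#' \eqn{\lceil(1-\alpha)B\rceil}-th order statistic of those B values:
#' calling a window significant at that threshold keeps the probability of
#' k or more false positives at or below \eqn{\alpha}.
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param strainValues named per-strain phenotype vector (raw scale).
#' @param scanParams a \linkS4class{ScanParams}.
#' @param gfwerParams a \linkS4class{GfwerParams} (permutation count B,
#'   order statistic k, alpha levels, seed).
#' @return a \linkS4class{GfwerCalibration}.
#' @export
calibrateGfwer <- function(panel, strainValues,
                           scanParams = ScanParams(),
                           gfwerParams = GfwerParams()) {
    strains <- strainNames(panel)
    if (!all(strains %in% names(strainValues)))
        stop("missing phenotype value for strain(s): ",
             paste(setdiff(strains, names(strainValues)), collapse = ", "))
    v <- strainValues[strains]
    B <- gfwerParams@B
    restore <- .localSeed(gfwerParams@seed)
    on.exit(restore())
    Y <- vapply(seq_len(B), function(b) sample(v), numeric(length(v)))
    rownames(Y) <- strains
    lp <- scanScores(panel, Y, scanParams)
    nScored <- sum(!is.na(lp[, 1]))
    if (nScored == 0L)
        stop("zero scored windows; calibration impossible")
    kth <- apply(lp, 2L, .kthLargest, k = gfwerParams@k)
    short <- if (nScored < gfwerParams@k) B else 0L
    s <- sort(kth)
    th <- vapply(gfwerParams@alphaLevels, function(a)
        s[ceiling((1 - a) * B)], numeric(1))
    names(th) <- as.character(gfwerParams@alphaLevels)
    new("GfwerCalibration", nullKthScores = unname(kth),
        params = gfwerParams, thresholds = th, shortScans = as.integer(short))
}

#' gFWER-adjusted p value of a scan score
#'
#' Finite-permutation estimator with the add-one convention:
#' \eqn{(1 + \#\{b: \mathrm{null}_b \ge s\}) / (B + 1)}.  Monotone
#' non-increasing in the score and bounded in \eqn{[1/(B+1), 1]}.
#'
#' @param calibration a \linkS4class{GfwerCalibration}.
#' @param score raw \eqn{-\log_{10}p} value(s).
#' @return adjusted p value(s) in (0, 1].
#' @examples
#' cal <- new("GfwerCalibration", nullKthScores = c(3, 5, 2, 4),
#'            params = GfwerParams(B = 4, alphaLevels = 0.05),
#'            thresholds = c("0.05" = 5))
#' adjustedP(cal, 4)  # (1 + 2) / 5 = 0.6
#' @export
adjustedP <- function(calibration, score) {
    B <- calibration@params@B
    vapply(score, function(s)
        (1 + sum(calibration@nullKthScores >= s)) / (B + 1), numeric(1))
}

#' Empirical gFWER of a threshold over null scan replicates
#'
#' Validation harness for the calibration: given scores from independent
#' null genome scans, returns the fraction of replicates in which at least
#' \code{k} windows reach the threshold (ties count as exceedances).
#'
#' @param nullScanScores matrix of \eqn{-\log_{10}p} scores, windows x
#'   replicates (as from \code{\link{scanScores}}), or a list of per-scan
#'   score vectors.
#' @param threshold raw \eqn{-\log_{10}p} threshold.
#' @param k order statistic index.
#' @return fraction in [0, 1].
#' @export
gfwerErrorRate <- function(nullScanScores, threshold, k) {
    if (is.matrix(nullScanScores))
        nullScanScores <- lapply(seq_len(ncol(nullScanScores)),
                                 function(j) nullScanScores[, j])
    exceed <- vapply(nullScanScores, function(x)
        sum(!is.na(x) & x >= threshold) >= k, logical(1))
    mean(exceed)
}
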