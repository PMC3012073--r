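## Haplotype association mapping core: sliding SNP windows, exact-string
## haplotype grouping, group-size filtering, relatedness-weighted one-way
## ANOVA on strain means, -log10(p) scoring, locus merging and strain
## distribution pattern (SDP) matching.

## Window bookkeeping: one window per run of windowSize consecutive SNPs
## within a chromosome (step 1 SNP), never spanning chromosome boundaries.
.windowIndex <- function(panel, windowSize) {
    rr <- snpRanges(panel)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    rl <- rle(chrom)
    firstRow <- cumsum(c(1L, rl$lengths[-length(rl$lengths)]))
    out <- list()
    for (i in seq_along(rl$values)) {
        m <- rl$lengths[i]
        if (m < windowSize) next
        f <- firstRow[i] + 0:(m - windowSize)
        out[[length(out) + 1L]] <- data.frame(
            chrom = rl$values[i], first = f,
            windowIndex = seq_along(f))
    }
    if (!length(out))
        return(data.frame(chrom = character(0), first = integer(0),
                          windowIndex = integer(0)))
    do.call(rbind, out)
}

#' Sliding SNP windows of a panel
#'
#' Enumerates every run of \code{windowSize} consecutive SNPs within each
#' chromosome (step one SNP).  Chromosomes with fewer SNPs than the window
#' contribute no windows and are reported via a message.
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param params a \linkS4class{ScanParams} (only \code{windowSize} is used).
#' @return a \code{GRanges}, one range per window spanning the first to last
#'   SNP position, with metadata columns \code{first_snp} (global SNP row of
#'   the window start), \code{window_index} (per chromosome) and
#'   \code{snps} (comma-joined rsIDs).
#' @export
hapWindows <- function(panel, params = ScanParams()) {
    W <- params@windowSize
    rr <- snpRanges(panel)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    short <- setdiff(unique(chrom),
                     unique(.windowIndex(panel, W)$chrom))
    if (length(short))
        message(sprintf("chromosome(s) with fewer than %d SNPs, no windows: %s",
                        W, paste(short, collapse = ", ")))
    wi <- .windowIndex(panel, W)
    if (!nrow(wi))
        return(GenomicRanges::GRanges())
    pos <- GenomicRanges::start(rr)
    ids <- names(rr)
    snps <- do.call(paste, c(lapply(0:(W - 1L), function(j)
        ids[wi$first + j]), sep = ","))
    gr <- GenomicRanges::GRanges(wi$chrom,
        IRanges::IRanges(pos[wi$first], pos[wi$first + W - 1L]))
    S4Vectors::mcols(gr)$first_snp <- wi$first
    S4Vectors::mcols(gr)$window_index <- wi$windowIndex
    S4Vectors::mcols(gr)$snps <- snps
    gr
}

#' Haplotype grouping within one window
#'
#' Strains are grouped by exact identity of their allele string across the
#' window's SNPs.  Strains with any missing call (\code{N}) in the window
#' are excluded from grouping and listed separately.
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param firstSnp global row index (or rsID) of the window's first SNP.
#' @param windowSize SNPs per window (default 3).
#' @return list with \code{window} (chromosome, start/end bp, rsIDs),
#'   \code{groups} (named list: haplotype string to strain ids) and
#'   \code{excluded} (strains with a missing call).
#' @export
inferWindowHaplotypes <- function(panel, firstSnp, windowSize = 3L) {
    calls <- alleleCalls(panel)
    if (is.character(firstSnp))
        firstSnp <- match(firstSnp, rownames(calls))
    rows <- firstSnp:(firstSnp + windowSize - 1L)
    if (firstSnp < 1L || max(rows) > nrow(calls))
        stop("window outside the panel")
    rr <- snpRanges(panel)
    chrom <- as.character(GenomicRanges::seqnames(rr))[rows]
    if (length(unique(chrom)) != 1L)
        stop("window spans a chromosome boundary")
    sub <- calls[rows, , drop = FALSE]
    str <- sub[1L, ]
    for (j in seq_len(windowSize - 1L)) str <- paste0(str, sub[j + 1L, ])
    miss <- colSums(sub == "N") > 0
    groups <- split(colnames(calls)[!miss], str[!miss])
    list(window = list(chrom = chrom[1L],
                       start = GenomicRanges::start(rr)[rows[1L]],
                       end = GenomicRanges::start(rr)[rows[windowSize]],
                       snps = rownames(calls)[rows]),
         groups = groups,
         excluded = colnames(calls)[miss])
}

#' Window filter: enough haplotypes with enough members
#'
#' A window is scored only if at least \code{minHaplotypes} of its haplotype
#' groups have at least \code{minMembers} strains.  Groups below the member
#' floor are set aside for that window (their strains do not enter the
#' ANOVA); they are not pooled.
#'
#' @param assignment result of \code{\link{inferWindowHaplotypes}}.
#' @param params a \linkS4class{ScanParams}.
#' @return logical flag.
#' @export
passesFilter <- function(assignment, params = ScanParams()) {
    sizes <- lengths(assignment$groups)
    sum(sizes >= params@minMembers) >= params@minHaplotypes
}

#' Relatedness-based strain weights
#'
#' Down-weights clusters of near-identical strains so that associations
#' driven by a block of close relatives do not dominate the scan.  The
#' genome-wide similarity between two strains is the fraction of SNPs (both
#' calls non-missing) at which their alleles agree.  Under the default
#' \code{"estimate3"} scheme the weight of strain \eqn{s} is
#' \eqn{w_s = 1 / \sum_t \mathrm{sim}(s,t)^e} (the sum includes \eqn{t=s}),
#' with integer exponent \eqn{e} (default 3, which sharpens the
#' down-weighting of near-duplicates), normalized to mean 1.
#' \code{"uniform"} gives every strain weight 1, reducing the scan to an
#' unweighted ANOVA.
#'
#' @param panel a \linkS4class{StrainPanel} with at least 2 strains.
#' @param scheme \code{"estimate3"} or \code{"uniform"}.
#' @param exponent integer exponent of the similarity power (default 3).
#' @return list with \code{weights} (named, mean 1), \code{scheme} and
#'   \code{similarity} (strain-by-strain matrix).
#' @export
strainWeights <- function(panel, scheme = "estimate3", exponent = 3L) {
    S <- ncol(panel)
    if (S < 2L) stop("need at least 2 strains")
    calls <- alleleCalls(panel)
    nn <- calls != "N"
    storage.mode(nn) <- "double"
    both <- crossprod(nn)
    eq <- matrix(0, S, S)
    for (a in c("A", "C", "G", "T")) {
        ind <- (calls == a)
        storage.mode(ind) <- "double"
        eq <- eq + crossprod(ind)
    }
    sim <- ifelse(both > 0, eq / both, 0)
    dimnames(sim) <- list(colnames(calls), colnames(calls))
    w <- switch(scheme,
        uniform = rep(1, S),
        estimate3 = {
            raw <- 1 / rowSums(sim^exponent)
            raw / mean(raw)
        },
        stop(sprintf("unknown weight scheme '%s'", scheme)))
    list(weights = stats::setNames(w, colnames(calls)), scheme = scheme,
         similarity = sim)
}

## Weighted one-way ANOVA on strain means for one window and one (or many)
## phenotype columns.  Group means are weighted, sums of squares use the
## weights, but the degrees of freedom count strains:
## F = (SSB / (h - 1)) / (SSW / (n - h)).
.wAnovaMany <- function(y, grp, h, w, n) {
    ## y: n x B matrix of values for the window's qualifying strains
    wy <- y * w
    Wg <- as.vector(rowsum(w, grp))
    A <- rowsum(wy, grp)                       # h x B weighted group sums
    S1 <- colSums(wy)
    S2 <- colSums(wy * y)
    Wtot <- sum(w)
    ssTotTerm <- S1 * S1 / Wtot
    grpTerm <- colSums(A * A / Wg)
    SSB <- grpTerm - ssTotTerm
    SSW <- S2 - grpTerm
    list(SSB = pmax(SSB, 0), SSW = pmax(SSW, 0),
         dfB = h - 1L, dfW = n - h)
}

.scoreMany <- function(an, logPCap) {
    SST <- an$SSB + an$SSW
    eps <- .Machine$double.eps^0.75
    degenerate <- an$SSW <= eps * pmax(SST, .Machine$double.xmin)
    FF <- (an$SSB / an$dfB) / (an$SSW / an$dfW)
    logP <- -stats::pf(FF, an$dfB, an$dfW, lower.tail = FALSE,
                       log.p = TRUE) / log(10)
    ## SSW ~ 0: perfect within-group fit
    if (any(degenerate)) {
        flat <- degenerate & an$SSB <= eps * pmax(SST, .Machine$double.xmin)
        FF[degenerate] <- Inf
        logP[degenerate] <- logPCap
        FF[flat] <- 0
        logP[flat] <- 0
    }
    logP <- pmin(logP, logPCap)
    list(F = FF, logP = logP, capped = degenerate & logP >= logPCap)
}

#' Weighted one-way ANOVA for one window
#'
#' Computes the relatedness-weighted F statistic for a haplotype grouping:
#' weighted group means and sums of squares, with degrees of freedom
#' counting strains (\eqn{h - 1} between, \eqn{n_{used} - h} within).
#' \eqn{p} comes from the F distribution and the score is
#' \eqn{-\log_{10} p}.  Doubling all weights leaves F unchanged.
#'
#' @param assignment result of \code{\link{inferWindowHaplotypes}}; only
#'   groups with at least \code{params@minMembers} strains enter.
#' @param strainValues named vector of (already transformed) strain
#'   phenotype values.
#' @param weights named strain weights (default all 1).
#' @param params a \linkS4class{ScanParams}.
#' @return list with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}, \code{logP}, \code{capped}, \code{n_used},
#'   \code{haplotype_sizes}.
#' @export
weightedAnova <- function(assignment, strainValues, weights = NULL,
                          params = ScanParams()) {
    sizes <- lengths(assignment$groups)
    qual <- assignment$groups[sizes >= params@minMembers]
    h <- length(qual)
    if (h < 2L) stop("fewer than 2 qualifying haplotype groups")
    strains <- unlist(qual, use.names = FALSE)
    n <- length(strains)
    if (n - h < 1L) stop("window unscored: no within-group degrees of freedom")
    if (is.null(weights)) weights <- stats::setNames(rep(1, n), strains)
    if (anyNA(strainValues[strains]) || anyNA(weights[strains]))
        stop("every qualifying strain needs a value and a weight")
    grp <- rep(seq_len(h), lengths(qual))
    y <- matrix(strainValues[strains], ncol = 1)
    an <- .wAnovaMany(y, grp, h, weights[strains], n)
    sc <- .scoreMany(an, params@logPCap)
    p <- if (is.finite(sc$F[1])) {
        stats::pf(sc$F[1], an$dfB, an$dfW, lower.tail = FALSE)
    } else 10^(-sc$logP[1])
    list(F = sc$F[1], df_between = an$dfB, df_within = an$dfW, p = p,
         logP = sc$logP[1], capped = sc$capped[1], n_used = n,
         haplotype_sizes = unname(sizes))
}

## Precompute, per window, the phenotype-independent pieces of the scan:
## haplotype group codes of the qualifying strains, group sizes, filter
## flag.  Shared by the observed scan and every permutation.
.scanCache <- function(panel, params) {
    W <- params@windowSize
    calls <- alleleCalls(panel)
    wi <- .windowIndex(panel, W)
    rr <- snpRanges(panel)
    pos <- GenomicRanges::start(rr)
    S <- ncol(calls)
    nW <- nrow(wi)
    win <- vector("list", nW)
    if (!nW)
        return(list(windows = wi, perWindow = win, pos = pos,
                    snpIds = rownames(calls), strains = colnames(calls),
                    W = W))
    ## integer-code the allele strings: base-5 digits over the window's
    ## SNPs (exact in doubles for any realistic window size)
    code <- matrix(match(calls, VALID_ALLELES), nrow(calls), S)
    isN <- code == 5L
    H <- matrix(0, nW, S)
    missM <- matrix(FALSE, nW, S)
    for (j in 0:(W - 1L)) {
        H <- H * 5 + code[wi$first + j, , drop = FALSE]
        missM <- missM | isN[wi$first + j, , drop = FALSE]
    }
    for (k in seq_len(nW)) {
        str <- H[k, ]
        miss <- missM[k, ]
        ok <- which(!miss)
        g0 <- match(str[ok], unique(str[ok]))
        sizes <- tabulate(g0)
        qual <- which(sizes >= params@minMembers)
        passed <- length(qual) >= params@minHaplotypes
        if (passed) {
            keep <- g0 %in% qual
            idx <- ok[keep]
            grp <- match(g0[keep], qual)
            win[[k]] <- list(idx = idx, grp = grp, h = length(qual),
                             n = length(idx), sizes = sizes,
                             passed = TRUE, nExcluded = sum(miss))
        } else {
            win[[k]] <- list(sizes = sizes, passed = FALSE,
                             nExcluded = sum(miss))
        }
    }
    ## flattened view of all scored windows for the vectorized
    ## one-phenotype path
    scored <- vapply(win, function(x) x$passed &&
        (x$n - x$h) >= 1L, logical(1))
    sw <- win[scored]
    flat <- NULL
    if (length(sw)) {
        hs <- vapply(sw, `[[`, integer(1), "h")
        ns <- vapply(sw, `[[`, integer(1), "n")
        flat <- list(
            idx = unlist(lapply(sw, `[[`, "idx"), use.names = FALSE),
            grpKey = unlist(lapply(seq_along(sw), function(i)
                sw[[i]]$grp + c(0L, cumsum(hs))[i]), use.names = FALSE),
            winOf = rep(seq_along(sw), ns),
            groupWin = rep(seq_along(sw), hs),
            h = hs, n = ns, which = which(scored))
    }
    list(windows = wi, perWindow = win, pos = pos, flat = flat,
         snpIds = rownames(calls), strains = colnames(calls), W = W)
}

## Vectorized scan of a single phenotype vector: every scored window's
## weighted sums of squares in a handful of rowsum() calls.
.scanOne <- function(cache, y, weights, logPCap) {
    nW <- length(cache$perWindow)
    FF <- rep(NA_real_, nW)
    LP <- rep(NA_real_, nW)
    fl <- cache$flat
    if (is.null(fl)) return(list(F = FF, logP = LP))
    wv <- weights[fl$idx]
    yv <- y[fl$idx]
    wy <- wv * yv
    Wg <- as.vector(rowsum(wv, fl$grpKey))
    A <- as.vector(rowsum(wy, fl$grpKey))
    grpTerm <- as.vector(rowsum(A * A / Wg, fl$groupWin))
    S1 <- as.vector(rowsum(wy, fl$winOf))
    S2 <- as.vector(rowsum(wy * yv, fl$winOf))
    Wtot <- as.vector(rowsum(wv, fl$winOf))
    an <- list(SSB = pmax(grpTerm - S1 * S1 / Wtot, 0),
               SSW = pmax(S2 - grpTerm, 0),
               dfB = fl$h - 1L, dfW = fl$n - fl$h)
    sc <- .scoreMany(an, logPCap)
    FF[fl$which] <- sc$F
    LP[fl$which] <- sc$logP
    list(F = FF, logP = LP)
}

## Score every passed window for each column of Y (strains x B, aligned to
## cache$strains).  Returns logP and F matrices (nWindows x B; NA where the
## window did not pass the filter).
.scanMany <- function(cache, Y, weights, logPCap) {
    nW <- length(cache$perWindow)
    B <- ncol(Y)
    FF <- matrix(NA_real_, nW, B)
    LP <- matrix(NA_real_, nW, B)
    for (k in seq_len(nW)) {
        cw <- cache$perWindow[[k]]
        if (!cw$passed) next
        if (cw$n - cw$h < 1L) next
        an <- .wAnovaMany(Y[cw$idx, , drop = FALSE], cw$grp, cw$h,
                          weights[cw$idx], cw$n)
        sc <- .scoreMany(an, logPCap)
        FF[k, ] <- sc$F
        LP[k, ] <- sc$logP
    }
    list(F = FF, logP = LP)
}

.transformValues <- function(values, how) {
    if (how == "none") return(values)
    if (any(values <= 0)) {
        bad <- names(values)[values <= 0]
        stop(sprintf(
            "log transform requires positive phenotypes; offending strain(s): %s",
            paste(bad, collapse = ", ")))
    }
    switch(how, log10 = log10(values), natural = log(values))
}

#' Genome scan: haplotype window ANOVA over a whole panel
#'
#' Runs the sliding-window haplotype association scan: per window, strains
#' are grouped by exact allele-string identity, small groups are set aside,
#' windows with at least \code{minHaplotypes} groups of at least
#' \code{minMembers} strains are scored by a relatedness-weighted one-way
#' ANOVA of the (log-transformed) strain phenotype means, and the score is
#' \eqn{-\log_{10} p} from the F distribution.
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param strainValues named numeric vector of per-strain phenotype values
#'   (raw scale; the transform in \code{params} is applied here).  Must
#'   cover every strain of the panel.
#' @param params a \linkS4class{ScanParams}.
#' @param weights optional precomputed \code{\link{strainWeights}} result;
#'   computed from \code{params@weightScheme} when \code{NULL}.
#' @return a \code{GRanges}, one range per window (ordered by chromosome
#'   and start), with metadata columns \code{first_snp},
#'   \code{window_index}, \code{snps}, \code{haplotype_sizes},
#'   \code{n_groups}, \code{F}, \code{df_between}, \code{df_within},
#'   \code{logP}, \code{passed_filter}, \code{capped}.  Windows that fail
#'   the filter carry \code{NA} scores.
#' @export
genomeScan <- function(panel, strainValues, params = ScanParams(),
                       weights = NULL) {
    strains <- strainNames(panel)
    if (is.null(names(strainValues)))
        stop("strainValues must be named by strain")
    if (!all(strains %in% names(strainValues)))
        stop("missing phenotype value for strain(s): ",
             paste(setdiff(strains, names(strainValues)), collapse = ", "))
    v <- .transformValues(strainValues[strains], params@logTransform)
    if (is.null(weights))
        weights <- strainWeights(panel, params@weightScheme,
                                 params@weightExponent)
    w <- weights$weights[strains]
    cache <- .scanCache(panel, params)
    gr <- hapWindows(panel, params)
    if (!length(gr)) return(gr)
    res <- .scanOne(cache, v, w, params@logPCap)
    res$F <- matrix(res$F, ncol = 1)
    res$logP <- matrix(res$logP, ncol = 1)
    pw <- cache$perWindow
    S4Vectors::mcols(gr)$haplotype_sizes <- vapply(pw, function(x)
        paste(sort(x$sizes, decreasing = TRUE), collapse = ","), character(1))
    S4Vectors::mcols(gr)$n_groups <- vapply(pw, function(x)
        if (x$passed) x$h else 0L, integer(1))
    S4Vectors::mcols(gr)$F <- res$F[, 1]
    S4Vectors::mcols(gr)$df_between <- vapply(pw, function(x)
        if (x$passed) x$h - 1L else NA_integer_, integer(1))
    S4Vectors::mcols(gr)$df_within <- vapply(pw, function(x)
        if (x$passed) x$n - x$h else NA_integer_, integer(1))
    S4Vectors::mcols(gr)$logP <- res$logP[, 1]
    S4Vectors::mcols(gr)$passed_filter <-
        vapply(pw, function(x) x$passed, logical(1)) &
        !is.na(res$logP[, 1])
    S4Vectors::mcols(gr)$capped <- !is.na(res$logP[, 1]) &
        res$logP[, 1] >= params@logPCap
    gr
}

#' Merge significant windows into loci
#'
#' Windows at or above the \eqn{-\log_{10}p} threshold are grouped per
#' chromosome; windows sharing at least one SNP (overlapping triples) merge
#' into one locus whose interval runs from the first to the last member SNP
#' position.  The locus carries its peak score and, when a calibration is
#' supplied, the gFWER-adjusted p value of the peak.
#'
#' @param scan result of \code{\link{genomeScan}}.
#' @param threshold raw \eqn{-\log_{10}p} floor for inclusion.
#' @param calibration optional \linkS4class{GfwerCalibration} used to attach
#'   adjusted p values.
#' @param params the \linkS4class{ScanParams} of the scan (window size).
#' @return a \code{GRanges} of loci with metadata columns \code{peak_logP},
#'   \code{peak_snps}, \code{n_windows}, and \code{adjusted_p} when a
#'   calibration is given.
#' @export
mergeLoci <- function(scan, threshold, calibration = NULL,
                      params = ScanParams()) {
    keep <- !is.na(scan$logP) & scan$passed_filter & scan$logP >= threshold
    hits <- scan[keep]
    if (!length(hits)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$peak_logP <- numeric(0)
        S4Vectors::mcols(gr)$peak_snps <- character(0)
        S4Vectors::mcols(gr)$n_windows <- integer(0)
        if (!is.null(calibration))
            S4Vectors::mcols(gr)$adjusted_p <- numeric(0)
        return(gr)
    }
    W <- params@windowSize
    chrV <- character(0); startV <- integer(0); endV <- integer(0)
    peakV <- numeric(0); snpV <- character(0); nV <- integer(0)
    for (chr in unique(as.character(GenomicRanges::seqnames(hits)))) {
        h <- hits[as.character(GenomicRanges::seqnames(hits)) == chr]
        ir <- IRanges::IRanges(h$first_snp, h$first_snp + W - 1L)
        merged <- IRanges::reduce(ir)
        ov <- IRanges::findOverlaps(ir, merged)
        for (m in seq_along(merged)) {
            members <- h[S4Vectors::subjectHits(ov) == m]
            peak <- which.max(members$logP)
            chrV <- c(chrV, chr)
            startV <- c(startV, min(GenomicRanges::start(members)))
            endV <- c(endV, max(GenomicRanges::end(members)))
            peakV <- c(peakV, members$logP[peak])
            snpV <- c(snpV, members$snps[peak])
            nV <- c(nV, length(members))
        }
    }
    res <- GenomicRanges::GRanges(chrV, IRanges::IRanges(startV, endV))
    S4Vectors::mcols(res)$peak_logP <- peakV
    S4Vectors::mcols(res)$peak_snps <- snpV
    S4Vectors::mcols(res)$n_windows <- nV
    if (!is.null(calibration))
        S4Vectors::mcols(res)$adjusted_p <- adjustedP(calibration, peakV)
    res[order(chrV, startV)]
}

#' SNPs matching a strain distribution pattern
#'
#' Finds SNPs whose biallelic split over the strains equals a given
#' carrier/non-carrier bipartition exactly (allele labels are ignored; a
#' missing call disqualifies the SNP; so does any strain on the wrong side).
#' Used to look for individual variants that segregate with the haplotype
#' pattern driving an association.
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param carriers character vector of strain ids forming one side of the
#'   bipartition; must be a non-empty proper subset of the panel's strains.
#' @param region optional \code{GRanges}; only SNPs overlapping it are
#'   considered.
#' @return character vector of matching rsIDs.
#' @export
sdpMatch <- function(panel, carriers, region = NULL) {
    strains <- strainNames(panel)
    unknown <- setdiff(carriers, strains)
    if (length(unknown))
        stop("unknown strain(s) in bipartition: ",
             paste(unknown, collapse = ", "))
    if (!length(carriers) || length(carriers) >= length(strains))
        stop("bipartition must be a non-empty proper subset of strains")
    calls <- alleleCalls(panel)
    if (!is.null(region)) {
        keep <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
            snpRanges(panel), region))
        calls <- calls[sort(unique(keep)), , drop = FALSE]
    }
    if (!nrow(calls)) return(character(0))
    cm <- strains %in% carriers
    noN <- rowSums(calls == "N") == 0
    cA <- calls[, cm, drop = FALSE]
    nC <- calls[, !cm, drop = FALSE]
    carrierSame <- rowSums(cA == cA[, 1L]) == ncol(cA)
    nonSame <- rowSums(nC == nC[, 1L]) == ncol(nC)
    differ <- cA[, 1L] != nC[, 1L]
    rownames(calls)[noN & carrierSame & nonSame & differ]
}
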