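## Strain-survey phenotype statistics: immobility scoring, exclusion
## handling, strain summaries, Pearson correlations and broad-sense
## heritability by one-way strain ANOVA.

#' Percent immobility from a tail-suspension activity series
#'
#' The tail suspension test records an immobility indicator in 200 ms bins
#' over a 7 minute session (2100 bins).  Animals are uniformly active during
#' the first minute, so the score is the percentage of time spent immobile
#' over the final 6 minutes only.
#'
#' @param bins ordered 0/1 immobility indicators (1 = immobile).
#' @param binDuration bin width in seconds (default 0.2).
#' @param testMinutes total session length in minutes (default 7).
#' @param settleMinutes initial minutes dropped from scoring (default 1).
#' @return percent immobility in [0, 100].
#' @examples
#' percentImmobility(rep(1, 2100))  # 100
#' @export
percentImmobility <- function(bins, binDuration = 0.2, testMinutes = 7,
                              settleMinutes = 1) {
    expected <- as.integer(round(testMinutes * 60 / binDuration))
    if (length(bins) != expected)
        stop(sprintf("activity series has %d bins; expected %d (%g min at %g s)",
                     length(bins), expected, testMinutes, binDuration))
    if (!all(bins %in% c(0, 1)))
        stop("immobility indicators must be 0 or 1")
    drop <- as.integer(round(settleMinutes * 60 / binDuration))
    scored <- bins[(drop + 1L):expected]
    100 * sum(scored) / length(scored)
}

#' Apply exclusion flags to a phenotype table
#'
#' Removes records whose \code{excluded} flag is set (for that record's trait
#' only) and logs the number removed per strain and trait.  A strain that
#' loses all its animals for a trait disappears from that trait's summaries;
#' a warning names it, and it remains visible in the exclusion log.
#'
#' @param table a \linkS4class{PhenoTable}.
#' @return a \linkS4class{PhenoTable} with flagged records removed and the
#'   exclusion log filled in.
#' @export
applyExclusions <- function(table) {
    stopifnot(is(table, "PhenoTable"))
    rec <- records(table)
    excl <- rec[rec$excluded, , drop = FALSE]
    keep <- rec[!rec$excluded, , drop = FALSE]
    log <- data.frame(strain = character(0), trait = character(0),
                      n_excluded = integer(0))
    if (nrow(excl)) {
        agg <- stats::aggregate(excluded ~ strain + trait, data = excl,
                                FUN = length)
        log <- data.frame(strain = agg$strain, trait = agg$trait,
                          n_excluded = as.integer(agg$excluded))
        ## strains wiped out for a trait
        for (i in seq_len(nrow(log))) {
            left <- sum(keep$strain == log$strain[i] &
                        keep$trait == log$trait[i])
            if (left == 0L)
                warning(sprintf(
                    "strain %s has no remaining animals for trait %s",
                    log$strain[i], log$trait[i]), call. = FALSE)
        }
    }
    out <- table
    out@records <- keep
    rownames(out@records) <- NULL
    out@exclusionLog <- log
    out
}

#' Per-strain summary statistics for one trait
#'
#' One row per retained strain with n, mean, sample standard deviation
#' (n - 1 denominator) and standard error of the mean.  Strains with a
#' single animal report \code{NA} for sd and sem.
#'
#' @param table a \linkS4class{PhenoTable} (exclusions already applied).
#' @param trait trait name.
#' @return data.frame with columns \code{strain}, \code{trait}, \code{n},
#'   \code{mean}, \code{sd}, \code{sem}.
#' @export
strainSummaries <- function(table, trait) {
    stopifnot(is(table, "PhenoTable"))
    rec <- records(table)
    rec <- rec[rec$trait == trait & !rec$excluded, , drop = FALSE]
    if (!nrow(rec))
        stop(sprintf("no records for trait '%s'", trait))
    sp <- split(rec$value, rec$strain)
    out <- data.frame(
        strain = names(sp),
        trait = trait,
        n = vapply(sp, length, integer(1)),
        mean = vapply(sp, mean, numeric(1)),
        sd = vapply(sp, function(v)
            if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1)))
    out$sem <- out$sd / sqrt(out$n)
    rownames(out) <- NULL
    out
}

#' Strain means for one trait
#'
#' Convenience accessor used by the genome scan: mean trait value per strain
#' after exclusions, as a named vector.
#'
#' @inheritParams strainSummaries
#' @return named numeric vector of strain means.
#' @export
strainMeans <- function(table, trait) {
    s <- strainSummaries(table, trait)
    stats::setNames(s$mean, s$strain)
}

#' Pearson correlation between two strain-mean vectors
#'
#' Product-moment correlation with a two-sided t test,
#' \eqn{t = r\sqrt{df}/\sqrt{1-r^2}} on \eqn{df = n - 2} degrees of freedom.
#' Inputs are paired by strain: both vectors must be named and cover the same
#' strains, or be plain equal-length vectors already aligned.
#'
#' @param x,y numeric vectors of strain means.
#' @return list with elements \code{r}, \code{n}, \code{t}, \code{df},
#'   \code{p}.
#' @examples
#' pearsonCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
#' @export
pearsonCorrelation <- function(x, y) {
    if (!is.null(names(x)) && !is.null(names(y))) {
        common <- intersect(names(x), names(y))
        if (length(common) < length(x) || length(common) < length(y))
            stop("x and y must cover the same strains (no missing pairs)")
        x <- x[common]; y <- y[common]
    }
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
    n <- length(x)
    if (n < 3L) stop("need at least 3 strain pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance in one input")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), n = n, t = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value)
}

## Core one-way ANOVA bookkeeping shared by the heritability estimator and
## the simulation recovery checks.  Adjusted variance explained:
## R2_adj = 1 - (SSE / (N - g)) / (SST / (N - 1)).
.anovaR2 <- function(values, groups) {
    groups <- as.factor(as.character(groups))
    if (nlevels(groups) < 2L) stop("need at least 2 strains")
    N <- length(values)
    g <- nlevels(groups)
    gm <- mean(values)
    sst <- sum((values - gm)^2)
    if (sst == 0) stop("total sum of squares is zero; R2 undefined")
    means <- tapply(values, groups, mean)
    sse <- sum((values - means[groups])^2)
    r2 <- 1 - sse / sst
    r2adj <- 1 - (sse / (N - g)) / (sst / (N - 1))
    list(R2 = r2, R2_adj = r2adj, N = N, g = g, SST = sst, SSE = sse)
}

#' Adjusted variance explained by strain
#'
#' One-way fixed-effect ANOVA of animal values on strain, returning the
#' adjusted percentage of variance explained
#' \eqn{R^2_{adj} = 1 - \frac{SSE/(N-g)}{SST/(N-1)}}, the broad-sense
#' heritability estimator for an inbred panel (all within-strain variance is
#' environmental because strain members are genetically identical).
#'
#' @param values animal-level trait values.
#' @param strains strain label per animal.
#' @return list with \code{R2}, \code{R2_adj}, \code{N} (animals),
#'   \code{g} (strains), \code{SST}, \code{SSE}.
#' @examples
#' adjustedVarianceExplained(c(1, 2, 3, 4, 5, 6),
#'                           rep(c("a", "b"), each = 3))$R2_adj  # 0.7143
#' @export
adjustedVarianceExplained <- function(values, strains) {
    stopifnot(length(values) == length(strains))
    .anovaR2(values, strains)
}

#' Broad-sense heritability by subsampled strain ANOVA
#'
#' Estimates heritability as the adjusted variance explained by strain in a
#' one-way ANOVA, computed on a balanced random subsample of
#' \code{perStrainN} animals per strain.  To guard against outliers the
#' estimate is made twice on disjoint animals: each strain's retained
#' animals are split at random into two pools and each replicate subsamples
#' from its own pool (strains with fewer than \code{2 * perStrainN} animals
#' contribute their whole pool).  Strains with fewer than \code{minPerStrain}
#' retained animals are dropped with a warning.
#'
#' @param table a \linkS4class{PhenoTable} (exclusions applied).
#' @param trait trait name.
#' @param perStrainN animals sampled per strain per replicate, in [8, 16]
#'   (default 14).
#' @param seed RNG seed for the subsampling.
#' @param minPerStrain inclusion floor on retained animals (default 8).
#' @return list with \code{trait}, \code{estimates} (the two replicate
#'   R2_adj values), \code{R2_adj} (their mean, the headline value),
#'   \code{N} (scores per replicate), \code{g} (strains used),
#'   \code{perStrainN}, \code{seed}, \code{droppedStrains}.
#' @export
heritabilityANOVA <- function(table, trait, perStrainN = 14L, seed = 1L,
                              minPerStrain = 8L) {
    stopifnot(is(table, "PhenoTable"))
    perStrainN <- as.integer(perStrainN)
    if (perStrainN < 8L || perStrainN > 16L)
        stop("perStrainN must lie in [8, 16]")
    rec <- records(table)
    rec <- rec[rec$trait == trait & !rec$excluded, , drop = FALSE]
    cnt <- table(rec$strain)
    dropped <- names(cnt)[cnt < minPerStrain]
    if (length(dropped))
        warning(sprintf(
            "dropping %d strain(s) with fewer than %d retained animals: %s",
            length(dropped), minPerStrain, paste(dropped, collapse = ", ")),
            call. = FALSE)
    keepStrains <- setdiff(names(cnt), dropped)
    if (length(keepStrains) < 2L)
        stop("need at least 2 strains with enough animals")
    rec <- rec[rec$strain %in% keepStrains, , drop = FALSE]

    withr_seed <- .localSeed(seed)
    on.exit(withr_seed())
    sp <- split(seq_len(nrow(rec)), rec$strain)
    pick <- list(integer(0), integer(0))
    for (idx in sp) {
        idx <- sample(idx)            # shuffle once, then split into pools
        half <- ceiling(length(idx) / 2)
        pools <- list(idx[seq_len(half)], idx[-seq_len(half)])
        for (r in 1:2) {
            p <- pools[[r]]
            take <- min(perStrainN, length(p))
            pick[[r]] <- c(pick[[r]], p[seq_len(take)])
        }
    }
    est <- vapply(pick, function(i)
        .anovaR2(rec$value[i], rec$strain[i])$R2_adj, numeric(1))
    list(trait = trait, estimates = est, R2_adj = mean(est),
         N = vapply(pick, length, integer(1)), g = length(keepStrains),
         perStrainN = perStrainN, seed = seed, droppedStrains = dropped)
}
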