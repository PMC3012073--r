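## Synthetic strain-panel generator.  Emulates the structure a haplotype
## scan on classical inbred panels assumes: chromosomes tiled into ancestral
## haplotype blocks, clades of closely related strains reusing a founder's
## block assignments, SNP spacing around a target density, optional planted
## QTL windows, and animal-level noise scaled to a target heritability.

#' Simulation configuration constructor
#'
#' Defaults mirror a desk-scale version of a classical inbred survey: 33
#' strains drawn from 5 ancestral lineages, SNPs spaced around 6 kb, blocks
#' of ancestral haplotype sharing, 8 to 49 animals per strain, and a target
#' broad-sense heritability of 0.64 (the level typical of tail-suspension
#' immobility).
#'
#' @param nStrains number of strains (default 33).
#' @param nClades number of clades of closely related strains (default 5).
#' @param cladeSizes integer vector summing to \code{nStrains}; default a
#'   near-equal split.
#' @param nChromosomes chromosomes (default 2).
#' @param snpsPerChromosome SNPs per chromosome (default 500).
#' @param meanSnpSpacing mean inter-SNP gap in bp (default 6000).
#' @param blockLengthMean mean ancestral block length in bp (default 60000;
#'   lengths are geometric, truncated at chromosome ends).
#' @param nAncestralHaplotypes distinct ancestral haplotypes per block
#'   (default 4).
#' @param cladeShareProb probability a clade member reuses its founder's
#'   block assignment (default 0.9).
#' @param qtlSpecs list of planted QTLs; each element a list with
#'   \code{chromosome}, \code{windowIndex}, \code{carrierStrains} (strain
#'   names or indices), \code{effectSize} (phenotype units added to carrier
#'   strain means).
#' @param targetH2 target broad-sense heritability in [0, 1] (default 0.64).
#' @param strainSD standard deviation of the strain-level random genetic
#'   effect in phenotype units (default 1).
#' @param nAnimalsPerStrain range \code{c(min, max)} of animals per strain
#'   (default \code{c(8, 49)}).
#' @param tailclimbProb per-strain tail-climb exclusion probability: scalar
#'   recycled over strains, or a named per-strain vector (default 0).
#' @param seed master RNG seed; genotype and phenotype stages draw from
#'   sub-streams derived deterministically from it.
#' @return a \linkS4class{SimConfig}.
#' @export
SimConfig <- function(nStrains = 33L, nClades = 5L, cladeSizes = NULL,
                      nChromosomes = 2L, snpsPerChromosome = 500L,
                      meanSnpSpacing = 6000, blockLengthMean = 60000,
                      nAncestralHaplotypes = 4L, cladeShareProb = 0.9,
                      qtlSpecs = list(), targetH2 = 0.64, strainSD = 1,
                      nAnimalsPerStrain = c(8L, 49L), tailclimbProb = 0,
                      seed = 1L) {
    nStrains <- as.integer(nStrains)
    nClades <- as.integer(nClades)
    if (is.null(cladeSizes)) {
        base <- nStrains %/% nClades
        cladeSizes <- rep(base, nClades)
        extra <- nStrains - sum(cladeSizes)
        if (extra > 0)
            cladeSizes[seq_len(extra)] <- cladeSizes[seq_len(extra)] + 1L
    }
    new("SimConfig", nStrains = nStrains, nClades = nClades,
        cladeSizes = as.integer(cladeSizes),
        nChromosomes = as.integer(nChromosomes),
        snpsPerChromosome = as.integer(snpsPerChromosome),
        meanSnpSpacing = meanSnpSpacing,
        blockLengthMean = blockLengthMean,
        nAncestralHaplotypes = as.integer(nAncestralHaplotypes),
        cladeShareProb = cladeShareProb, qtlSpecs = qtlSpecs,
        targetH2 = targetH2, strainSD = strainSD,
        nAnimalsPerStrain = as.integer(nAnimalsPerStrain),
        tailclimbProb = tailclimbProb, seed = as.integer(seed))
}

.strainIds <- function(n) sprintf("S%02d", seq_len(n))

.normalizeCarriers <- function(carriers, strains) {
    if (is.numeric(carriers)) carriers <- strains[carriers]
    unknown <- setdiff(carriers, strains)
    if (length(unknown))
        stop("unknown carrier strain(s): ", paste(unknown, collapse = ", "))
    unique(carriers)
}

#' Simulate a genotype panel with mosaic block structure
#'
#' Each chromosome is tiled into blocks with geometric lengths around
#' \code{blockLengthMean}.  Within a block every strain carries one of
#' \code{nAncestralHaplotypes} ancestral allele strings; members of a clade
#' reuse their clade founder's choice with probability
#' \code{cladeShareProb}, otherwise they draw independently, so clades show
#' excess genotype sharing.  A minor-allele floor of one strain is enforced
#' by redrawing the ancestral pattern of SNPs that come out monomorphic
#' (impossible, and therefore skipped, when only one ancestral haplotype is
#' configured).  Planted QTL windows are rewritten so that carriers share
#' one allele string and non-carriers carry the complementary string,
#' making the carrier bipartition exactly recoverable from the genotypes.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{panel} (a \linkS4class{StrainPanel})
#'   and \code{truth} (a \linkS4class{TruthRecord}).
#' @export
simulatePanel <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    S <- config@nStrains
    K <- config@nAncestralHaplotypes
    M <- config@snpsPerChromosome
    strains <- .strainIds(S)
    clade <- rep(seq_len(config@nClades), config@cladeSizes)
    names(clade) <- strains

    restore <- .localSeed(.stageSeed(config@seed, 1L))
    on.exit(restore())

    letters4 <- c("A", "C", "G", "T")
    callsAll <- list(); chromAll <- list(); posAll <- list(); idAll <- list()
    for (cc in seq_len(config@nChromosomes)) {
        gaps <- pmax(1, round(stats::rexp(M, 1 / config@meanSnpSpacing)))
        pos <- cumsum(gaps)
        ## two distinct allele letters per SNP
        a1 <- sample(letters4, M, replace = TRUE)
        shift <- sample(1:3, M, replace = TRUE)
        a2 <- letters4[(match(a1, letters4) + shift - 1L) %% 4L + 1L]
        ## block tiling (geometric lengths, truncated at the chromosome end)
        bnd <- integer(0); total <- 0
        while (total < pos[M]) {
            len <- stats::rgeom(1, 1 / config@blockLengthMean) + 1
            total <- total + len
            bnd <- c(bnd, total)
        }
        blockId <- findInterval(pos - 1, c(0, bnd))
        ## per-block ancestral patterns and strain assignments
        hap <- matrix(1L, S, M)                 # ancestral allele index (1/2)
        for (b in unique(blockId)) {
            idx <- which(blockId == b)
            n <- length(idx)
            P <- matrix(sample(1:2, K * n, replace = TRUE), K, n)
            if (K >= 2L) {
                monoCol <- function(M) apply(M, 2L, function(col)
                    all(col == col[1L]))
                mono <- which(monoCol(P))
                while (length(mono)) {
                    P[, mono] <- sample(1:2, K * length(mono), replace = TRUE)
                    mono <- mono[monoCol(P[, mono, drop = FALSE])]
                }
            }
            founders <- sample(seq_len(K), config@nClades, replace = TRUE)
            own <- sample(seq_len(K), S, replace = TRUE)
            useFounder <- stats::runif(S) < config@cladeShareProb
            assign <- ifelse(useFounder, founders[clade], own)
            hap[, idx] <- P[assign, , drop = FALSE]
        }
        calls <- matrix(a2, M, S)               # M x S
        calls[t(hap) == 1L] <- matrix(a1, M, S)[t(hap) == 1L]
        ## minor-allele floor: no monomorphic SNP unless K == 1
        if (K >= 2L) {
            mono <- which(vapply(seq_len(M), function(j)
                length(unique(calls[j, ])) == 1L, logical(1)))
            for (j in mono) {
                flip <- sample(S, 1L)
                calls[j, flip] <- if (calls[j, flip] == a1[j]) a2[j] else a1[j]
            }
        }
        dimnames(calls) <- list(sprintf("rs_c%d_%05d", cc, seq_len(M)),
                                strains)
        callsAll[[cc]] <- calls
        chromAll[[cc]] <- rep(sprintf("chr%d", cc), M)
        posAll[[cc]] <- pos
        idAll[[cc]] <- rownames(calls)
    }
    calls <- do.call(rbind, callsAll)
    chrom <- unlist(chromAll)
    pos <- unlist(posAll)

    ## plant QTL windows
    planted <- list()
    for (q in config@qtlSpecs) {
        carriers <- .normalizeCarriers(q$carrierStrains, strains)
        cc <- as.integer(q$chromosome)
        localRows <- q$windowIndex:(q$windowIndex + 2L)
        globalRows <- (cc - 1L) * M + localRows
        cm <- strains %in% carriers
        for (r in globalRows) {
            u <- setdiff(unique(calls[r, ]), "N")
            if (length(u) < 2L)
                u <- c(u, setdiff(c("A", "G", "C", "T"), u))
            calls[r, cm] <- u[1L]
            calls[r, !cm] <- u[2L]
        }
        planted[[length(planted) + 1L]] <- list(
            chromosome = sprintf("chr%d", cc), windowIndex = q$windowIndex,
            carrierStrains = carriers, effectSize = q$effectSize,
            start = pos[(cc - 1L) * M + q$windowIndex][1L],
            end = unname(pos[(cc - 1L) * M + q$windowIndex + 2L]),
            snps = rownames(calls)[globalRows])
    }

    panel <- StrainPanel(calls, chrom = chrom, pos = pos)
    truth <- new("TruthRecord", plantedQtls = planted,
                 cladeAssignment = clade,
                 realizedH2 = NA_real_,
                 strainGeneticValues = stats::setNames(rep(NA_real_, S),
                                                       strains))
    list(panel = panel, truth = truth)
}

#' Simulate animal-level phenotypes for a panel
#'
#' Inverts the one-way strain ANOVA model: each animal's value is its
#' strain's genetic value (baseline + strain random effect + planted QTL
#' effects for carriers) plus residual noise whose variance is scaled so
#' that the between-strain share of total variance equals \code{targetH2}.
#' Tail-climb exclusion flags are drawn per animal with the strain's
#' configured probability.
#'
#' @param panel the simulated \linkS4class{StrainPanel}.
#' @param truth the matching \linkS4class{TruthRecord}.
#' @param config the \linkS4class{SimConfig} used for the panel.
#' @param trait trait name used in the emitted records (default
#'   \code{"TST"}).
#' @param baseline grand mean in phenotype units (default 30).
#' @return list with \code{phenotypes} (a \linkS4class{PhenoTable}) and
#'   \code{truth} (updated with strain genetic values and the realized
#'   heritability from the generating variance components).
#' @export
simulatePhenotypes <- function(panel, truth, config, trait = "TST",
                               baseline = 30) {
    stopifnot(is(panel, "StrainPanel"), is(truth, "TruthRecord"),
              is(config, "SimConfig"))
    strains <- strainNames(panel)
    S <- length(strains)
    h2 <- config@targetH2

    restore <- .localSeed(.stageSeed(config@seed, 2L))
    on.exit(restore())

    qtlShift <- stats::setNames(rep(0, S), strains)
    for (q in truth@plantedQtls)
        qtlShift[q$carrierStrains] <- qtlShift[q$carrierStrains] +
            q$effectSize
    if (h2 == 0) {
        if (any(qtlShift != 0))
            stop("targetH2 = 0 is unreachable with non-zero planted effects")
        g <- stats::setNames(rep(baseline, S), strains)
        sigmaE <- 1
    } else {
        g <- baseline + stats::rnorm(S, 0, config@strainSD) + qtlShift
        names(g) <- strains
        varG <- stats::var(g)
        if (varG == 0)
            stop("targetH2 > 0 is unreachable: zero between-strain variance")
        sigmaE <- if (h2 == 1) 0 else sqrt(varG * (1 - h2) / h2)
    }
    varG <- stats::var(g)
    realized <- if (varG == 0 && sigmaE > 0) 0 else
        varG / (varG + sigmaE^2)

    nMin <- config@nAnimalsPerStrain[1L]
    nMax <- config@nAnimalsPerStrain[2L]
    nAnimals <- if (nMin == nMax) rep(nMin, S) else
        sample(nMin:nMax, S, replace = TRUE)
    pTail <- config@tailclimbProb
    if (!is.null(names(pTail))) {
        p <- stats::setNames(rep(0, S), strains)
        p[names(pTail)] <- pTail
        pTail <- p
    } else pTail <- rep(pTail, length.out = S)

    recs <- vector("list", S)
    for (s in seq_len(S)) {
        n <- nAnimals[s]
        vals <- g[s] + stats::rnorm(n, 0, sigmaE)
        climbed <- stats::runif(n) < pTail[s]
        recs[[s]] <- data.frame(
            strain = strains[s],
            animal_id = sprintf("%s_a%03d", strains[s], seq_len(n)),
            trait = trait, value = vals, excluded = climbed,
            reason = ifelse(climbed, "tail_climb", ""))
    }
    pt <- PhenoTable(do.call(rbind, recs),
                     traits = data.frame(name = trait, units = "au",
                                         transform = "none"))
    truth@strainGeneticValues <- g
    truth@realizedH2 <- realized
    list(phenotypes = pt, truth = truth)
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d strains in %d clade(s), %d chromosome(s) x %d SNPs\n",
        object@nStrains, object@nClades, object@nChromosomes,
        object@snpsPerChromosome))
    cat(sprintf(
        "  spacing ~%g bp, blocks ~%g bp, %d ancestral haplotype(s), clade share %.2f\n",
        object@meanSnpSpacing, object@blockLengthMean,
        object@nAncestralHaplotypes, object@cladeShareProb))
    cat(sprintf("  target H2 = %.2f, %d planted QTL(s), seed %d\n",
        object@targetH2, length(object@qtlSpecs), object@seed))
})

setMethod("show", "TruthRecord", function(object) {
    cat(sprintf("TruthRecord: %d planted QTL(s), %d strain(s), realized H2 = %s\n",
        length(object@plantedQtls), length(object@cladeAssignment),
        ifelse(is.na(object@realizedH2), "NA",
               sprintf("%.3f", object@realizedH2))))
})
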