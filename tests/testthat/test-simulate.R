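test_that("simulation is bit-identical under a fixed seed", {
    cfg <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                     snpsPerChromosome = 60, nAncestralHaplotypes = 4,
                     nAnimalsPerStrain = c(5, 9), tailclimbProb = 0.1,
                     seed = 77)
    a <- simulatePanel(cfg)
    b <- simulatePanel(cfg)
    expect_identical(alleleCalls(a$panel), alleleCalls(b$panel))
    expect_equal(snpRanges(a$panel), snpRanges(b$panel))
    pa <- simulatePhenotypes(a$panel, a$truth, cfg)
    pb <- simulatePhenotypes(b$panel, b$truth, cfg)
    expect_identical(records(pa$phenotypes), records(pb$phenotypes))
    expect_identical(pa$truth@strainGeneticValues,
                     pb$truth@strainGeneticValues)
    ## a different seed gives a different panel
    cfg2 <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                      snpsPerChromosome = 60, seed = 78)
    expect_false(identical(alleleCalls(simulatePanel(cfg2)$panel),
                           alleleCalls(a$panel)))
})

test_that("one ancestral haplotype gives a monomorphic panel and an empty scan", {
    cfg <- SimConfig(nStrains = 10, nClades = 2, nChromosomes = 1,
                     snpsPerChromosome = 40, nAncestralHaplotypes = 1,
                     seed = 5)
    sim <- simulatePanel(cfg)
    nAllele <- apply(alleleCalls(sim$panel), 1, function(x)
        length(unique(x)))
    expect_true(all(nAllele == 1))
    vals <- stats::setNames(rnorm(10, 30), strainNames(sim$panel))
    scan <- genomeScan(sim$panel, vals, ScanParams(logTransform = "none"))
    expect_identical(sum(scan$passed_filter), 0L)
})

test_that("emitted SNP spacing honours the configured density", {
    cfg <- SimConfig(nStrains = 30, nClades = 5, nChromosomes = 1,
                     snpsPerChromosome = 500, meanSnpSpacing = 6000,
                     seed = 13)
    sim <- simulatePanel(cfg)
    pos <- GenomicRanges::start(snpRanges(sim$panel))
    gaps <- diff(pos)
    expect_true(all(gaps > 0))
    med <- stats::median(gaps)
    expect_gt(med, 3000)
    expect_lt(med, 9000)
})

test_that("no SNP is monomorphic when more than one ancestral haplotype", {
    cfg <- SimConfig(nStrains = 16, nClades = 4, nChromosomes = 2,
                     snpsPerChromosome = 120, nAncestralHaplotypes = 3,
                     seed = 19)
    sim <- simulatePanel(cfg)
    nAllele <- apply(alleleCalls(sim$panel), 1, function(x)
        length(unique(x)))
    expect_true(all(nAllele == 2))
})

test_that("clades share strictly more genotype identity than non-clades", {
    cfg <- SimConfig(nStrains = 20, nClades = 4, nChromosomes = 1,
                     snpsPerChromosome = 300, cladeShareProb = 0.9,
                     seed = 23)
    sim <- simulatePanel(cfg)
    simMat <- strainWeights(sim$panel, "uniform")$similarity
    cl <- sim$truth@cladeAssignment[rownames(simMat)]
    same <- outer(cl, cl, "==") & upper.tri(simMat)
    diffc <- outer(cl, cl, "!=") & upper.tri(simMat)
    expect_gt(mean(simMat[same]), mean(simMat[diffc]))
})

test_that("the planted window separates carriers from non-carriers exactly", {
    carriers <- c("S01", "S04", "S07", "S10", "S13")
    cfg <- SimConfig(nStrains = 15, nClades = 3, nChromosomes = 1,
                     snpsPerChromosome = 80,
                     qtlSpecs = list(list(chromosome = 1, windowIndex = 30,
                                          carrierStrains = carriers,
                                          effectSize = 2)),
                     seed = 31)
    sim <- simulatePanel(cfg)
    q <- sim$truth@plantedQtls[[1]]
    asn <- inferWindowHaplotypes(sim$panel, q$snps[1])
    grpOf <- rep(names(asn$groups), lengths(asn$groups))
    names(grpOf) <- unlist(asn$groups)
    expect_length(unique(grpOf[carriers]), 1L)
    others <- setdiff(strainNames(sim$panel), carriers)
    expect_false(any(grpOf[others] %in% grpOf[carriers]))
    ## and the SDP matcher finds exactly the planted SNPs in that region
    hits <- sdpMatch(sim$panel, carriers)
    expect_true(all(q$snps %in% hits))
})

test_that("phenotype generation hits degenerate heritability targets", {
    cfg0 <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                      snpsPerChromosome = 30, targetH2 = 0,
                      nAnimalsPerStrain = c(10, 10), seed = 41)
    sim <- simulatePanel(cfg0)
    ph0 <- simulatePhenotypes(sim$panel, sim$truth, cfg0)
    expect_equal(ph0$truth@realizedH2, 0)
    expect_equal(unname(stats::sd(ph0$truth@strainGeneticValues)), 0)

    ## residual variance zero: estimator returns 1
    cfg1 <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                      snpsPerChromosome = 30, targetH2 = 1,
                      nAnimalsPerStrain = c(10, 10), seed = 41)
    ph1 <- simulatePhenotypes(sim$panel, sim$truth, cfg1)
    rec <- records(ph1$phenotypes)
    expect_equal(adjustedVarianceExplained(rec$value, rec$strain)$R2_adj, 1,
                 tolerance = 1e-12)

    ## unreachable targets are configuration errors
    cfgBad <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                        snpsPerChromosome = 30, targetH2 = 1, strainSD = 0,
                        nAnimalsPerStrain = c(10, 10), seed = 41)
    expect_error(simulatePhenotypes(sim$panel, sim$truth, cfgBad),
                 "unreachable")
    cfgBad0 <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                         snpsPerChromosome = 30, targetH2 = 0,
                         qtlSpecs = list(list(chromosome = 1,
                                              windowIndex = 5,
                                              carrierStrains = 1:3,
                                              effectSize = 1)),
                         nAnimalsPerStrain = c(10, 10), seed = 41)
    simB <- simulatePanel(cfgBad0)
    expect_error(simulatePhenotypes(simB$panel, simB$truth, cfgBad0),
                 "unreachable")
})

test_that("tail-climb flags follow the per-strain probabilities", {
    p <- stats::setNames(rep(0, 12), sprintf("S%02d", 1:12))
    p[c("S01", "S02")] <- 0.5
    cfg <- SimConfig(nStrains = 12, nClades = 3, nChromosomes = 1,
                     snpsPerChromosome = 30, targetH2 = 0.5,
                     nAnimalsPerStrain = c(30, 30), tailclimbProb = p,
                     seed = 51)
    sim <- simulatePanel(cfg)
    ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
    rec <- records(ph$phenotypes)
    flagged <- tapply(rec$excluded, rec$strain, sum)
    expect_true(all(flagged[c("S01", "S02")] > 0))
    expect_true(all(flagged[setdiff(names(flagged),
                                    c("S01", "S02"))] == 0))
    expect_true(all(rec$reason[rec$excluded] == "tail_climb"))
})

test_that("configuration errors are caught at construction", {
    expect_error(SimConfig(nStrains = 10, nClades = 2,
                           cladeSizes = c(4, 4)), "sum to nStrains")
    expect_error(SimConfig(snpsPerChromosome = 0), ">= 1")
    expect_error(SimConfig(meanSnpSpacing = -5), "positive")
    expect_error(SimConfig(targetH2 = 1.2), "\\[0, 1\\]")
    expect_error(SimConfig(qtlSpecs = list(list(chromosome = 1,
        windowIndex = 5, carrierStrains = 1:33, effectSize = 1))),
        "proper subset")
})
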