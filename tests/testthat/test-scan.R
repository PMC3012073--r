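test_that("haplotype grouping is exact string identity with missing-call handling", {
    ## all strains identical in the window
    p1 <- panelFromRows(list(rep("A", 8), rep("C", 8), rep("G", 8)))
    a1 <- inferWindowHaplotypes(p1, 1)
    expect_length(a1$groups, 1L)
    expect_length(a1$groups[[1]], 8L)

    ## 12 strains: AAA x5, GGG x5, AGA x2
    str12 <- c(rep("AAA", 5), rep("GGG", 5), rep("AGA", 2))
    rows <- lapply(1:3, function(i) substr(str12, i, i))
    p2 <- panelFromRows(rows)
    a2 <- inferWindowHaplotypes(p2, 1)
    expect_setequal(lengths(a2$groups), c(5L, 5L, 2L))
    expect_identical(sort(unlist(a2$groups, use.names = FALSE)),
                     sort(strainNames(p2)))

    ## a missing call excludes that strain; the rest still partition
    rows3 <- rows; rows3[[2]][1] <- "N"
    p3 <- panelFromRows(rows3)
    a3 <- inferWindowHaplotypes(p3, 1)
    expect_identical(a3$excluded, "s01")
    expect_identical(sort(unlist(a3$groups, use.names = FALSE)),
                     sort(setdiff(strainNames(p3), "s01")))
})

test_that("the group-size filter matches the stated rule", {
    str12 <- c(rep("AAA", 5), rep("GGG", 5), rep("AGA", 2))
    p <- panelFromRows(lapply(1:3, function(i) substr(str12, i, i)))
    a <- inferWindowHaplotypes(p, 1)
    expect_true(passesFilter(a))                       # {5,5,2}
    pAll <- panelFromRows(list(c(rep("A", 30), rep("G", 3)),
                               rep("C", 33), rep("G", 33)))
    ## {30,3} at snp1..3: only one group reaches 5 members
    expect_false(passesFilter(inferWindowHaplotypes(pAll, 1)))
    str444 <- rep(c("AAA", "GGG", "AGA"), 4)
    p444 <- panelFromRows(lapply(1:3, function(i) substr(str444, i, i)))
    expect_false(passesFilter(inferWindowHaplotypes(p444, 1)))  # {4,4,4}
    expect_true(passesFilter(inferWindowHaplotypes(p444, 1),
                             ScanParams(minMembers = 4)))
})

test_that("toy panel window retention matches hand enumeration", {
    p <- toyPanel()
    scan <- genomeScan(p, stats::setNames(rnorm(12, 30),
                                          strainNames(p)),
                       ScanParams(logTransform = "none"))
    expect_identical(scan$passed_filter, toyPanelExpectedPass)
})

test_that("raising the member floor never increases scored windows", {
    p <- randomPanel(20, 150, seed = 8)
    vals <- stats::setNames(rnorm(20, 30), strainNames(p))
    scored <- vapply(2:8, function(m)
        sum(genomeScan(p, vals, ScanParams(minMembers = m,
            logTransform = "none"))$passed_filter), integer(1))
    expect_true(all(diff(scored) <= 0))
})

test_that("strain weights down-weight near-duplicates and preserve symmetry", {
    p <- randomPanel(10, 200, seed = 14)
    w0 <- strainWeights(p, "uniform")
    expect_true(all(w0$weights == 1))
    expect_equal(diag(w0$similarity), rep(1, 10), ignore_attr = TRUE)
    expect_equal(w0$similarity, t(w0$similarity))

    ## duplicate a strain: the twin pair gets strictly the lowest weights
    calls <- alleleCalls(p)
    calls <- cbind(calls, s11 = calls[, "s01"])
    rr <- snpRanges(p)
    pDup <- StrainPanel(calls, as.character(GenomicRanges::seqnames(rr)),
                        GenomicRanges::start(rr))
    w <- strainWeights(pDup, "estimate3")
    expect_equal(unname(mean(w$weights)), 1, tolerance = 1e-12)
    twins <- w$weights[c("s01", "s11")]
    expect_true(all(twins < min(w$weights[setdiff(names(w$weights),
                                                  c("s01", "s11"))])))
    expect_error(strainWeights(p, "bogus"), "unknown weight scheme")
    ## weights do not depend on strain ordering
    o <- sample(ncol(calls))
    pPerm <- StrainPanel(calls[, o],
                         as.character(GenomicRanges::seqnames(rr)),
                         GenomicRanges::start(rr))
    wPerm <- strainWeights(pPerm, "estimate3")
    expect_equal(wPerm$weights[names(w$weights)], w$weights,
                 tolerance = 1e-12)
})

test_that("weighted ANOVA reduces to the textbook F under uniform weights", {
    str <- c(rep("AAA", 3), rep("GGG", 3))
    p <- panelFromRows(lapply(1:3, function(i) substr(str, i, i)))
    a <- inferWindowHaplotypes(p, 1)
    vals <- stats::setNames(c(1, 2, 3, 4, 5, 6), strainNames(p))
    prm <- ScanParams(minMembers = 1, logTransform = "none")
    res <- weightedAnova(a, vals, params = prm)
    expect_equal(res$F, 13.5, tolerance = 1e-12)
    expect_identical(c(res$df_between, res$df_within), c(1L, 4L))
    expect_equal(res$p, lmAnovaOracle(vals, rep(1:2, each = 3))$p,
                 tolerance = 1e-12)

    ## equal group means: F = 0, logP ~ 0
    vals0 <- stats::setNames(c(1, 2, 3, 1, 2, 3), strainNames(p))
    expect_equal(weightedAnova(a, vals0, params = prm)$F, 0,
                 tolerance = 1e-12)

    ## doubling all weights leaves F unchanged
    w1 <- stats::setNames(runif(6, 0.5, 2), strainNames(p))
    r1 <- weightedAnova(a, vals, weights = w1, params = prm)
    r2 <- weightedAnova(a, vals, weights = 2 * w1, params = prm)
    expect_equal(r1$F, r2$F, tolerance = 1e-12)

    ## zero within-group variance: capped score, flagged
    valsC <- stats::setNames(c(1, 1, 1, 2, 2, 2), strainNames(p))
    rc <- weightedAnova(a, valsC, params = prm)
    expect_true(rc$capped)
    expect_equal(rc$logP, 50)
})

test_that("the genome scan is invariant to strain order and allele relabeling", {
    p <- randomPanel(16, 80, seed = 26)
    vals <- stats::setNames(rnorm(16, 30), strainNames(p))
    prm <- ScanParams(minMembers = 3, logTransform = "none")
    ref <- genomeScan(p, vals, prm)

    ## permute strain columns and the value vector
    calls <- alleleCalls(p)
    rr <- snpRanges(p)
    o <- sample(16)
    pPerm <- StrainPanel(calls[, o],
                         as.character(GenomicRanges::seqnames(rr)),
                         GenomicRanges::start(rr))
    out <- genomeScan(pPerm, vals[sample(16)], prm)
    expect_equal(out$logP, ref$logP)
    expect_equal(out$F, ref$F)

    ## relabel alleles at a third of the SNPs (swap the two letters)
    calls2 <- calls
    for (j in sample(nrow(calls2), 25)) {
        u <- unique(calls2[j, ])
        calls2[j, ] <- ifelse(calls2[j, ] == u[1], u[2], u[1])
    }
    pSwap <- StrainPanel(calls2,
                         as.character(GenomicRanges::seqnames(rr)),
                         GenomicRanges::start(rr))
    out2 <- genomeScan(pSwap, vals, prm)
    expect_equal(out2$logP, ref$logP, tolerance = 1e-12)
})

test_that("log transforms are applied and nonpositive phenotypes are named", {
    p <- randomPanel(12, 30, seed = 31)
    vals <- stats::setNames(runif(12, 10, 60), strainNames(p))
    prm10 <- ScanParams(minMembers = 2, logTransform = "log10")
    prmNo <- ScanParams(minMembers = 2, logTransform = "none")
    s10 <- genomeScan(p, vals, prm10)
    sNo <- genomeScan(p, log10(vals), prmNo)
    expect_equal(s10$logP, sNo$logP, tolerance = 1e-10)
    bad <- vals; bad["s05"] <- -1
    expect_error(genomeScan(p, bad, prm10), "s05")
})

test_that("a strong planted QTL is the scan peak under both weight schemes", {
    for (r in 1:5) {
        carriers <- sprintf("S%02d", c(1, 5, 9, 13, 17, 20, 3))
        cfg <- SimConfig(nStrains = 20, nClades = 4, nChromosomes = 1,
                         snpsPerChromosome = 300,
                         qtlSpecs = list(list(chromosome = 1,
                                              windowIndex = 150,
                                              carrierStrains = carriers,
                                              effectSize = 4)),
                         targetH2 = 0.7, nAnimalsPerStrain = c(12, 12),
                         seed = 600 + r)
        sim <- simulatePanel(cfg)
        ph <- simulatePhenotypes(sim$panel, sim$truth, cfg)
        mv <- strainMeans(ph$phenotypes, "TST")
        for (ws in c("estimate3", "uniform")) {
            scan <- genomeScan(sim$panel, mv,
                               ScanParams(logTransform = "none",
                                          weightScheme = ws))
            pk <- which.max(scan$logP)
            expect_lte(abs(scan$first_snp[pk] - 150), 2)
        }
    }
})

test_that("locus merging unions overlapping windows per chromosome", {
    p <- randomPanel(12, 40, seed = 37)
    vals <- stats::setNames(rnorm(12, 30), strainNames(p))
    scan <- genomeScan(p, vals, ScanParams(minMembers = 2,
                                           logTransform = "none"))
    ## no window above an impossible threshold
    expect_length(mergeLoci(scan, threshold = Inf), 0L)

    ## fabricate three consecutive overlapping significant windows: the
    ## locus must span the first SNP of w10 to the last SNP of w12
    scan$logP[] <- 0.1
    scan$passed_filter[] <- TRUE
    scan$logP[10:12] <- c(3, 5, 4)
    loci <- mergeLoci(scan, threshold = 2.5)
    expect_length(loci, 1L)
    pos <- GenomicRanges::start(snpRanges(p))
    expect_identical(GenomicRanges::start(loci), pos[10])
    expect_identical(GenomicRanges::end(loci), pos[14])
    expect_equal(loci$peak_logP, 5)
    expect_identical(loci$n_windows, 3L)

    ## windows on different chromosomes never merge
    calls <- alleleCalls(p)
    p2 <- StrainPanel(calls, chrom = rep(c("chr1", "chr2"), each = 20),
                      pos = rep(seq_len(20) * 100L, 2))
    scan2 <- genomeScan(p2, vals, ScanParams(minMembers = 2,
                                             logTransform = "none"))
    scan2$logP[] <- 0.1; scan2$passed_filter[] <- TRUE
    scan2$logP[c(5, 23)] <- 4
    expect_length(mergeLoci(scan2, threshold = 2.5), 2L)
})

test_that("SDP matching equals the brute-force scan", {
    p <- randomPanel(20, 200, seed = 43, missing = 30)
    strains <- strainNames(p)
    set.seed(44)
    carriers <- sample(strains, 7)
    got <- sdpMatch(p, carriers)
    ## brute force: compare every SNP's allele split with the bipartition
    calls <- alleleCalls(p)
    want <- rownames(calls)[vapply(seq_len(nrow(calls)), function(j) {
        x <- calls[j, ]
        if (any(x == "N")) return(FALSE)
        split <- strains[x == x[1]]
        setequal(split, carriers) || setequal(setdiff(strains, split),
                                              carriers)
    }, logical(1))]
    expect_identical(got, want)

    ## exactness: one strain off the pattern disqualifies the SNP
    row <- ifelse(strains %in% carriers, "A", "G")
    row2 <- row; row2[match(carriers[1], strains)] <- "G"
    pX <- panelFromRows(list(row, row2, rep("C", 20)), strains = strains)
    hits <- sdpMatch(pX, carriers)
    expect_identical(hits, "snp1")
    expect_error(sdpMatch(pX, c(carriers, "nope")), "unknown strain")
    ## region restriction
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 350))
    expect_identical(sdpMatch(pX, carriers, region = reg), character(0))
})
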