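## Shared fixture builders.  Everything is generated in code; nothing is
## read from disk except files the tests themselves write to tempdir().

## 12 strains x 7 SNPs with designed haplotype structure.  Strain groups:
## A = s01..s05, B = s06..s10, C = s11..s12; SNPs 6-7 split by strain
## parity.  Window-by-window group sizes (W = 3) enumerated by hand:
##   w1 (snp1-3): AAA x5, GGG x5, GGA x2          -> {5,5,2}  pass
##   w2 (snp2-4): AAA x5, GGG x5, GAA x2          -> {5,5,2}  pass
##   w3 (snp3-5): AAA x5, GGG x5, AAG x2          -> {5,5,2}  pass
##   w4 (snp4-6): splits by parity                -> {3,2,3,2,1,1} fail
##   w5 (snp5-7): splits by parity                -> {3,2,3,2,3,... } fail
toyPanel <- function() {
    strains <- sprintf("s%02d", 1:12)
    inA <- 1:12 <= 5
    even <- 1:12 %% 2 == 0
    rows <- rbind(
        ifelse(inA, "A", "G"),
        ifelse(inA, "A", "G"),
        ifelse(inA | 1:12 >= 11, "A", "G"),
        ifelse(inA | 1:12 >= 11, "A", "G"),
        ifelse(inA, "A", "G"),
        ifelse(even, "A", "G"),
        ifelse(even, "A", "G"))
    dimnames(rows) <- list(sprintf("snp%d", 1:7), strains)
    StrainPanel(rows, chrom = rep("chr1", 7), pos = seq(1000, 7000, 1000))
}

toyPanelExpectedPass <- c(TRUE, TRUE, TRUE, FALSE, FALSE)

## Panel from explicit allele rows (list of per-strain vectors).
panelFromRows <- function(rows, strains = NULL, chrom = NULL, pos = NULL) {
    m <- do.call(rbind, rows)
    if (is.null(strains)) strains <- sprintf("s%02d", seq_len(ncol(m)))
    dimnames(m) <- list(sprintf("snp%d", seq_len(nrow(m))), strains)
    if (is.null(chrom)) chrom <- rep("chr1", nrow(m))
    if (is.null(pos)) pos <- seq_len(nrow(m)) * 100L
    StrainPanel(m, chrom = chrom, pos = pos)
}

## Random biallelic panel (no missing calls) for property tests.
randomPanel <- function(nStrains, nSnps, seed, missing = 0) {
    set.seed(seed)
    strains <- sprintf("s%02d", seq_len(nStrains))
    calls <- matrix("", nSnps, nStrains)
    for (j in seq_len(nSnps)) {
        ab <- sample(c("A", "C", "G", "T"), 2)
        x <- sample(ab, nStrains, replace = TRUE)
        if (length(unique(x)) == 1L) x[1] <- setdiff(ab, x[1])
        calls[j, ] <- x
    }
    if (missing > 0)
        calls[sample(length(calls), missing)] <- "N"
    dimnames(calls) <- list(sprintf("snp%d", seq_len(nSnps)), strains)
    StrainPanel(calls, chrom = rep("chr1", nSnps),
                pos = seq_len(nSnps) * 50L)
}

## Long-form animal table from a named list strain -> values.
animalTable <- function(valuesByStrain, trait = "TST", units = "au",
                        excluded = NULL) {
    rec <- do.call(rbind, lapply(names(valuesByStrain), function(s) {
        v <- valuesByStrain[[s]]
        data.frame(strain = s,
                   animal_id = sprintf("%s_%03d", s, seq_along(v)),
                   trait = trait, value = v)
    }))
    if (!is.null(excluded)) {
        rec$excluded <- excluded
        rec$reason <- ifelse(excluded, "tail_climb", "")
    }
    PhenoTable(rec, traits = data.frame(name = trait, units = units))
}

## Textbook unweighted one-way ANOVA via lm(): the independent oracle for
## the weighted scan under uniform weights.
lmAnovaOracle <- function(values, groups) {
    fit <- stats::lm(values ~ factor(groups))
    a <- stats::anova(fit)
    list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
         df = unname(a$Df))
}
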