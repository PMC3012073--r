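#' Construct a StrainPanel
#'
#' Assemble a genotype panel from a character matrix of single-allele SNP
#' calls (rows = SNPs, columns = strains) and the SNPs' genomic coordinates.
#' SNPs are sorted canonically by (chromosome, position); ties are an error
#' because positions must be strictly increasing within a chromosome.
#'
#' @param calls character matrix of alleles in \code{A,C,G,T,N}; rows SNPs,
#'   columns strains.  Column names are the strain identifiers.
#' @param chrom chromosome identifier per SNP.
#' @param pos 1-based base-pair position per SNP.
#' @param rsID SNP identifiers; defaults to the row names of \code{calls}.
#' @return a \linkS4class{StrainPanel}.
#' @examples
#' calls <- matrix(c("A","A","G","G", "C","T","T","T"), nrow = 2,
#'                 byrow = TRUE, dimnames = list(c("rs1","rs2"),
#'                 c("s1","s2","s3","s4")))
#' StrainPanel(calls, chrom = c("chr1","chr1"), pos = c(100, 200))
#' @export
StrainPanel <- function(calls, chrom, pos, rsID = rownames(calls)) {
    stopifnot(is.matrix(calls), length(chrom) == nrow(calls),
              length(pos) == nrow(calls))
    if (is.null(rsID))
        stop("SNP identifiers (rsID) are required")
    if (anyDuplicated(rsID))
        stop("duplicate rsID: ", paste(unique(rsID[duplicated(rsID)]),
                                       collapse = ", "))
    if (is.null(colnames(calls)))
        stop("strain names (column names of 'calls') are required")
    if (anyDuplicated(colnames(calls)))
        stop("duplicated strain column: ",
             paste(unique(colnames(calls)[duplicated(colnames(calls))]),
                   collapse = ", "))
    o <- order(as.character(chrom), pos)
    calls <- calls[o, , drop = FALSE]
    chrom <- as.character(chrom)[o]
    pos <- as.integer(pos)[o]
    rsID <- as.character(rsID)[o]
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    names(rr) <- rsID
    rownames(calls) <- rsID
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls), rowRanges = rr)
    new("StrainPanel", se)
}

#' Accessors for StrainPanel
#'
#' \code{strainNames} returns the strain identifiers, \code{alleleCalls} the
#' SNP-by-strain allele matrix, and \code{snpRanges} the SNP coordinates as a
#' \code{GRanges} named by rsID.
#'
#' @param x a \linkS4class{StrainPanel}.
#' @return see individual descriptions.
#' @name StrainPanel-accessors
#' @aliases strainNames alleleCalls snpRanges
NULL

#' @rdname StrainPanel-accessors
#' @export
setMethod("strainNames", "StrainPanel", function(x) colnames(x))

#' @rdname StrainPanel-accessors
#' @export
setMethod("alleleCalls", "StrainPanel",
    function(x) SummarizedExperiment::assay(x, "calls"))

#' @rdname StrainPanel-accessors
#' @export
setMethod("snpRanges", "StrainPanel",
    function(x) SummarizedExperiment::rowRanges(x))

setMethod("show", "StrainPanel", function(object) {
    nChr <- length(unique(as.character(
        GenomicRanges::seqnames(snpRanges(object)))))
    cat(sprintf("StrainPanel: %d SNPs x %d strains on %d chromosome(s)\n",
                nrow(object), ncol(object), nChr))
    nmiss <- sum(alleleCalls(object) == "N")
    if (nmiss)
        cat(sprintf("  missing calls (N): %d\n", nmiss))
})
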