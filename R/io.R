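## Readers and writers for the plain-text dialects the pipeline uses:
## genotype TSV, phenotype CSV (long or wide), scan/locus TSV, BED, and
## calibration JSON.  All writes are atomic (temp file + rename) and TSV
## outputs carry a provenance comment header.

## Reasons that imply exclusion for a specific trait only.
.exclusionRules <- c(tail_climb = "TST", fell_off = "TST")

.atomicWrite <- function(writer, path) {
    dir <- dirname(path)
    if (!dir.exists(dir))
        stop("output directory does not exist: ", dir)
    tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("could not move temporary file onto ", path)
    invisible(path)
}

.provenance <- function(seed = NA, extra = character(0)) {
    ver <- as.character(utils::packageVersion("strainHAM"))
    c(sprintf("# strainHAM %s", ver),
      if (!is.na(seed)) sprintf("# seed: %s", seed),
      extra)
}

#' Read a genotype panel from TSV
#'
#' Expects a tab-separated file with header
#' \code{rsID chrom bp <strain1> ... <strainS>} and allele letters
#' \code{A,C,G,T} or \code{N} for missing.  Comment lines starting with
#' \code{#} are skipped.  SNPs with more than two non-N alleles are
#' rejected with their line numbers (a message reports the count);
#' duplicate rsIDs and duplicated strain columns are errors; rows out of
#' positional order are sorted with a warning.
#'
#' @param path file path.
#' @return a \linkS4class{StrainPanel}.
#' @export
readGenotypes <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                            colClasses = "character")
    need <- c("rsID", "chrom", "bp")
    if (!all(need %in% names(df)[1:3]))
        stop("genotype TSV must start with columns rsID, chrom, bp")
    strains <- names(df)[-(1:3)]
    if (!length(strains)) stop("no strain columns found")
    dup <- unique(strains[duplicated(strains)])
    if (length(dup))
        stop("duplicated strain column: ", paste(dup, collapse = ", "))
    if (anyDuplicated(df$rsID))
        stop("duplicate rsID: ",
             paste(unique(df$rsID[duplicated(df$rsID)]), collapse = ", "))
    calls <- as.matrix(df[strains])
    bad <- which(!(calls %in% VALID_ALLELES))
    if (length(bad)) {
        rowi <- ((bad - 1L) %% nrow(calls)) + 1L
        stop(sprintf("unknown allele symbol '%s' at line %d (SNP %s)",
                     calls[bad[1L]], rowi[1L] + 1L, df$rsID[rowi[1L]]))
    }
    nAllele <- apply(calls, 1L, function(x) length(unique(x[x != "N"])))
    tri <- which(nAllele > 2L)
    if (length(tri)) {
        message(sprintf(
            "rejecting %d SNP(s) with more than 2 alleles (line(s) %s)",
            length(tri), paste(tri + 1L, collapse = ", ")))
        calls <- calls[-tri, , drop = FALSE]
        df <- df[-tri, , drop = FALSE]
    }
    bp <- as.integer(df$bp)
    unsorted <- any(vapply(split(bp, df$chrom),
                           function(p) any(diff(p) <= 0), logical(1)))
    if (unsorted)
        warning("positions not strictly increasing; sorting canonically",
                call. = FALSE)
    rownames(calls) <- df$rsID
    StrainPanel(calls, chrom = df$chrom, pos = bp)
}

#' Write a genotype panel to TSV
#'
#' @param panel a \linkS4class{StrainPanel}.
#' @param path output file path.
#' @param seed optional seed recorded in the provenance header.
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(panel, path, seed = NA) {
    rr <- snpRanges(panel)
    df <- data.frame(rsID = names(rr),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     bp = GenomicRanges::start(rr),
                     alleleCalls(panel), check.names = FALSE)
    .atomicWrite(function(tmp) {
        writeLines(.provenance(seed), tmp)
        suppressWarnings(utils::write.table(df, tmp, sep = "\t",
            quote = FALSE, row.names = FALSE, append = TRUE))
    }, path)
}

#' Read a phenotype table from CSV
#'
#' Long form has header
#' \code{strain,animal_id,trait,value,excluded,reason}; \code{excluded}
#' may be logical, or empty with the reason carried in \code{reason}.
#' Alternatively a wide form has one row per animal with trait columns
#' named in \code{traits} and an optional \code{exclude_reason} column.  A
#' reason known to apply to a specific trait (for example
#' \code{tail_climb}, which invalidates the tail suspension test only)
#' flags that trait's record alone; unknown reasons flag the record they
#' appear on (long form) or all of the animal's records (wide form).
#'
#' @param path file path.
#' @param traits optional trait dictionary data.frame (\code{name},
#'   \code{units}); required to interpret the wide form, defaulted for the
#'   long form.
#' @return a \linkS4class{PhenoTable}.
#' @export
readPhenotypes <- function(path, traits = NULL) {
    df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
    if (!nrow(df)) stop("empty phenotype file: ", path)
    long <- all(c("strain", "animal_id", "trait", "value") %in% names(df))
    if (long) {
        if (is.null(df$reason)) df$reason <- ""
        df$reason[is.na(df$reason)] <- ""
        if (is.null(df$excluded)) df$excluded <- NA
        if (is.character(df$excluded)) {
            ## the excluded column may carry the reason string itself
            isReason <- !toupper(df$excluded) %in% c("TRUE", "FALSE", "")
            isReason[is.na(isReason)] <- FALSE
            df$reason[isReason & df$reason == ""] <- df$excluded[isReason]
            df$excluded[isReason] <- NA
        }
        excl <- df$excluded
        if (!is.logical(excl)) excl <- as.logical(excl)
        ## reasons imply exclusion; trait-specific reasons only bind their
        ## own trait's records
        ruleTrait <- .exclusionRules[df$reason]
        implied <- df$reason != "" &
            (is.na(ruleTrait) | ruleTrait == df$trait)
        df$excluded <- ifelse(is.na(excl), implied, excl & implied |
                              (excl & df$reason == ""))
        df$reason[!df$excluded] <- ""
    } else {
        if (is.null(traits))
            stop("wide-form phenotype CSV needs a trait dictionary")
        if (!all(c("strain", "animal_id") %in% names(df)))
            stop("wide form needs strain and animal_id columns")
        missingTr <- setdiff(traits$name, names(df))
        if (length(missingTr))
            stop("declared trait column(s) absent: ",
                 paste(missingTr, collapse = ", "))
        reason <- if ("exclude_reason" %in% names(df))
            ifelse(is.na(df$exclude_reason), "", df$exclude_reason)
            else rep("", nrow(df))
        rows <- lapply(traits$name, function(tr) {
            ruleTrait <- .exclusionRules[reason]
            flag <- reason != "" & (is.na(ruleTrait) | ruleTrait == tr)
            data.frame(strain = df$strain, animal_id = df$animal_id,
                       trait = tr, value = as.numeric(df[[tr]]),
                       excluded = flag,
                       reason = ifelse(flag, reason, ""))
        })
        df <- do.call(rbind, rows)
        df <- df[!is.na(df$value), , drop = FALSE]
    }
    key <- paste(df$strain, df$animal_id, df$trait)
    if (anyDuplicated(key))
        stop("duplicate (strain, animal_id, trait) at row(s): ",
             paste(which(duplicated(key)), collapse = ", "))
    if (is.null(traits))
        traits <- data.frame(name = unique(df$trait), units = "au")
    pct <- traits$name[traits$units %in% c("percent", "%")]
    bad <- which(df$trait %in% pct & !is.na(df$value) &
                 (df$value < 0 | df$value > 100))
    if (length(bad))
        stop(sprintf("percent value out of [0, 100] at row %d (%s %s = %g)",
                     bad[1L], df$strain[bad[1L]], df$trait[bad[1L]],
                     df$value[bad[1L]]))
    PhenoTable(df, traits = traits)
}

#' Write a phenotype table to CSV
#'
#' @param table a \linkS4class{PhenoTable}.
#' @param path output file path.
#' @param form \code{"long"} (default) or \code{"wide"} (one row per
#'   animal, one column per trait, exclusion reasons in
#'   \code{exclude_reason}).
#' @return the path, invisibly.
#' @export
writePhenotypes <- function(table, path, form = c("long", "wide")) {
    form <- match.arg(form)
    rec <- records(table)
    if (form == "wide") {
        wide <- stats::reshape(
            rec[c("strain", "animal_id", "trait", "value")],
            idvar = c("strain", "animal_id"), timevar = "trait",
            direction = "wide")
        names(wide) <- sub("^value\\.", "", names(wide))
        reasons <- tapply(rec$reason, paste(rec$strain, rec$animal_id),
                          function(r) {
                              r <- r[r != ""]
                              if (length(r)) r[1L] else ""
                          })
        wide$exclude_reason <- reasons[paste(wide$strain, wide$animal_id)]
        rec <- wide
    }
    .atomicWrite(function(tmp)
        utils::write.csv(rec, tmp, row.names = FALSE, quote = FALSE),
        path)
}

#' Write a gFWER calibration to JSON
#'
#' @param calibration a \linkS4class{GfwerCalibration}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCalibration <- function(calibration, path) {
    obj <- list(
        params = list(B = calibration@params@B, k = calibration@params@k,
                      alpha_levels = calibration@params@alphaLevels,
                      seed = calibration@params@seed),
        null_kth_scores = calibration@nullKthScores,
        thresholds = as.list(calibration@thresholds),
        short_scans = calibration@shortScans)
    .atomicWrite(function(tmp)
        jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA),
        path)
}

#' Read a gFWER calibration from JSON
#'
#' @param path file written by \code{\link{writeCalibration}}.
#' @return a \linkS4class{GfwerCalibration}.
#' @export
readCalibration <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    params <- GfwerParams(B = obj$params$B, k = obj$params$k,
                          alphaLevels = obj$params$alpha_levels,
                          seed = obj$params$seed)
    new("GfwerCalibration",
        nullKthScores = as.numeric(obj$null_kth_scores), params = params,
        thresholds = unlist(obj$thresholds),
        shortScans = as.integer(obj$short_scans))
}

.lociTable <- function(loci) {
    if (!length(loci))
        return(data.frame(chrom = character(0), start_bp = integer(0),
                          end_bp = integer(0), Mb = character(0),
                          peak_logP = numeric(0), adjusted_p = numeric(0),
                          peak_snps = character(0), n_windows = integer(0)))
    data.frame(
        chrom = as.character(GenomicRanges::seqnames(loci)),
        start_bp = GenomicRanges::start(loci),
        end_bp = GenomicRanges::end(loci),
        Mb = sprintf("%.2f-%.2f", GenomicRanges::start(loci) / 1e6,
                     GenomicRanges::end(loci) / 1e6),
        peak_logP = loci$peak_logP,
        adjusted_p = if (!is.null(loci$adjusted_p)) loci$adjusted_p
                     else NA_real_,
        peak_snps = loci$peak_snps,
        n_windows = loci$n_windows)
}

#' Write scan outputs to a directory
#'
#' Emits \code{windows.tsv} (every window with haplotype sizes, F and
#' \eqn{-\log_{10}p}), \code{loci.tsv} and \code{loci.bed} (merged loci;
#' BED uses the 0-based half-open convention, internal coordinates are
#' 1-based inclusive), \code{calibration.json} when a calibration is given,
#' and \code{manhattan.tsv} (chromosome, position, cumulative bp, score)
#' for plotting.  Writes are atomic and each TSV carries a provenance
#' header.  Empty locus sets produce header-only files.
#'
#' @param scan result of \code{\link{genomeScan}}.
#' @param loci result of \code{\link{mergeLoci}} (may be empty).
#' @param calibration optional \linkS4class{GfwerCalibration}.
#' @param outDir output directory (created if needed).
#' @param seed seed recorded in the provenance headers.
#' @return named character vector of written paths, invisibly.
#' @export
writeResults <- function(scan, loci, calibration = NULL, outDir,
                         seed = NA) {
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    if (!dir.exists(outDir) || file.access(outDir, 2L) != 0L)
        stop("output directory is not writable: ", outDir)
    paths <- c(windows = file.path(outDir, "windows.tsv"),
               loci = file.path(outDir, "loci.tsv"),
               bed = file.path(outDir, "loci.bed"),
               manhattan = file.path(outDir, "manhattan.tsv"))
    win <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(scan)),
        start_bp = GenomicRanges::start(scan),
        end_bp = GenomicRanges::end(scan),
        snps = scan$snps, haplotype_sizes = scan$haplotype_sizes,
        F = scan$F, logP = scan$logP, passed_filter = scan$passed_filter)
    .atomicWrite(function(tmp) {
        writeLines(.provenance(seed), tmp)
        suppressWarnings(utils::write.table(win, tmp, sep = "\t",
            quote = FALSE, row.names = FALSE, append = TRUE))
    }, paths["windows"])
    lt <- .lociTable(loci)
    .atomicWrite(function(tmp) {
        writeLines(.provenance(seed), tmp)
        suppressWarnings(utils::write.table(lt, tmp, sep = "\t",
            quote = FALSE, row.names = FALSE, append = TRUE))
    }, paths["loci"])
    ## BED: 0-based half-open
    .atomicWrite(function(tmp) {
        lines <- if (nrow(lt))
            sprintf("%s\t%d\t%d\tlocus_%d\t%.3f", lt$chrom,
                    lt$start_bp - 1L, lt$end_bp, seq_len(nrow(lt)),
                    lt$peak_logP)
        else character(0)
        writeLines(c("track name=strainHAM_loci", lines), tmp)
    }, paths["bed"])
    scored <- !is.na(scan$logP)
    chrOrder <- unique(as.character(GenomicRanges::seqnames(scan)))
    chrMax <- vapply(chrOrder, function(ch)
        max(GenomicRanges::end(scan[as.character(
            GenomicRanges::seqnames(scan)) == ch])), numeric(1))
    offsets <- stats::setNames(cumsum(c(0, chrMax[-length(chrMax)])),
                               chrOrder)
    man <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(scan))[scored],
        bp = GenomicRanges::start(scan)[scored],
        cumulative_bp = GenomicRanges::start(scan)[scored] +
            offsets[as.character(GenomicRanges::seqnames(scan))[scored]],
        logP = scan$logP[scored])
    .atomicWrite(function(tmp) {
        writeLines(.provenance(seed), tmp)
        suppressWarnings(utils::write.table(man, tmp, sep = "\t",
            quote = FALSE, row.names = FALSE, append = TRUE))
    }, paths["manhattan"])
    if (!is.null(calibration)) {
        paths <- c(paths, calibration = file.path(outDir,
                                                  "calibration.json"))
        writeCalibration(calibration, paths[["calibration"]])
    }
    invisible(paths)
}

#' Expected column layout for strain-survey phenotype downloads
#'
#' Converter stub: public strain-survey repositories export per-animal
#' measurement tables in their own dialects.  This documents the wide-form
#' CSV shape \code{\link{readPhenotypes}} expects after conversion — one
#' row per animal with \code{strain}, \code{animal_id}, one column per
#' trait, and an optional \code{exclude_reason} — and returns an empty
#' template data.frame.
#'
#' @param traitNames trait column names to include.
#' @return zero-row data.frame with the expected columns.
#' @export
mpdPhenotypeTemplate <- function(traitNames = c("TST", "OF_center_pct",
                                                "OF_distance_cm")) {
    cols <- c("strain", "animal_id", traitNames, "exclude_reason")
    out <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols))
    for (tr in traitNames) out[[tr]] <- numeric(0)
    out
}
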