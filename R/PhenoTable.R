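#' Construct a PhenoTable
#'
#' @param records data.frame with columns \code{strain}, \code{animal_id},
#'   \code{trait}, \code{value}, and optionally \code{excluded} (logical,
#'   default \code{FALSE}) and \code{reason} (character, default \code{""}).
#' @param traits trait dictionary: data.frame with columns \code{name},
#'   \code{units} and optionally \code{transform}.  If omitted, every trait
#'   present in \code{records} is declared with units \code{"au"}.
#' @return a \linkS4class{PhenoTable}.
#' @examples
#' rec <- data.frame(strain = "A", animal_id = 1:3, trait = "TST",
#'                   value = c(20, 25, 30))
#' PhenoTable(rec, traits = data.frame(name = "TST", units = "percent"))
#' @export
PhenoTable <- function(records, traits = NULL) {
    records <- as.data.frame(records)
    if (is.null(records$excluded)) records$excluded <- FALSE
    if (is.null(records$reason)) records$reason <- ""
    records$strain <- as.character(records$strain)
    records$animal_id <- as.character(records$animal_id)
    records$trait <- as.character(records$trait)
    records$value <- as.numeric(records$value)
    records$excluded <- as.logical(records$excluded)
    records$reason <- as.character(records$reason)
    if (is.null(traits))
        traits <- data.frame(name = unique(records$trait), units = "au")
    traits <- as.data.frame(traits)
    if (is.null(traits$transform)) traits$transform <- "none"
    rownames(records) <- NULL
    new("PhenoTable", records = records, traits = traits,
        exclusionLog = data.frame(strain = character(0),
                                  trait = character(0),
                                  n_excluded = integer(0)))
}

#' Accessors for PhenoTable
#'
#' \code{records} returns the long-form animal records, \code{traitInfo} the
#' trait dictionary, and \code{exclusionLog} the per-strain exclusion counts
#' recorded by \code{\link{applyExclusions}}.
#'
#' @param x a \linkS4class{PhenoTable}.
#' @return a data.frame.
#' @name PhenoTable-accessors
#' @aliases records traitInfo exclusionLog
NULL

#' @rdname PhenoTable-accessors
#' @export
setMethod("records", "PhenoTable", function(x) x@records)

#' @rdname PhenoTable-accessors
#' @export
setMethod("traitInfo", "PhenoTable", function(x) x@traits)

#' @rdname PhenoTable-accessors
#' @export
setMethod("exclusionLog", "PhenoTable", function(x) x@exclusionLog)

setMethod("show", "PhenoTable", function(object) {
    rec <- object@records
    cat(sprintf(
        "PhenoTable: %d records, %d strains, trait(s): %s\n",
        nrow(rec), length(unique(rec$strain)),
        paste(object@traits$name, collapse = ", ")))
    if (any(rec$excluded))
        cat(sprintf("  flagged for exclusion: %d\n", sum(rec$excluded)))
    if (nrow(object@exclusionLog))
        cat(sprintf("  exclusions applied: %d\n",
                    sum(object@exclusionLog$n_excluded)))
})
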