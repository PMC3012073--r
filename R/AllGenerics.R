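#' @rdname StrainPanel-accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname StrainPanel-accessors
#' @export
setGeneric("alleleCalls", function(x) standardGeneric("alleleCalls"))

#' @rdname StrainPanel-accessors
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname PhenoTable-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname PhenoTable-accessors
#' @export
setGeneric("traitInfo", function(x) standardGeneric("traitInfo"))

#' @rdname PhenoTable-accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname GfwerCalibration-accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @rdname GfwerCalibration-accessors
#' @export
setGeneric("gfwerThresholds", function(x) standardGeneric("gfwerThresholds"))
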