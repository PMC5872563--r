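#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname accessors
#' @export
setGeneric("readIDs", function(x) standardGeneric("readIDs"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("readOrigins", function(x) standardGeneric("readOrigins"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("mec", function(x) standardGeneric("mec"))

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("truthHaplotypes", function(x) standardGeneric("truthHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))

#' @rdname accessors
#' @export
setGeneric("plantedErrors", function(x) standardGeneric("plantedErrors"))

#' @rdname assignmentMatrix
#' @export
setGeneric("assignmentMatrix", function(x, ...) standardGeneric("assignmentMatrix"))
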