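#' Accessor generics
#'
#' Small accessor layer over the S4 classes so user code never touches slots.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The corresponding slot value; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneLabel", function(x, ...) standardGeneric("geneLabel"))

#' @rdname accessors
#' @export
setGeneric("tssIndex", function(x, ...) standardGeneric("tssIndex"))

#' @rdname accessors
#' @export
setGeneric("promoterSeq", function(x, ...) standardGeneric("promoterSeq"))

#' @rdname accessors
#' @export
setGeneric("minusLnKd", function(x, ...) standardGeneric("minusLnKd"))

#' @rdname accessors
#' @export
setGeneric("uncertainty", function(x, ...) standardGeneric("uncertainty"))

#' @rdname accessors
#' @export
setGeneric("bestWindow", function(x, ...) standardGeneric("bestWindow"))

#' @rdname accessors
#' @export
setGeneric("componentValues", function(x, ...) standardGeneric("componentValues"))

#' @rdname accessors
#' @export
setGeneric("scanTrace", function(x, ...) standardGeneric("scanTrace"))

#' @rdname accessors
#' @export
setGeneric("zScore", function(x, ...) standardGeneric("zScore"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x, ...) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("foldChange", function(x, ...) standardGeneric("foldChange"))

#' @rdname accessors
#' @export
setGeneric("rateConstants", function(x, ...) standardGeneric("rateConstants"))

#' @rdname accessors
#' @export
setGeneric("derivedConstants", function(x, ...) standardGeneric("derivedConstants"))

#' @rdname accessors
#' @export
setGeneric("standardErrors", function(x, ...) standardGeneric("standardErrors"))

#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x, ...) standardGeneric("modelCoefficients"))

#' @rdname accessors
#' @export
setGeneric("windowLength", function(x, ...) standardGeneric("windowLength"))
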