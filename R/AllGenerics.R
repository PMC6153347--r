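#' @title Accessor generics
#' @description Accessors for the pipeline's S4 containers.
#' @param object an amdecode S4 object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object, ...) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("accuracySE", function(object, ...) standardGeneric("accuracySE"))

#' @rdname accessors
#' @export
setGeneric("bestWindow", function(object, ...) standardGeneric("bestWindow"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(object, ...) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("decodingMap", function(object, ...) standardGeneric("decodingMap"))

#' @rdname accessors
#' @export
setGeneric("nullValues", function(object, ...) standardGeneric("nullValues"))

#' @rdname accessors
#' @export
setGeneric("probMap", function(object, ...) standardGeneric("probMap"))

#' @rdname accessors
#' @export
setGeneric("selectedVoxels", function(object, ...) standardGeneric("selectedVoxels"))

#' @rdname accessors
#' @export
setGeneric("trialTable", function(object, ...) standardGeneric("trialTable"))

#' @rdname accessors
#' @export
setGeneric("windowTimes", function(object, ...) standardGeneric("windowTimes"))

#' @rdname accessors
#' @export
setGeneric("valenceGroup", function(object, ...) standardGeneric("valenceGroup"))

#' @rdname accessors
#' @export
setGeneric("diceMatrix", function(object, ...) standardGeneric("diceMatrix"))
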