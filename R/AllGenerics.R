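#' @importFrom BiocGenerics sizeFactors
NULL

#' @export
setGeneric("rpkm", function(object, ...) standardGeneric("rpkm"))

#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))

#' @export
setGeneric("layerType", function(object) standardGeneric("layerType"))

#' @export
setGeneric("studyLayer",
           function(object, layer, compartment = NULL, ageGroup = NULL)
               standardGeneric("studyLayer"))

#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))

#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @export
setGeneric("minSize", function(object) standardGeneric("minSize"))
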