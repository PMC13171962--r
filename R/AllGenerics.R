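#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' @export
setGeneric("sampleSex", function(x) standardGeneric("sampleSex"))

#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @export
setGeneric("readFate", function(x) standardGeneric("readFate"))

#' @export
setGeneric("readLengths", function(x) standardGeneric("readLengths"))

#' @export
setGeneric("meanQ", function(x) standardGeneric("meanQ"))

#' @export
setGeneric("endReason", function(x) standardGeneric("endReason"))

#' @export
setGeneric("readIDs", function(x) standardGeneric("readIDs"))

#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("readClass", function(x) standardGeneric("readClass"))

#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))

#' @export
setGeneric("referenceDepth", function(x) standardGeneric("referenceDepth"))

#' @export
setGeneric("junctionTable", function(x) standardGeneric("junctionTable"))

#' @export
setGeneric("junctionSupport", function(x) standardGeneric("junctionSupport"))

#' @export
setGeneric("graphSegments", function(x) standardGeneric("graphSegments"))

#' @export
setGeneric("graphJunctions", function(x) standardGeneric("graphJunctions"))

#' @export
setGeneric("truthSVs", function(x) standardGeneric("truthSVs"))

#' @export
setGeneric("truthFates", function(x) standardGeneric("truthFates"))

#' @export
setGeneric("truthJunctions", function(x) standardGeneric("truthJunctions"))

#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))
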