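#' @export
setGeneric("shiftGHz", function(x) standardGeneric("shiftGHz"))
#' @export
setGeneric("fwhmGHz", function(x) standardGeneric("fwhmGHz"))
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @export
setGeneric("frequencyAxis", function(x) standardGeneric("frequencyAxis"))
#' @export
setGeneric("gainValues", function(x) standardGeneric("gainValues"))
#' @export
setGeneric("dcLevel", function(x) standardGeneric("dcLevel"))
#' @export
setGeneric("integrationTimeMs", function(x) standardGeneric("integrationTimeMs"))
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))
#' @export
setGeneric("pixelMask", function(x) standardGeneric("pixelMask"))
#' @export
setGeneric("dutyCycle", function(x, ...) standardGeneric("dutyCycle"))
#' @export
setGeneric("enhancementFactor", function(x, ...) standardGeneric("enhancementFactor"))
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))
#' @export
setGeneric("residualRms", function(x) standardGeneric("residualRms"))
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
#' @export
setGeneric("classificationLabel", function(x) standardGeneric("classificationLabel"))
#' @export
setGeneric("multiPeakMetric", function(x) standardGeneric("multiPeakMetric"))
#' @export
setGeneric("brillouinMap", function(x, which, ...) standardGeneric("brillouinMap"))
#' @export
setGeneric("correctLineShift", function(x, ...) standardGeneric("correctLineShift"))
#' @export
setGeneric("storagePa", function(x) standardGeneric("storagePa"))
#' @export
setGeneric("lossPa", function(x) standardGeneric("lossPa"))
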