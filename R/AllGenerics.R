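#' @name phantoMAR-accessors
#' @title Accessors for phantoMAR S4 objects
#' @param x an object.
#' @description Accessor generics for the image, sinogram and study classes:
#'   pixel data, pixel spacing, condition labels, provenance, projection
#'   angles, metal trace/path, study images and ground-truth labels.
NULL

#' @rdname phantoMAR-accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("projectionAngles", function(x) standardGeneric("projectionAngles"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("metalTrace", function(x) standardGeneric("metalTrace"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("metalPath", function(x) standardGeneric("metalPath"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("studyImages", function(x) standardGeneric("studyImages"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("relativeMARPct", function(x) standardGeneric("relativeMARPct"))
#' @rdname phantoMAR-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setMethod("pixels", "SliceImage", function(x) x@pixels)
#' @export
setMethod("pixelSpacing", "SliceImage", function(x) x@pixelSpacing)
#' @export
setMethod("condition", "SliceImage", function(x) x@condition)
#' @export
setMethod("provenance", "SliceImage", function(x) x@provenance)
#' @export
setMethod("sinogramValues", "Sinogram", function(x) x@values)
#' @export
setMethod("projectionAngles", "Sinogram", function(x) x@angles)
#' @export
setMethod("metalPath", "Sinogram", function(x) x@metalPath)
#' @export
setMethod("metalTrace", "Sinogram", function(x) x@metalPath > x@traceThresholdMM)
#' @export
setMethod("studyImages", "PhantomStudy", function(x) x@images)
#' @export
setMethod("groundTruth", "PhantomStudy", function(x) x@groundTruth)
#' @export
setMethod("roiTable", "ROITemplate", function(x) x@rois)
#' @export
setMethod("relativeMARPct", "MARComparison", function(x) x@relativeMARPct)
#' @export
setMethod("pValue", "MARComparison", function(x) x@pValue)

#' @rdname rasterizePhantom
#' @export
setGeneric("rasterizePhantom", function(spec, reconstruction = "conventional")
    standardGeneric("rasterizePhantom"))

#' @rdname forwardProject
#' @export
setGeneric("forwardProject", function(image, nAngles = 360L, nBins = NULL, ...)
    standardGeneric("forwardProject"))

#' @rdname reconstructFBP
#' @export
setGeneric("reconstructFBP", function(sino, ...)
    standardGeneric("reconstructFBP"))

#' @rdname corruptSinogram
#' @export
setGeneric("corruptSinogram", function(sino, severity, seed = 1L, ...)
    standardGeneric("corruptSinogram"))

#' @rdname applyOMAREmulation
#' @export
setGeneric("applyOMAREmulation", function(sino, ...)
    standardGeneric("applyOMAREmulation"))

#' @rdname vmiBrightStreaks
#' @export
setGeneric("vmiBrightStreaks", function(sino, gamma, every = 6L)
    standardGeneric("vmiBrightStreaks"))

#' @rdname measureROIs
#' @export
setGeneric("measureROIs", function(image, template,
                                   sdMode = c("population", "sample"))
    standardGeneric("measureROIs"))
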