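## Accessors ------------------------------------------------------------

#' Accessors for the imaging containers
#'
#' Small accessor family avoiding direct slot access: acquisition times,
#' signal/concentration arrays, the fitted Patlak maps and the vascular
#' input function components.
#'
#' @param x an object of the documented class.
#' @return The requested component (numeric vector or array).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("acquisitionTimes", function(x) standardGeneric("acquisitionTimes"))

#' @rdname accessors
#' @export
setMethod("acquisitionTimes", "DynamicSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("acquisitionTimes", "ConcentrationSeries", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("acquisitionTimes", "VascularInputFunction", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setMethod("signalData", "DynamicSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("concData", function(x) standardGeneric("concData"))

#' @rdname accessors
#' @export
setMethod("concData", "ConcentrationSeries", function(x) x@conc)

#' @rdname accessors
#' @export
setGeneric("kiArray", function(x) standardGeneric("kiArray"))

#' @rdname accessors
#' @export
setMethod("kiArray", "KiMap", function(x) x@ki)

#' @rdname accessors
#' @export
setGeneric("vpArray", function(x) standardGeneric("vpArray"))

#' @rdname accessors
#' @export
setMethod("vpArray", "KiMap", function(x) x@vp)

#' @rdname accessors
#' @export
setGeneric("r2Array", function(x) standardGeneric("r2Array"))

#' @rdname accessors
#' @export
setMethod("r2Array", "KiMap", function(x) x@r2)

#' @rdname accessors
#' @export
setGeneric("plasmaCurve", function(x) standardGeneric("plasmaCurve"))

#' @rdname accessors
#' @export
setMethod("plasmaCurve", "VascularInputFunction", function(x) x@cp)

#' @rdname accessors
#' @export
setGeneric("bloodCurve", function(x) standardGeneric("bloodCurve"))

#' @rdname accessors
#' @export
setMethod("bloodCurve", "VascularInputFunction", function(x) x@cb)

#' @rdname accessors
#' @export
setGeneric("plasmaIntegral", function(x) standardGeneric("plasmaIntegral"))

#' @rdname accessors
#' @export
setMethod("plasmaIntegral", "VascularInputFunction", function(x) x@integral)

#' @rdname accessors
#' @export
setGeneric("leakageVolume", function(x) standardGeneric("leakageVolume"))

#' @rdname accessors
#' @export
setMethod("leakageVolume", "LeakageMeasures", function(x) x@vL)

#' @rdname accessors
#' @export
setGeneric("meanKi", function(x) standardGeneric("meanKi"))

#' @rdname accessors
#' @export
setMethod("meanKi", "LeakageMeasures", function(x) x@meanKi)
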