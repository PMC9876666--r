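#' Accessors for MVDF objects
#'
#' Small generic accessors used across the package's S4 classes.
#'
#' @param object an object of one of the package's S4 classes.
#' @return The corresponding component; see the class documentation.
#' @name mvdf-accessors
NULL

#' @rdname mvdf-accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' @rdname mvdf-accessors
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))

#' @rdname mvdf-accessors
#' @export
setGeneric("viewOf", function(object) standardGeneric("viewOf"))

#' @rdname mvdf-accessors
#' @export
setGeneric("viewNames", function(object) standardGeneric("viewNames"))

#' @rdname mvdf-accessors
#' @export
setGeneric("nViews", function(object) standardGeneric("nViews"))

#' @rdname mvdf-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname mvdf-accessors
#' @export
setGeneric("nIndicators", function(object) standardGeneric("nIndicators"))

#' @rdname mvdf-accessors
#' @export
setGeneric("indicatorNames", function(object) {
  standardGeneric("indicatorNames")
})

#' @rdname mvdf-accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname mvdf-accessors
#' @export
setGeneric("labelLevels", function(object) standardGeneric("labelLevels"))

#' @rdname mvdf-accessors
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))
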