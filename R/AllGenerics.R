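#' @name cliMargin-generics
#' @title Accessor generics
#' @description Accessor generics for the CLI data classes.
#' @param object an object of one of the package's classes
#' @keywords internal
NULL

#' @rdname cliMargin-generics
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname cliMargin-generics
#' @export
setGeneric("radianceValues", function(object) standardGeneric("radianceValues"))

#' @rdname cliMargin-generics
#' @export
setGeneric("acqSettings", function(object) standardGeneric("acqSettings"))

#' @rdname cliMargin-generics
#' @export
setGeneric("exposureTime", function(object) standardGeneric("exposureTime"))

#' @rdname cliMargin-generics
#' @export
setGeneric("binningFactor", function(object) standardGeneric("binningFactor"))

#' @rdname cliMargin-generics
#' @export
setGeneric("opticalFilter", function(object) standardGeneric("opticalFilter"))

#' @rdname cliMargin-generics
#' @export
setGeneric("acquisitionTime", function(object) standardGeneric("acquisitionTime"))

#' @rdname cliMargin-generics
#' @export
setGeneric("frameKind", function(object) standardGeneric("frameKind"))

#' @rdname cliMargin-generics
#' @export
setGeneric("viewLabel", function(object) standardGeneric("viewLabel"))

#' @rdname cliMargin-generics
#' @export
setGeneric("processingHistory",
           function(object) standardGeneric("processingHistory"))

#' @rdname cliMargin-generics
#' @export
setGeneric("frameMeta", function(object) standardGeneric("frameMeta"))

#' @rdname cliMargin-generics
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname cliMargin-generics
#' @export
setGeneric("hotspots", function(object) standardGeneric("hotspots"))

#' @rdname cliMargin-generics
#' @export
setGeneric("isPersistent", function(object) standardGeneric("isPersistent"))

#' @rdname cliMargin-generics
#' @export
setGeneric("roiPixels", function(object) standardGeneric("roiPixels"))

#' @rdname cliMargin-generics
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname cliMargin-generics
#' @export
setGeneric("studyManifest", function(object) standardGeneric("studyManifest"))
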