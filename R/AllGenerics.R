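#' @rdname GeneticMap-accessors
#' @export
setGeneric("mapId", function(x) standardGeneric("mapId"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname mapDensity
#' @export
setGeneric("mapLength", function(x) standardGeneric("mapLength"))

#' @rdname mapDensity
#' @export
setGeneric("mapDensity", function(x) standardGeneric("mapDensity"))
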