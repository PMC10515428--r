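#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Slot access in
#' user code should always go through these.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("acquisitionTimes", function(x) standardGeneric("acquisitionTimes"))

#' @rdname accessors
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname accessors
#' @export
setGeneric("seriesArray", function(x) standardGeneric("seriesArray"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("dynMap", function(x) standardGeneric("dynMap"))

#' @rdname accessors
#' @export
setGeneric("ttMap", function(x) standardGeneric("ttMap"))

#' @rdname accessors
#' @export
setGeneric("aotMap", function(x) standardGeneric("aotMap"))

#' @rdname accessors
#' @export
setGeneric("r2Map", function(x) standardGeneric("r2Map"))

#' @rdname accessors
#' @export
setGeneric("fittedMask", function(x) standardGeneric("fittedMask"))

#' @rdname accessors
#' @export
setGeneric("bbboMask", function(x) standardGeneric("bbboMask"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("volumeMm3", function(x) standardGeneric("volumeMm3"))

#' @rdname accessors
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
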