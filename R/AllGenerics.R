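#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the container classes. Each has methods
#' documented with the corresponding class.
#'
#' @param x an object.
#' @param ... additional arguments for methods.
#' @return The slot contents; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("stackMetadata", function(x) standardGeneric("stackMetadata"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("aDonor", function(x) standardGeneric("aDonor"))

#' @rdname accessors
#' @export
setGeneric("bAcceptor", function(x) standardGeneric("bAcceptor"))

#' @rdname accessors
#' @export
setGeneric("fretn", function(x) standardGeneric("fretn"))

#' @rdname accessors
#' @export
setGeneric("isIncluded", function(x) standardGeneric("isIncluded"))

#' @rdname accessors
#' @export
setGeneric("bindingPoints", function(x) standardGeneric("bindingPoints"))

#' @rdname accessors
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))

#' @rdname accessors
#' @export
setGeneric("bmax", function(x) standardGeneric("bmax"))

#' @rdname accessors
#' @export
setGeneric("spotCounts", function(x) standardGeneric("spotCounts"))

#' @rdname accessors
#' @export
setGeneric("percentOfMax", function(x) standardGeneric("percentOfMax"))

#' @rdname accessors
#' @export
setGeneric("persistentFraction", function(x) standardGeneric("persistentFraction"))

#' @rdname accessors
#' @export
setGeneric("endocytosisIndex", function(x) standardGeneric("endocytosisIndex"))
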