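#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("pH", function(x) standardGeneric("pH"))

#' @export
setGeneric("isBound", function(x) standardGeneric("isBound"))

#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @export
setGeneric("hillFit", function(x, ...) standardGeneric("hillFit"))
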