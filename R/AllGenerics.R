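#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Use these rather
#' than reaching into slots.
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flyId", function(x) standardGeneric("flyId"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("arena", function(x) standardGeneric("arena"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("turnLabels", function(x) standardGeneric("turnLabels"))

#' @rdname accessors
#' @export
setGeneric("runEpisodes", function(x) standardGeneric("runEpisodes"))

#' @rdname accessors
#' @export
setGeneric("stopEpisodes", function(x) standardGeneric("stopEpisodes"))

#' @rdname accessors
#' @export
setGeneric("sharpTurnEvents", function(x) standardGeneric("sharpTurnEvents"))

#' @rdname accessors
#' @export
setGeneric("epochInterval",
           function(x, which = c("before", "during", "after"))
             standardGeneric("epochInterval"))

#' @rdname accessors
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))

#' @rdname accessors
#' @export
setGeneric("canonicalAxes", function(x) standardGeneric("canonicalAxes"))

#' @rdname accessors
#' @export
setGeneric("canonicalProjections",
           function(x) standardGeneric("canonicalProjections"))

#' @rdname accessors
#' @export
setGeneric("groupDistance", function(x) standardGeneric("groupDistance"))

#' @rdname accessors
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))
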