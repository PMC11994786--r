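#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the design, contrast and interactome
#' classes. Each has a method on the class that owns the slot; none of them
#' exposes slots directly.
#'
#' @param x an object
#' @param object an object
#' @return the slot value (see the class documentation)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCouples", function(x) standardGeneric("nCouples"))

#' @rdname accessors
#' @export
setGeneric("replicatesPerArm", function(x) standardGeneric("replicatesPerArm"))

#' @rdname accessors
#' @export
setGeneric("arms", function(x) standardGeneric("arms"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("tagOf", function(x) standardGeneric("tagOf"))

#' @rdname accessors
#' @export
setGeneric("caseGroup", function(x) standardGeneric("caseGroup"))

#' @rdname accessors
#' @export
setGeneric("controlGroups", function(x) standardGeneric("controlGroups"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
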