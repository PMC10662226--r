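## Generics for accessor functions. Slot access from user code is never
## needed; these are the supported surface.

#' @rdname accessors
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' @rdname accessors
#' @export
setGeneric("treatmentOf", function(x) standardGeneric("treatmentOf"))

#' @rdname accessors
#' @export
setGeneric("timeOfDayOf", function(x) standardGeneric("timeOfDayOf"))

#' @rdname accessors
#' @export
setGeneric("replicateIdOf", function(x) standardGeneric("replicateIdOf"))

#' @rdname accessors
#' @export
setGeneric("aciPoints", function(x) standardGeneric("aciPoints"))

#' @rdname accessors
#' @export
setGeneric("pulses", function(x) standardGeneric("pulses"))

#' @rdname accessors
#' @export
setGeneric("kmOf", function(x) standardGeneric("kmOf"))

#' @rdname accessors
#' @export
setGeneric("fitCoefs", function(x) standardGeneric("fitCoefs"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
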