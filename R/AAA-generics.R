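#' @export
setGeneric("smorfRanges", function(x) standardGeneric("smorfRanges"))

#' @export
setGeneric("ntSeq", function(x) standardGeneric("ntSeq"))

#' @export
setGeneric("aaSeq", function(x) standardGeneric("aaSeq"))

#' @export
setGeneric("smorfIds", function(x) standardGeneric("smorfIds"))

#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @export
setGeneric("lengthNt", function(x) standardGeneric("lengthNt"))

#' @export
setGeneric("lengthAa", function(x) standardGeneric("lengthAa"))

#' @export
setGeneric("frameOf", function(x) standardGeneric("frameOf"))
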