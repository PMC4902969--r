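#' @rdname GeneTable-class
#' @param x a `GeneTable`
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname GeneTable-class
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' @rdname GeneTable-class
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname OrthologMap-class
#' @param x an `OrthologMap`
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))

#' @rdname SuperScaffoldSet-class
#' @param x a `SuperScaffoldSet`
#' @export
setGeneric("superscaffoldMembers", function(x) standardGeneric("superscaffoldMembers"))

#' @rdname SuperScaffoldSet-class
#' @export
setGeneric("superscaffoldJoins", function(x) standardGeneric("superscaffoldJoins"))
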