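#' Accessors for transcript models and units
#'
#' @param x A `TranscriptSet`, `TranscriptUnits` or `StageExpression` object.
#' @param ... Unused.
#' @return `txIds`: character vector of transcript ids. `txExons`: the exon
#'   `GRangesList`. `txSpans`: a `GRanges` of transcript spans (first exon
#'   start to last exon end) with metadata columns `tx_id` and `origin`.
#'   `txOrigin`: `"predicted_gene"`/`"assembled"` per model. `txLengths`:
#'   named integer vector of spliced lengths. `unitIds`, `unitSpans`,
#'   `unitMembers`, `containsGene`: the corresponding unit columns.
#'   `exprValues`, `stages`, `exprUnit`: the expression matrix, its stage
#'   labels, and its unit.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("txIds", function(x, ...) standardGeneric("txIds"))
#' @rdname accessors
#' @export
setGeneric("txExons", function(x, ...) standardGeneric("txExons"))
#' @rdname accessors
#' @export
setGeneric("txSpans", function(x, ...) standardGeneric("txSpans"))
#' @rdname accessors
#' @export
setGeneric("txOrigin", function(x, ...) standardGeneric("txOrigin"))
#' @rdname accessors
#' @export
setGeneric("txLengths", function(x, ...) standardGeneric("txLengths"))
#' @rdname accessors
#' @export
setGeneric("unitIds", function(x, ...) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setGeneric("unitSpans", function(x, ...) standardGeneric("unitSpans"))
#' @rdname accessors
#' @export
setGeneric("unitMembers", function(x, ...) standardGeneric("unitMembers"))
#' @rdname accessors
#' @export
setGeneric("containsGene", function(x, ...) standardGeneric("containsGene"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("stages", function(x, ...) standardGeneric("stages"))
#' @rdname accessors
#' @export
setGeneric("exprUnit", function(x, ...) standardGeneric("exprUnit"))
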