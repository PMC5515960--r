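#' Construct a TranscriptSet from an exon list
#'
#' @param exons A named `GRangesList` (or list of `GRanges`) of exons, one
#'   element per transcript. Exons are canonicalized: sorted by start.
#' @param origin `"predicted_gene"` or `"assembled"`, recycled to length.
#' @return A [TranscriptSet-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("scaf1", IRanges::IRanges(101, 200), strand = "+"))
#' TranscriptSet(ex, origin = "assembled")
#' @export
TranscriptSet <- function(exons, origin) {
  if (!methods::is(exons, "GRangesList"))
    exons <- GenomicRanges::GRangesList(exons)
  if (length(exons)) {
    o <- S4Vectors::endoapply(exons, function(g) g[order(start(g))])
    exons <- o
  }
  origin <- rep_len(origin, length(exons))
  methods::new("TranscriptSet", exons = exons, origin = origin)
}

#' @rdname accessors
setMethod("txIds", "TranscriptSet", function(x, ...) names(x@exons))

#' @rdname accessors
setMethod("txExons", "TranscriptSet", function(x, ...) x@exons)

#' @rdname accessors
setMethod("txOrigin", "TranscriptSet", function(x, ...)
  stats::setNames(x@origin, names(x@exons)))

#' @rdname accessors
setMethod("txSpans", "TranscriptSet", function(x, ...) {
  if (!length(x@exons)) {
    gr <- GRanges()
    mcols(gr)$tx_id <- character(0)
    mcols(gr)$origin <- character(0)
    return(gr)
  }
  gr <- unlist(range(x@exons), use.names = FALSE)
  mcols(gr)$tx_id <- names(x@exons)
  mcols(gr)$origin <- x@origin
  names(gr) <- names(x@exons)
  gr
})

#' @rdname accessors
setMethod("txLengths", "TranscriptSet", function(x, ...) {
  stats::setNames(as.integer(sum(width(x@exons))), names(x@exons))
})

#' @describeIn TranscriptSet Number of transcript models.
#' @param x A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @describeIn TranscriptSet Subset by index, logical vector or transcript id.
#' @param i Index.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  methods::new("TranscriptSet", exons = x@exons[i], origin = x@origin[i])
})

#' Combine transcript sets
#'
#' @param x,... `TranscriptSet` objects.
#' @return A single `TranscriptSet`; ids must remain unique.
#' @export
setMethod("c", "TranscriptSet", function(x, ...) {
  xs <- c(list(x), list(...))
  ex <- do.call(c, lapply(xs, txExons))
  methods::new("TranscriptSet", exons = ex,
               origin = unlist(lapply(xs, function(z) z@origin), use.names = FALSE))
})

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object)
  tab <- table(factor(object@origin, levels = c("predicted_gene", "assembled")))
  cat("TranscriptSet with", n, "models (",
      tab[["predicted_gene"]], "predicted genes,",
      tab[["assembled"]], "assembled ) on",
      length(unique(as.character(GenomicRanges::seqnames(txSpans(object))))),
      "scaffold(s)\n")
})

#' @rdname accessors
setMethod("unitIds", "TranscriptUnits", function(x, ...) mcols(x@span)$unit_id)

#' @rdname accessors
setMethod("unitSpans", "TranscriptUnits", function(x, ...) x@span)

#' @rdname accessors
setMethod("unitMembers", "TranscriptUnits", function(x, ...)
  stats::setNames(mcols(x@span)$members, mcols(x@span)$unit_id))

#' @rdname accessors
setMethod("containsGene", "TranscriptUnits", function(x, ...)
  stats::setNames(mcols(x@span)$contains_gene, mcols(x@span)$unit_id))

#' @describeIn TranscriptUnits Number of transcript units.
#' @param x A `TranscriptUnits`.
#' @export
setMethod("length", "TranscriptUnits", function(x) length(x@span))

setMethod("show", "TranscriptUnits", function(object) {
  cat("TranscriptUnits:", length(object@span), "units,",
      sum(mcols(object@span)$n_members), "member models,",
      sum(mcols(object@span)$contains_gene), "unit(s) containing a predicted gene\n")
})

#' @rdname accessors
setMethod("exprValues", "StageExpression", function(x, ...) x@values)

#' @rdname accessors
setMethod("stages", "StageExpression", function(x, ...) colnames(x@values))

#' @rdname accessors
setMethod("exprUnit", "StageExpression", function(x, ...) x@unit)

#' @describeIn StageExpression Number of transcript rows.
#' @param x A `StageExpression`.
#' @export
setMethod("nrow", "StageExpression", function(x) nrow(x@values))

setMethod("show", "StageExpression", function(object) {
  cat("StageExpression:", nrow(object@values), "transcripts x",
      ncol(object@values), "stages (", paste(colnames(object@values), collapse = ", "),
      ") in", object@unit, "\n")
})

#' Construct a StageExpression matrix
#'
#' @param values Non-negative numeric matrix with transcript row names and
#'   stage column names.
#' @param unit `"RPKM"` or `"raw_count"`.
#' @return A [StageExpression-class] object.
#' @export
StageExpression <- function(values, unit = c("RPKM", "raw_count")) {
  unit <- match.arg(unit)
  methods::new("StageExpression", values = values, unit = unit)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (sl in methods::slotNames(object))
    cat(sprintf("  %-24s %s\n", sl, format(methods::slot(object, sl))))
})

setMethod("show", "SyntheticFixture", function(object) {
  cat("SyntheticFixture (seed ", object@seed, ") in ", object@dir, "\n", sep = "")
  cat("  files:", paste(names(object@files), collapse = ", "), "\n")
  cat("  planted:", nrow(object@truth$cis), "cis pairs,",
      nrow(object@truth$trans), "trans pairs,",
      sum(object@truth$candidates$is_decoy), "decoys\n")
})

#' Pipeline configuration constructor
#'
#' @param ... Named overrides of [PipelineConfig-class] slots, e.g.
#'   `natConfig(overlap_rule = "both", rpkm_cutoff = 1)`.
#' @return A validated `PipelineConfig`.
#' @examples
#' natConfig()
#' natConfig(cis_overlap_frac = 0.2, seed = 7L)
#' @export
natConfig <- function(...) {
  args <- list(...)
  if ("seed" %in% names(args)) args$seed <- as.integer(args$seed)
  do.call(methods::new, c(list(Class = "PipelineConfig"), args))
}

#' Serialize a PipelineConfig to a named list
#'
#' Used to echo the configuration into every run's provenance record.
#'
#' @param config A `PipelineConfig`.
#' @return A named list of slot values.
#' @export
configAsList <- function(config) {
  stopifnot(methods::is(config, "PipelineConfig"))
  sl <- methods::slotNames(config)
  stats::setNames(lapply(sl, function(s) methods::slot(config, s)), sl)
}
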