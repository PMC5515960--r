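#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle
#' @importFrom IRanges IRanges ranges width start end
#' @import GenomicRanges
NULL

#' TranscriptSet: a collection of stranded, exon-structured transcript models
#'
#' Holds gene models (from GFF3) and/or assembled transcripts (from GTF) as a
#' named [GenomicRanges::GRangesList] of exons, one element per transcript.
#' All exons of one transcript share a scaffold and strand; exons are stored
#' sorted by start and must not overlap one another.
#'
#' @slot exons A named `GRangesList`, one element per transcript model.
#' @slot origin Character vector parallel to `exons`; each element is
#'   `"predicted_gene"` or `"assembled"`.
#'
#' @seealso [readGeneModels()], [readAssembledTranscripts()],
#'   [buildTranscriptUnits()]
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", origin = "character"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  msgs <- character()
  if (length(ex) && (is.null(names(ex)) || anyDuplicated(names(ex)) ||
                     any(!nzchar(names(ex)))))
    msgs <- c(msgs, "transcript ids must be unique and non-empty")
  if (length(object@origin) != length(ex))
    msgs <- c(msgs, "'origin' must be parallel to 'exons'")
  if (length(object@origin) && !all(object@origin %in% c("predicted_gene", "assembled")))
    msgs <- c(msgs, "origin must be 'predicted_gene' or 'assembled'")
  if (length(ex)) {
    u <- unlist(ex, use.names = FALSE)
    if (any(strand(u) == "*"))
      msgs <- c(msgs, "unstranded exons are not allowed")
    nsc <- lengths(unique(GenomicRanges::seqnames(ex)))
    nst <- lengths(unique(strand(ex)))
    if (any(nsc != 1L) || any(nst != 1L))
      msgs <- c(msgs, "exons of one transcript must share scaffold and strand")
    # sorted, non-overlapping exons
    ok <- vapply(seq_along(ex), function(i) {
      s <- start(ex[[i]]); e <- end(ex[[i]])
      !is.unsorted(s, strictly = FALSE) && all(diff(order(s)) == 1L) &&
        (length(s) < 2L || all(s[-1L] > e[-length(e)]))
    }, logical(1))
    if (!all(ok)) msgs <- c(msgs, "exons must be sorted by start and non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' TranscriptUnits: same-strand overlap clusters of transcript models
#'
#' A transcript unit is the union of all genes and assembled transcripts on
#' one scaffold and strand whose spans form a connected overlap component
#' (overlap means at least one shared base; abutting models are not merged).
#' Represented as a `GRanges` of unit spans with metadata columns
#' `unit_id`, `members` (a `CharacterList` of member transcript ids),
#' `n_members`, and `contains_gene`.
#'
#' @slot span A `GRanges` of unit spans with the metadata columns above.
#'
#' @seealso [buildTranscriptUnits()]
#' @export
setClass("TranscriptUnits", representation(span = "GRanges"))

setValidity("TranscriptUnits", function(object) {
  mc <- mcols(object@span)
  need <- c("unit_id", "members", "n_members", "contains_gene")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata columns:", paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (anyDuplicated(mc$unit_id)) return("unit ids must be unique")
  TRUE
})

#' StageExpression: transcript-by-stage abundance matrix
#'
#' @slot values Non-negative numeric matrix; rows are transcript ids, columns
#'   are ordered stage labels (canonically M, P, FB for mycelia, primordia
#'   and fruiting bodies).
#' @slot unit `"RPKM"` or `"raw_count"`.
#'
#' @seealso [readExpression()], [vennPartition()]
#' @export
setClass("StageExpression",
  representation(values = "matrix", unit = "character"))

setValidity("StageExpression", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (anyNA(v)) msgs <- c(msgs, "missing cells are not allowed")
  if (is.numeric(v) && !anyNA(v) && any(v < 0)) msgs <- c(msgs, "negative abundances are not allowed")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "rows must be uniquely named by transcript id")
  if (is.null(colnames(v))) msgs <- c(msgs, "columns must be named by stage")
  if (!identical(length(object@unit), 1L) || !object@unit %in% c("RPKM", "raw_count"))
    msgs <- c(msgs, "unit must be 'RPKM' or 'raw_count'")
  if (length(msgs)) msgs else TRUE
})

#' Result tables
#'
#' Thin [S4Vectors::DFrame] subclasses so pipeline catalogs print and subset
#' like ordinary Bioconductor result tables:
#' * `CisPairs` — one row per cis ST-NAT pair (overlap, fractions, configuration).
#' * `TransPairs` — one row per trans ST-NAT pair (complementary region, coverage, duplex).
#' * `NatRecords` — one row per candidate with its five-step filter trail.
#' * `EnrichmentResults` — one row per functional category with hypergeometric
#'   p and BH q.
#'
#' @name result-tables
#' @aliases CisPairs-class TransPairs-class NatRecords-class EnrichmentResults-class
#' @export
setClass("CisPairs", contains = "DFrame")

#' @rdname result-tables
#' @export
setClass("TransPairs", contains = "DFrame")

#' @rdname result-tables
#' @export
setClass("NatRecords", contains = "DFrame")

#' @rdname result-tables
#' @export
setClass("EnrichmentResults", contains = "DFrame")

#' PipelineConfig: every tunable threshold of the NAT pipeline
#'
#' Defaults are the pipeline's published operating point: cis admission at an
#' overlap of at least 10 percent of either transcript; trans admission at a
#' continuous complementary region longer than 100 nt covering more than 50
#' percent of either transcript with duplex bubbles no longer than 10 percent
#' of the annealed region; the non-coding cascade keeps transcripts longer
#' than 200 nt, with at most 100 aa of open reading frame, no protein hit at
#' e-value <= 1e-3, coding-potential score < 0, and no housekeeping/small-RNA
#' hit at e-value <= 1e-10; stage presence at RPKM >= 2.
#'
#' @slot cis_overlap_frac Minimum overlap fraction for cis admission (0.10).
#' @slot overlap_rule `"any"` (>= 10 percent of at least one transcript) or
#'   `"both"`.
#' @slot trans_min_complement_nt Complementary region must be longer than
#'   this many nt (100).
#' @slot trans_coverage_frac High-coverage threshold (0.50, strict >).
#' @slot coverage_rule `"any"` or `"both"`.
#' @slot bubble_max_frac Maximum bubble length as a fraction of the annealed
#'   region (0.10).
#' @slot min_length_nt Non-coding cascade step 1: keep if longer than this (200).
#' @slot max_orf_aa Step 2: keep if the longest ORF is at most this (100).
#' @slot nr_evalue_cutoff Step 3: a protein hit at e-value <= cutoff removes (1e-3).
#' @slot cpc_keep_below Step 4: keep if coding-potential score is strictly
#'   below this (0).
#' @slot ncrna_evalue_cutoff Step 5: a housekeeping/small-RNA hit at e-value
#'   <= cutoff removes (1e-10).
#' @slot rpkm_cutoff Stage-presence cutoff, inclusive (2).
#' @slot min_mapped_for_report Enrichment report filter: minimum mapped STs (4).
#' @slot seed Integer seed echoed into run provenance.
#'
#' @seealso [natConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
  representation(
    cis_overlap_frac = "numeric", overlap_rule = "character",
    trans_min_complement_nt = "numeric", trans_coverage_frac = "numeric",
    coverage_rule = "character", bubble_max_frac = "numeric",
    min_length_nt = "numeric", max_orf_aa = "numeric",
    nr_evalue_cutoff = "numeric", cpc_keep_below = "numeric",
    ncrna_evalue_cutoff = "numeric", rpkm_cutoff = "numeric",
    min_mapped_for_report = "numeric", seed = "integer"),
  prototype(
    cis_overlap_frac = 0.10, overlap_rule = "any",
    trans_min_complement_nt = 100, trans_coverage_frac = 0.50,
    coverage_rule = "any", bubble_max_frac = 0.10,
    min_length_nt = 200, max_orf_aa = 100,
    nr_evalue_cutoff = 1e-3, cpc_keep_below = 0,
    ncrna_evalue_cutoff = 1e-10, rpkm_cutoff = 2.0,
    min_mapped_for_report = 4, seed = 1L))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  fr <- c(cis_overlap_frac = object@cis_overlap_frac,
          trans_coverage_frac = object@trans_coverage_frac,
          bubble_max_frac = object@bubble_max_frac)
  if (any(fr <= 0 | fr > 1))
    msgs <- c(msgs, "fractions must lie in (0, 1]")
  pos <- c(object@trans_min_complement_nt, object@min_length_nt, object@max_orf_aa,
           object@nr_evalue_cutoff, object@ncrna_evalue_cutoff, object@rpkm_cutoff,
           object@min_mapped_for_report)
  if (any(pos <= 0)) msgs <- c(msgs, "cutoffs must be positive")
  if (!object@overlap_rule %in% c("any", "both")) msgs <- c(msgs, "overlap_rule must be 'any' or 'both'")
  if (!object@coverage_rule %in% c("any", "both")) msgs <- c(msgs, "coverage_rule must be 'any' or 'both'")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticFixture: a seeded fixture bundle with planted ground truth
#'
#' Produced by [generateFixture()]. `files` names the emitted FASTA, GFF3,
#' GTF and TSV files; `truth` records what was planted (cis pairs with their
#' configurations and overlap fractions, trans pairs with region design,
#' decoys with the single criterion each violates, stage-presence classes,
#' correlation signs, and the deliberately over-represented annotation term)
#' so every pipeline stage can be scored against it.
#'
#' @slot dir Directory holding the fixture files.
#' @slot files Named character vector of file paths.
#' @slot truth Named list of planted-truth tables (see [generateFixture()]).
#' @slot seed Integer seed the bundle was generated from.
#'
#' @export
setClass("SyntheticFixture",
  representation(dir = "character", files = "character",
                 truth = "list", seed = "integer"))
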