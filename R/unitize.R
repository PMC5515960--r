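#' Cluster gene models and transcripts into transcript units
#'
#' A transcript unit is the combination of all overlapping transcripts and
#' genes on the same strand: two models fall in one unit iff they are
#' connected by a chain of same-scaffold, same-strand span overlaps sharing
#' at least one base. Abutting spans (no shared base) are not merged, and
#' opposite strands never merge. Units partition the input; ids are assigned
#' deterministically in (scaffold, start, strand) order as `TUnnnnnn`.
#'
#' Overlap is evaluated on transcript spans (first to last exon), not exon
#' chains: an intron-only overlap still marks a single locus.
#'
#' @param models A [TranscriptSet-class] of gene models and/or assembled
#'   transcripts (combine with [c()]).
#' @return A [TranscriptUnits-class] object. `contains_gene` is `TRUE` for
#'   units with at least one `predicted_gene` member.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   g1 = GenomicRanges::GRanges("s1", IRanges::IRanges(1, 100), strand = "+"),
#'   t1 = GenomicRanges::GRanges("s1", IRanges::IRanges(51, 150), strand = "+"),
#'   t2 = GenomicRanges::GRanges("s1", IRanges::IRanges(60, 140), strand = "-"))
#' ts <- TranscriptSet(ex, origin = c("predicted_gene", "assembled", "assembled"))
#' buildTranscriptUnits(ts)  # 2 units: the two + models merge, - stays apart
#' @export
buildTranscriptUnits <- function(models) {
  stopifnot(methods::is(models, "TranscriptSet"))
  spans <- txSpans(models)
  if (!length(spans)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(unit_id = character(0),
                           members = IRanges::CharacterList(),
                           n_members = integer(0),
                           contains_gene = logical(0))
    return(methods::new("TranscriptUnits", span = gr))
  }
  # connected overlap components per (scaffold, strand); min.gapwidth = 0
  # keeps abutting spans apart (merging requires >= 1 shared base)
  comp <- GenomicRanges::reduce(spans, min.gapwidth = 0L, ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(spans, comp, minoverlap = 1L,
                                      ignore.strand = FALSE)
  stopifnot(length(hits) == length(spans))  # partition property
  grp <- S4Vectors::subjectHits(hits)

  ord <- order(as.character(GenomicRanges::seqnames(comp)), start(comp),
               as.character(strand(comp)))
  comp <- comp[ord]
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  grp <- rank[grp]

  grp <- factor(grp, levels = seq_along(comp))
  members <- split(mcols(spans)$tx_id, grp)
  origin <- split(mcols(spans)$origin, grp)
  out <- comp
  mcols(out) <- DataFrame(
    unit_id = sprintf("TU%06d", seq_along(comp)),
    members = IRanges::CharacterList(lapply(members, unname)),
    n_members = unname(lengths(members)),
    contains_gene = unname(vapply(origin, function(o)
      any(o == "predicted_gene"), logical(1))))
  methods::new("TranscriptUnits", span = out)
}

#' Map each model to its transcript unit
#'
#' @param models A `TranscriptSet`.
#' @param units `TranscriptUnits` built from (a superset of) the models.
#' @return Named character vector: transcript id -> unit id.
#' @export
unitOf <- function(models, units) {
  spans <- txSpans(models)
  hits <- GenomicRanges::findOverlaps(spans, unitSpans(units), minoverlap = 1L,
                                      ignore.strand = FALSE)
  out <- rep(NA_character_, length(spans))
  out[S4Vectors::queryHits(hits)] <- unitIds(units)[S4Vectors::subjectHits(hits)]
  stats::setNames(out, mcols(spans)$tx_id)
}
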