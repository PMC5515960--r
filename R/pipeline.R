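#' Length histogram with 100-nt bins
#'
#' Bins transcript lengths as 1-100, 101-200, 201-300, ... (the catalog
#' convention: the shortest admissible NAT bin is 201-300 nt).
#'
#' @param lengths Integer vector of lengths in nt.
#' @return A `data.frame` with columns `bin`, `from`, `to`, `count` covering
#'   the observed range.
#' @export
lengthHistogram <- function(lengths) {
  if (!length(lengths))
    return(data.frame(bin = character(0), from = integer(0), to = integer(0),
                      count = integer(0)))
  hi <- max(lengths)
  breaks <- seq(0L, 100L * ceiling(hi / 100), by = 100L)
  idx <- findInterval(lengths, breaks + 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin = paste0(utils::head(breaks, -1L) + 1L, "-", breaks[-1L]),
             from = utils::head(breaks, -1L) + 1L, to = breaks[-1L],
             count = counts)
}

## Internal: expand unit-level cis pairs to (gene, member transcript) records.
.expandCisPairs <- function(pairs, units, genes, transcripts) {
  gsp <- txSpans(genes); tsp <- txSpans(transcripts)
  mem <- unitMembers(units)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    g <- gsp[mcols(gsp)$tx_id == pairs$st_id[k]]
    for (m in mem[[pairs$nat_id[k]]]) {
      t <- tsp[mcols(tsp)$tx_id == m]
      if (!length(t)) next
      os <- max(start(g), start(t)); oe <- min(end(g), end(t))
      if (oe < os) next
      rows[[length(rows) + 1L]] <- data.frame(
        st_id = pairs$st_id[k], nat_id = m, nat_unit = pairs$nat_id[k],
        scaffold = pairs$scaffold[k],
        st_start = start(g), st_end = end(g),
        st_strand = as.character(strand(g)),
        nat_start = start(t), nat_end = end(t),
        nat_strand = as.character(strand(t)),
        overlap_len = oe - os + 1L,
        frac_of_st = (oe - os + 1L) / width(g),
        frac_of_nat = (oe - os + 1L) / width(t),
        config = classifyCisPair(g, t), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(methods::new("CisPairs", DataFrame(
      st_id = character(0), nat_id = character(0), nat_unit = character(0),
      scaffold = character(0), st_start = integer(0), st_end = integer(0),
      st_strand = character(0), nat_start = integer(0), nat_end = integer(0),
      nat_strand = character(0), overlap_len = integer(0),
      frac_of_st = numeric(0), frac_of_nat = numeric(0), config = character(0))))
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$st_start, out$nat_start), , drop = FALSE]
  rownames(out) <- NULL
  methods::new("CisPairs", as(out, "DFrame"))
}

#' Run the full NAT discovery and characterization pipeline
#'
#' Orchestrates the stages end to end: transcript-unit clustering, cis and
#' trans candidate identification, the five-step non-coding filter, SAT-pair
#' relationship typing, stage-presence Venn partitioning, ST-NAT expression
#' correlation and functional-category enrichment. Every report is written
#' as TSV/BED into `out_dir` alongside a machine-readable `summary.json`
#' echoing the configuration (provenance). Identical inputs and configuration
#' produce byte-identical reports.
#'
#' Cis admission is decided at the transcript-unit level (a unit containing a
#' predicted gene is an ST-side locus and never a NAT candidate); admitted
#' units are then expanded to their member transcripts, which are the units
#' of filtering, expression analysis and the final catalog.
#'
#' @param genome_fa Genome FASTA path.
#' @param genes_gff Predicted gene models, GFF3.
#' @param transcripts_gtf Assembled transcripts, GTF.
#' @param expression_tsv Transcript-by-stage RPKM matrix, TSV (optional).
#' @param evidence_dir Directory of evidence TSVs (optional; see
#'   [readEvidenceTables()]).
#' @param annotation_tsv Gene-to-term annotation map, TSV with columns
#'   `gene_id`, `term_id`, `term_name` (optional).
#' @param out_dir Report directory, created if needed.
#' @param config A [PipelineConfig-class].
#' @param verbose Emit per-stage record counts (default `TRUE`).
#' @return Invisibly, a list: `units`, `cis_pairs` (transcript-level
#'   catalog), `trans_pairs`, `records` (filter trails), `funnel`,
#'   `final_cis`, `final_trans`, `final_nat_ids`, `relationships`,
#'   `relationship_counts`, `venn`, `correlations`, `config_histogram`,
#'   `length_histogram`, `enrichment`, `summary`.
#' @export
runPipeline <- function(genome_fa, genes_gff, transcripts_gtf,
                        expression_tsv = NULL, evidence_dir = NULL,
                        annotation_tsv = NULL, out_dir,
                        config = natConfig(), verbose = TRUE) {
  stopifnot(methods::is(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[natseek] ", ...)

  genome <- readGenome(genome_fa)
  genes <- readGeneModels(genes_gff)
  txs <- readAssembledTranscripts(transcripts_gtf)
  say(length(genes), " gene models, ", length(txs), " assembled transcripts, ",
      length(genome), " scaffolds")

  units <- buildTranscriptUnits(c(genes, txs))
  say(length(units), " transcript units")

  cis_units <- findCisCandidates(units, genes, min_frac = config@cis_overlap_frac,
                                 overlap_rule = config@overlap_rule)
  cis_pairs <- .expandCisPairs(cis_units, units, genes, txs)
  say(nrow(cis_pairs), " candidate cis pairs (", nrow(cis_units), " unit-level)")

  trans_pairs <- findTransCandidates(genes, txs, genome, config, units = units)
  say(nrow(trans_pairs), " candidate trans pairs")

  cis_ids <- unique(as.character(cis_pairs$nat_id))
  trans_ids <- setdiff(unique(as.character(trans_pairs$nat_id)), cis_ids)
  cand_ids <- c(cis_ids, trans_ids)
  evidence <- if (!is.null(evidence_dir)) readEvidenceTables(evidence_dir)
              else evidenceTables()
  if (length(cand_ids)) {
    seqs <- as.character(extractTranscriptSeq(txs[cand_ids], genome))
    candidates <- data.frame(
      id = cand_ids,
      kind = c(rep("cis", length(cis_ids)), rep("trans", length(trans_ids))),
      sequence = unname(seqs[cand_ids]), stringsAsFactors = FALSE)
    records <- applyNoncodingFilters(candidates, evidence, config)
  } else {
    records <- applyNoncodingFilters(
      data.frame(id = character(0), kind = character(0), sequence = character(0)),
      evidence, config)
  }
  funnel <- filterFunnelCounts(records)
  final_ids <- as.character(records$id[records$final])
  say(length(final_ids), " NATs pass the five-step filter (",
      sum(records$kind == "cis" & records$final), " cis, ",
      sum(records$kind == "trans" & records$final), " trans)")

  final_cis <- cis_pairs[as.character(cis_pairs$nat_id) %in% final_ids, , drop = FALSE]
  final_trans <- trans_pairs[as.character(trans_pairs$nat_id) %in% final_ids, , drop = FALSE]

  relationships <- relationshipType(final_cis)
  rel_counts <- table(factor(relationships$relation,
                             levels = c("1:1", "1:n", "n:1", "n:n")))
  cfg_hist <- configHistogram(final_cis)
  tx_len <- txLengths(txs)
  len_hist <- lengthHistogram(unname(tx_len[final_ids]))

  venn <- NULL; correlations <- NULL
  if (!is.null(expression_tsv)) {
    expr <- readExpression(expression_tsv, unit = "RPKM")
    known <- intersect(final_ids, rownames(exprValues(expr)))
    venn <- vennPartition(expr, known, cutoff = config@rpkm_cutoff)
    correlations <- correlatePairs(final_cis, expr)
  }

  enrichment <- NULL
  if (!is.null(annotation_tsv)) {
    ann <- utils::read.delim(annotation_tsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    st_ids <- unique(as.character(final_cis$st_id))
    enrichment <- enrich(st_ids, ann, total_genes = length(genes),
                         min_mapped = config@min_mapped_for_report)
  }

  # --- reports --------------------------------------------------------------
  .writeTsv(cis_pairs, file.path(out_dir, "cis_pairs.tsv"))
  .writeTsv(trans_pairs, file.path(out_dir, "trans_pairs.tsv"))
  .writeTsv(records, file.path(out_dir, "filter_trails.tsv"))
  .writeTsv(funnel, file.path(out_dir, "filter_funnel.tsv"))
  .writeTsv(relationships, file.path(out_dir, "relationships.tsv"))
  .writeTsv(cfg_hist, file.path(out_dir, "config_histogram.tsv"))
  .writeTsv(len_hist, file.path(out_dir, "length_histogram.tsv"))
  writeUnitsBed(units, file.path(out_dir, "units.bed"))
  if (nrow(final_cis)) writeCisBed(final_cis, file.path(out_dir, "cis_nats.bed"))
  if (!is.null(venn))
    .writeTsv(data.frame(region = names(venn$counts), count = venn$counts),
              file.path(out_dir, "venn_counts.tsv"))
  if (!is.null(correlations))
    .writeTsv(correlations, file.path(out_dir, "correlations.tsv"))
  if (!is.null(enrichment))
    .writeTsv(enrichment, file.path(out_dir, "enrichment.tsv"))

  summary <- list(
    config = configAsList(config),
    n_genes = length(genes), n_transcripts = length(txs),
    n_units = length(units),
    n_cis_candidates = nrow(cis_pairs), n_trans_candidates = nrow(trans_pairs),
    n_final_nats = length(final_ids),
    n_final_cis = sum(records$kind == "cis" & records$final),
    n_final_trans = sum(records$kind == "trans" & records$final),
    relationship_counts = as.list(rel_counts),
    config_counts = stats::setNames(as.list(cfg_hist$count), cfg_hist$config),
    venn = if (!is.null(venn)) c(as.list(venn$counts),
                                 total_expressed = venn$total_expressed))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("reports written to ", out_dir)

  invisible(list(units = units, cis_pairs = cis_pairs, trans_pairs = trans_pairs,
                 records = records, funnel = funnel,
                 final_cis = final_cis, final_trans = final_trans,
                 final_nat_ids = final_ids,
                 relationships = relationships,
                 relationship_counts = rel_counts,
                 venn = venn, correlations = correlations,
                 config_histogram = cfg_hist, length_histogram = len_hist,
                 enrichment = enrichment, summary = summary))
}
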