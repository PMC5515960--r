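#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString reverseComplement
#' @importFrom rtracklayer import export
NULL

## Internal: drop records without a usable strand, with a warning.
.dropUnstranded <- function(gr, what) {
  bad <- as.character(strand(gr)) == "*"
  if (any(bad)) {
    warning(sum(bad), " ", what,
            " record(s) without strand rejected (the method is strand-specific)",
            call. = FALSE)
    gr <- gr[!bad]
  }
  gr
}

#' Read predicted gene models from GFF3
#'
#' One transcript model is produced per `gene` feature (or per `mRNA` when the
#' file has no `gene` features). Exon children are attached via their `Parent`
#' attribute, following one level of gene -> mRNA -> exon nesting if present;
#' a gene without exon children gets a single exon equal to its span.
#' Unstranded records are rejected with a warning; duplicated IDs are an error.
#'
#' @param path Path to a GFF3 file.
#' @return A [TranscriptSet-class] with `origin = "predicted_gene"`.
#' @seealso [readAssembledTranscripts()], [writeGeneModels()]
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  if (!length(gff))
    return(TranscriptSet(GenomicRanges::GRangesList(), character(0)))
  type <- as.character(gff$type)
  lead_type <- if (any(type == "gene")) "gene" else "mRNA"
  lead <- gff[type == lead_type]
  lead <- .dropUnstranded(lead, "gene")
  ids <- as.character(lead$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("gene features must carry an ID attribute")
  if (anyDuplicated(ids))
    stop("duplicate gene ID(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))

  # map exon Parent to the lead feature, resolving one mRNA level if needed
  parent_of <- character(0)
  if (lead_type == "gene" && any(type == "mRNA")) {
    mr <- gff[type == "mRNA"]
    parent_of <- stats::setNames(
      vapply(mr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, ""),
      as.character(mr$ID))
  }
  exons <- gff[type == "exon"]
  assign_to <- function(p) {
    p <- as.character(p)
    ifelse(p %in% ids, p,
           ifelse(p %in% names(parent_of), unname(parent_of[p]), NA_character_))
  }
  ex_parent <- if (length(exons)) {
    vapply(exons$Parent, function(p) {
      hits <- assign_to(p)
      hits <- hits[!is.na(hits)]
      if (length(hits)) hits[[1]] else NA_character_
    }, "")
  } else character(0)

  ex_list <- vector("list", length(ids))
  names(ex_list) <- ids
  for (k in seq_along(ids)) {
    e <- exons[!is.na(ex_parent) & ex_parent == ids[k]]
    if (!length(e)) e <- lead[k]
    e <- GRanges(GenomicRanges::seqnames(e), ranges(e), strand = strand(e))
    ex_list[[k]] <- sort(e)
  }
  TranscriptSet(GenomicRanges::GRangesList(ex_list), origin = "predicted_gene")
}

#' Read assembled transcript models from GTF
#'
#' Exon features are grouped by `transcript_id` and sorted by start.
#' Disagreeing exon strands within one transcript are an error; unstranded
#' transcripts are rejected with a warning.
#'
#' @param path Path to a GTF file (e.g. assembler output).
#' @return A [TranscriptSet-class] with `origin = "assembled"`.
#' @export
readAssembledTranscripts <- function(path) {
  if (file.size(path) == 0L || !any(nzchar(readLines(path, n = 10L))))
    return(TranscriptSet(GenomicRanges::GRangesList(), character(0)))
  gtf <- rtracklayer::import(path, format = "gtf")
  gtf <- gtf[as.character(gtf$type) == "exon"]
  if (!length(gtf))
    return(TranscriptSet(GenomicRanges::GRangesList(), character(0)))
  tid <- gtf$transcript_id
  if (is.null(tid) || anyNA(tid))
    stop("GTF exon records must carry transcript_id")
  for (id in unique(tid)) {
    st <- unique(as.character(strand(gtf[tid == id])))
    if (length(st) > 1L)
      stop("exon strands disagree within transcript ", id)
  }
  keep <- as.character(strand(gtf)) != "*"
  if (!all(keep)) {
    warning(length(unique(tid[!keep])),
            " unstranded transcript(s) rejected", call. = FALSE)
    gtf <- gtf[keep]; tid <- tid[keep]
  }
  if (!length(gtf))
    return(TranscriptSet(GenomicRanges::GRangesList(), character(0)))
  gr <- GRanges(GenomicRanges::seqnames(gtf), ranges(gtf), strand = strand(gtf))
  ex <- GenomicRanges::split(gr, tid)
  TranscriptSet(ex, origin = "assembled")
}

#' Write gene models as GFF3 / transcripts as GTF
#'
#' Inverse of [readGeneModels()] and [readAssembledTranscripts()]; a
#' write-then-read round trip reproduces the models exactly.
#'
#' @param x A `TranscriptSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(x, path) {
  stopifnot(methods::is(x, "TranscriptSet"))
  spans <- txSpans(x)
  rows <- list()
  for (k in seq_along(spans)) {
    id <- mcols(spans)$tx_id[k]
    g <- spans[k]
    mcols(g) <- NULL
    g$type <- "gene"; g$ID <- id; g$Parent <- NA_character_
    e <- txExons(x)[[k]]
    mcols(e) <- NULL
    if (length(e)) {
      e$type <- "exon"
      e$ID <- paste0(id, ".exon", seq_along(e))
      e$Parent <- id
    }
    rows[[length(rows) + 1L]] <- c(g, e)
  }
  out <- if (length(rows)) do.call(c, rows) else GRanges()
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGeneModels
#' @export
writeTranscriptsGTF <- function(x, path) {
  stopifnot(methods::is(x, "TranscriptSet"))
  ex <- txExons(x)
  u <- unlist(ex, use.names = FALSE)
  if (length(u)) {
    mcols(u) <- NULL
    u$type <- "exon"
    u$transcript_id <- rep(names(ex), lengths(ex))
    u$gene_id <- u$transcript_id
  }
  rtracklayer::export(u, path, format = "gtf")
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequence names are truncated at the first whitespace and sequences are
#' uppercased (alphabet ACGTN; N never base-pairs downstream).
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract spliced transcript sequences
#'
#' Concatenates each model's exon sequences in genomic order and reverse
#' complements minus-strand models, so every returned sequence reads 5' to 3'
#' on its own strand.
#'
#' @param x A `TranscriptSet`.
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   scaffold sequences.
#' @return A named `DNAStringSet`, one spliced sequence per model.
#' @export
extractTranscriptSeq <- function(x, genome) {
  stopifnot(methods::is(x, "TranscriptSet"))
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  ex <- txExons(x)
  out <- vector("list", length(ex))
  for (k in seq_along(ex)) {
    e <- ex[[k]]
    sc <- as.character(GenomicRanges::seqnames(e)[1])
    if (!sc %in% names(genome))
      stop("scaffold ", sc, " absent from genome")
    chrom <- genome[[sc]]
    if (any(start(e) < 1L) || any(end(e) > length(chrom)))
      stop("exon out of scaffold bounds for transcript ", names(ex)[k])
    s <- do.call(Biostrings::xscat,
                 lapply(seq_along(e), function(i)
                   Biostrings::subseq(chrom, start(e)[i], end(e)[i])))
    if (as.character(strand(e)[1]) == "-")
      s <- Biostrings::reverseComplement(s)
    out[[k]] <- s
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(ex)
  res
}

#' Read / write a transcript-by-stage expression matrix
#'
#' The TSV must have a header row naming the stages and transcript ids in the
#' first column. Negative values, missing cells and duplicated transcript
#' rows are errors.
#'
#' @param path TSV file path.
#' @param unit Unit of the stored values, `"RPKM"` or `"raw_count"`.
#' @return A [StageExpression-class] object.
#' @export
readExpression <- function(path, unit = c("RPKM", "raw_count")) {
  unit <- match.arg(unit)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs an id column and >=1 stage")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated transcript row(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing cells in expression table")
  if (any(m < 0)) stop("negative expression values")
  rownames(m) <- ids
  StageExpression(m, unit = unit)
}

#' @rdname readExpression
#' @param x A `StageExpression`.
#' @export
writeExpression <- function(x, path) {
  stopifnot(methods::is(x, "StageExpression"))
  df <- data.frame(transcript_id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evidence tables for the non-coding filter cascade
#'
#' External search results (best protein-database e-value, coding-potential
#' score, best housekeeping-ncRNA e-value, best small-RNA e-value) are
#' consumed as plain two-column TSVs (`id`, `value`), one optional file per
#' table, so externally run searches can be slotted in. An absent table means
#' "no evidence"; an absent id means "no hit". All e-values must be positive.
#'
#' `evidenceTables()` builds the same structure from in-memory named vectors.
#'
#' @param dir Directory searched for `nr.tsv`, `cpc.tsv`, `housekeeping.tsv`,
#'   `smallrna.tsv`; missing files yield `NULL` entries.
#' @return A named list with elements `nr`, `cpc`, `housekeeping`, `smallrna`;
#'   each a named numeric vector or `NULL`.
#' @export
readEvidenceTables <- function(dir) {
  one <- function(fn, evalue = TRUE) {
    p <- file.path(dir, fn)
    if (!file.exists(p)) return(NULL)
    tab <- utils::read.delim(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    v <- stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
    if (evalue && any(v <= 0)) stop("e-values must be > 0 in ", fn)
    v
  }
  evidenceTables(nr = one("nr.tsv"), cpc = one("cpc.tsv", evalue = FALSE),
                 housekeeping = one("housekeeping.tsv"),
                 smallrna = one("smallrna.tsv"))
}

#' @rdname readEvidenceTables
#' @param nr,cpc,housekeeping,smallrna Named numeric vectors keyed by
#'   transcript id, or `NULL` for an absent table.
#' @export
evidenceTables <- function(nr = NULL, cpc = NULL, housekeeping = NULL,
                           smallrna = NULL) {
  chk <- function(v, nm, evalue = TRUE) {
    if (is.null(v)) return(NULL)
    if (is.null(names(v))) stop(nm, " table must be named by transcript id")
    if (evalue && any(v <= 0)) stop(nm, " e-values must be > 0")
    v
  }
  list(nr = chk(nr, "nr"), cpc = chk(cpc, "cpc", evalue = FALSE),
       housekeeping = chk(housekeeping, "housekeeping"),
       smallrna = chk(smallrna, "smallrna"))
}

## Internal TSV writer for report catalogs.
.writeTsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export transcript units as BED6
#'
#' Name is the unit id, score the member count.
#'
#' @param units A [TranscriptUnits-class] object.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeUnitsBed <- function(units, path) {
  stopifnot(methods::is(units, "TranscriptUnits"))
  sp <- unitSpans(units)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sp)),
    start = start(sp) - 1L, end = end(sp),
    name = mcols(sp)$unit_id, score = mcols(sp)$n_members,
    strand = as.character(strand(sp)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export cis-NATs as a BED12 track colored by configuration
#'
#' One BED12 line per cis pair over the NAT span; divergent, convergent and
#' the two containment configurations get distinct itemRgb colors.
#'
#' @param pairs A [result-tables] `CisPairs` object.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeCisBed <- function(pairs, path) {
  cols <- c(divergent = "27,158,119", convergent = "217,95,2",
            S_contains_N = "117,112,179", N_contains_S = "231,41,138")
  df <- data.frame(
    chrom = pairs$scaffold,
    start = pairs$nat_start - 1L, end = pairs$nat_end,
    name = paste0(pairs$nat_id, "|", pairs$st_id),
    score = 0L, strand = pairs$nat_strand,
    thickStart = pairs$nat_start - 1L, thickEnd = pairs$nat_end,
    itemRgb = unname(cols[as.character(pairs$config)]),
    blockCount = 1L,
    blockSizes = pairs$nat_end - pairs$nat_start + 1L,
    blockStarts = 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
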