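#' Longest open reading frame of a transcript
#'
#' Scans the three forward reading frames of the given strand (a transcript's
#' coding potential is read 5' to 3'; set `both_strands = TRUE` for a 6-frame
#' scan) for ATG-initiated, stop-terminated open reading frames under the
#' standard genetic code. Returns the longest ORF length in amino acids, stop
#' codon excluded; 0 when no complete ORF exists. Codons containing `N` are
#' neither starts nor stops.
#'
#' @param seq Nucleotide sequence, 5' to 3' (character or `DNAString`).
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return Integer amino-acid count.
#' @examples
#' maxOrfLength("ATGAAATAA")  # 2 (Met-Lys)
#' @export
maxOrfLength <- function(seq, both_strands = FALSE) {
  seq <- toupper(as.character(seq))
  scan3 <- function(s) {
    n <- nchar(s)
    best <- 0L
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2L) next
      cs <- seq(1L + f, by = 3L, length.out = ncod)
      codons <- substring(s, cs, cs + 2L)
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      atgs <- which(codons == "ATG")
      if (!length(stops) || !length(atgs)) next
      # next stop strictly after each ATG
      nxt <- stops[findInterval(atgs, stops) + 1L]
      ok <- !is.na(nxt)
      if (any(ok)) best <- max(best, max(nxt[ok] - atgs[ok]))
    }
    best
  }
  out <- scan3(seq)
  if (both_strands) out <- max(out, scan3(.revcomp(seq)))
  as.integer(out)
}

#' Apply the five-step non-coding filter cascade
#'
#' Turns candidate antisense transcripts into NATs through five ordered
#' filters; evaluation of a candidate stops at its first failure:
#' \enumerate{
#'   \item length: keep iff spliced length > `min_length_nt` (200 nt;
#'     exactly 200 fails);
#'   \item ORF: keep iff the longest ORF is <= `max_orf_aa` (100 aa; exactly
#'     100 passes);
#'   \item protein similarity: keep iff no protein-database hit with e-value
#'     <= `nr_evalue_cutoff` (1e-3; a hit at exactly the cutoff disqualifies);
#'   \item coding potential: keep iff the score is strictly below
#'     `cpc_keep_below` (0; a score of exactly 0 fails); a candidate absent
#'     from a present table passes with a warning;
#'   \item housekeeping/small RNA: keep iff no hit in either table with
#'     e-value <= `ncrna_evalue_cutoff` (1e-10).
#' }
#' An entirely absent evidence table makes its step pass vacuously with a
#' warning, unless `strict = TRUE`, which makes it an error.
#'
#' @param candidates A `data.frame` (or `DataFrame`) with columns `id`,
#'   `kind` (`"cis"`/`"trans"`) and `sequence` (spliced, 5' to 3').
#' @param evidence An [evidenceTables()] list.
#' @param config A [PipelineConfig-class].
#' @param strict Treat a missing evidence table as an error.
#' @return A `NatRecords` table: `id`, `kind`, `length_nt`, `max_orf_aa`
#'   (`NA` when step 2 was never reached), pass flags `step1_length` ..
#'   `step5_ncrna` (`NA` = not evaluated), `failed_at` (`NA` when final) and
#'   `final`. Same inputs always yield identical trails.
#' @export
applyNoncodingFilters <- function(candidates, evidence = evidenceTables(),
                                  config = natConfig(), strict = FALSE) {
  stopifnot(all(c("id", "kind", "sequence") %in% colnames(candidates)))
  n <- nrow(candidates)
  miss <- names(evidence)[vapply(evidence, is.null, TRUE)]
  if (length(miss)) {
    msg <- paste("evidence table(s) absent:", paste(miss, collapse = ", "),
                 "- the corresponding step(s) pass vacuously")
    if (strict) stop(msg) else if (n) warning(msg, call. = FALSE)
  }
  id <- as.character(candidates$id)
  kind <- as.character(candidates$kind)
  sq <- toupper(as.character(candidates$sequence))
  len <- nchar(sq)

  s1 <- len > config@min_length_nt
  orf <- rep(NA_integer_, n)
  s2 <- s3 <- s4 <- s5 <- rep(NA, n)
  failed <- rep(NA_character_, n)
  failed[!s1] <- "length"

  act <- which(s1)
  orf[act] <- vapply(sq[act], maxOrfLength, 0L, USE.NAMES = FALSE)
  s2[act] <- orf[act] <= config@max_orf_aa
  failed[act][!s2[act]] <- "orf"

  lookup <- function(tab, ids) if (is.null(tab)) rep(NA_real_, length(ids)) else unname(tab[ids])

  act <- which(s1 & s2 %in% TRUE)
  ev <- lookup(evidence$nr, id[act])
  s3[act] <- is.na(ev) | ev > config@nr_evalue_cutoff
  failed[act][!s3[act]] <- "nr_hit"

  act <- which(s3 %in% TRUE)
  sc <- lookup(evidence$cpc, id[act])
  if (!is.null(evidence$cpc) && anyNA(sc))
    warning(sum(is.na(sc)), " candidate(s) missing from the coding-potential",
            " table pass step 4 vacuously", call. = FALSE)
  s4[act] <- is.na(sc) | sc < config@cpc_keep_below
  failed[act][!s4[act]] <- "coding_potential"

  act <- which(s4 %in% TRUE)
  hk <- lookup(evidence$housekeeping, id[act])
  sr <- lookup(evidence$smallrna, id[act])
  bad <- (!is.na(hk) & hk <= config@ncrna_evalue_cutoff) |
         (!is.na(sr) & sr <= config@ncrna_evalue_cutoff)
  s5[act] <- !bad
  failed[act][bad] <- "ncrna_hit"

  final <- s5 %in% TRUE
  methods::new("NatRecords", DataFrame(
    id = id, kind = kind, length_nt = as.integer(len), max_orf_aa = orf,
    step1_length = s1, step2_orf = s2, step3_nr = s3,
    step4_cpc = s4, step5_ncrna = s5,
    failed_at = failed, final = final))
}

#' Filter funnel counts
#'
#' Cumulative retained/discarded counts after each of the five filter steps,
#' per kind (cis/trans) and combined, mirroring a pipeline funnel diagram.
#' Retained counts are non-increasing along the cascade.
#'
#' @param records A `NatRecords` table from [applyNoncodingFilters()].
#' @return A `data.frame` with columns `kind`, `step`, `entered`, `retained`,
#'   `discarded`.
#' @export
filterFunnelCounts <- function(records) {
  steps <- c("step1_length", "step2_orf", "step3_nr", "step4_cpc", "step5_ncrna")
  one <- function(rec, label) {
    entered <- nrow(rec)
    out <- data.frame(kind = character(0), step = character(0),
                      entered = integer(0), retained = integer(0),
                      discarded = integer(0))
    for (s in steps) {
      passed <- sum(rec[[s]] %in% TRUE)
      out <- rbind(out, data.frame(kind = label, step = sub("^step\\d_", "", s),
                                   entered = entered, retained = passed,
                                   discarded = entered - passed))
      entered <- passed
    }
    out
  }
  rbind(one(records, "combined"),
        one(records[records$kind == "cis", , drop = FALSE], "cis"),
        one(records[records$kind == "trans", , drop = FALSE], "trans"))
}
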