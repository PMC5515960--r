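#' Classify a sense-antisense pair into one of four configurations
#'
#' The four configurations of an overlapping opposite-strand pair are:
#' `divergent` (head-to-head, the NAT overlaps the ST's 5' end),
#' `convergent` (tail-to-tail, the NAT overlaps the ST's 3' end),
#' `S_contains_N` (the NAT is embedded in the ST) and `N_contains_S`
#' (the NAT spans the entire ST). Containment is checked first; otherwise
#' the overlapped end of the ST decides. Exactly one class is returned, and
#' the class is invariant under mirroring the whole locus (strand flip).
#'
#' @param st,nat Single-range `GRanges` on one scaffold, opposite strands,
#'   overlapping; otherwise an error.
#' @return One of `"divergent"`, `"convergent"`, `"S_contains_N"`,
#'   `"N_contains_S"`.
#' @examples
#' st  <- GenomicRanges::GRanges("s1", IRanges::IRanges(101, 500), strand = "+")
#' nat <- GenomicRanges::GRanges("s1", IRanges::IRanges(401, 600), strand = "-")
#' classifyCisPair(st, nat)  # "convergent"
#' @export
classifyCisPair <- function(st, nat) {
  stopifnot(length(st) == 1L, length(nat) == 1L)
  if (as.character(GenomicRanges::seqnames(st)) != as.character(GenomicRanges::seqnames(nat)))
    stop("pair must lie on one scaffold")
  s_strand <- as.character(strand(st)); n_strand <- as.character(strand(nat))
  if (s_strand == "*" || n_strand == "*" || s_strand == n_strand)
    stop("pair must be on opposite strands")
  if (end(nat) < start(st) || end(st) < start(nat))
    stop("pair must overlap")
  if (start(nat) >= start(st) && end(nat) <= end(st)) return("S_contains_N")
  if (start(nat) <= start(st) && end(nat) >= end(st)) return("N_contains_S")
  # partial overlap: which end of the ST is covered (5' depends on strand)
  left <- start(nat) < start(st)   # overlap covers the ST's left end
  five_prime_left <- s_strand == "+"
  if (left == five_prime_left) "divergent" else "convergent"
}

#' Find candidate cis-NAT pairs
#'
#' Pairs every predicted gene against every opposite-strand transcript unit
#' on the same scaffold whose span overlap is at least `min_frac` of the
#' length of at least one of the two (`overlap_rule = "any"`, the default
#' reading of "10 percent of either transcript"; `"both"` requires the
#' fraction on both sides). Units containing a predicted gene are ST-side
#' loci and are never NAT candidates. Overlap is computed on transcript
#' spans, intron inclusive.
#'
#' @param units A [TranscriptUnits-class] object built over genes and
#'   transcripts together.
#' @param genes A [TranscriptSet-class] of predicted genes.
#' @param min_frac Admission fraction in (0, 1]; default 0.10.
#' @param overlap_rule `"any"` or `"both"`.
#' @return A `CisPairs` table sorted by (scaffold, ST start, NAT start) with
#'   columns `st_id`, `nat_id`, `scaffold`, `st_start`, `st_end`,
#'   `st_strand`, `nat_start`, `nat_end`, `nat_strand`, `overlap_start`,
#'   `overlap_end`, `overlap_len`, `frac_of_st`, `frac_of_nat`, `config`.
#' @export
findCisCandidates <- function(units, genes, min_frac = 0.10,
                              overlap_rule = c("any", "both")) {
  overlap_rule <- match.arg(overlap_rule)
  if (!is.numeric(min_frac) || length(min_frac) != 1L || min_frac <= 0 || min_frac > 1)
    stop("min_frac must lie in (0, 1]")
  gsp <- txSpans(genes)
  usp <- unitSpans(units)
  nat_units <- usp[!mcols(usp)$contains_gene]
  empty <- methods::new("CisPairs", DataFrame(
    st_id = character(0), nat_id = character(0), scaffold = character(0),
    st_start = integer(0), st_end = integer(0), st_strand = character(0),
    nat_start = integer(0), nat_end = integer(0), nat_strand = character(0),
    overlap_start = integer(0), overlap_end = integer(0), overlap_len = integer(0),
    frac_of_st = numeric(0), frac_of_nat = numeric(0), config = character(0)))
  if (!length(gsp) || !length(nat_units)) return(empty)

  flipped <- gsp
  strand(flipped) <- ifelse(as.character(strand(gsp)) == "+", "-", "+")
  hits <- GenomicRanges::findOverlaps(flipped, nat_units, minoverlap = 1L,
                                      ignore.strand = FALSE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  g <- gsp[qi]; u <- nat_units[si]
  ov_start <- pmax(start(g), start(u))
  ov_end <- pmin(end(g), end(u))
  ov_len <- ov_end - ov_start + 1L
  f_st <- ov_len / width(g)
  f_nat <- ov_len / width(u)
  keep <- if (overlap_rule == "any") f_st >= min_frac | f_nat >= min_frac
          else f_st >= min_frac & f_nat >= min_frac
  if (!any(keep)) return(empty)
  g <- g[keep]; u <- u[keep]
  ov_start <- ov_start[keep]; ov_end <- ov_end[keep]; ov_len <- ov_len[keep]
  f_st <- f_st[keep]; f_nat <- f_nat[keep]
  config <- vapply(seq_along(g), function(i)
    classifyCisPair(g[i], GRanges(GenomicRanges::seqnames(u[i]), ranges(u[i]),
                                  strand = strand(u[i]))), "")
  df <- DataFrame(
    st_id = mcols(g)$tx_id, nat_id = mcols(u)$unit_id,
    scaffold = as.character(GenomicRanges::seqnames(g)),
    st_start = start(g), st_end = end(g),
    st_strand = as.character(strand(gsp[qi][keep])),
    nat_start = start(u), nat_end = end(u),
    nat_strand = as.character(strand(u)),
    overlap_start = ov_start, overlap_end = ov_end, overlap_len = ov_len,
    frac_of_st = f_st, frac_of_nat = f_nat, config = config)
  df <- df[order(df$scaffold, df$st_start, df$nat_start), , drop = FALSE]
  rownames(df) <- NULL
  methods::new("CisPairs", df)
}

#' Overlap-ratio profile of a cis catalog
#'
#' One row per pair with the overlap length and the ratio of the overlap to
#' the ST and to the NAT length; containment of the NAT forces
#' `frac_of_nat = 1`.
#'
#' @param pairs A `CisPairs` table.
#' @return A `DataFrame` with columns `st_id`, `nat_id`, `overlap_len`,
#'   `frac_of_st`, `frac_of_nat`, `config`.
#' @export
overlapRatioProfile <- function(pairs) {
  DataFrame(st_id = pairs$st_id, nat_id = pairs$nat_id,
            overlap_len = pairs$overlap_len,
            frac_of_st = pairs$frac_of_st, frac_of_nat = pairs$frac_of_nat,
            config = pairs$config)
}

#' Configuration histogram of a cis catalog
#'
#' @param pairs A `CisPairs` table.
#' @return A `data.frame` with columns `config`, `count`, `percent` over the
#'   four configurations.
#' @export
configHistogram <- function(pairs) {
  lv <- c("divergent", "convergent", "S_contains_N", "N_contains_S")
  n <- as.integer(table(factor(as.character(pairs$config), levels = lv)))
  data.frame(config = lv, count = n,
             percent = if (sum(n)) round(100 * n / sum(n), 1) else rep(0, 4L))
}
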