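## Internal: character vector of a sequence, uppercased.
.chars <- function(x) strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]

## Internal: reverse complement as a character scalar (N maps to N).
.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Find continuous complementary regions between two transcripts
#'
#' Locates gap-free stretches where a window of `a` equals the reverse
#' complement of a window of `b` ("100-nt pair" search). Matching is seeded
#' with exact `seed_len`-mers of `a` against the reverse complement of `b`;
#' on each seeded diagonal, maximal exact runs of at least `seed_len` bases
#' form cores, which are then extended across single mismatches as long as
#' the region identity stays at or above `min_identity`. Regions are trimmed
#' to matching ends, merged when they overlap on a diagonal, and reported if
#' at least `min_len` long. `N` never base-pairs.
#'
#' @param a,b Nucleotide sequences (character or `DNAString`), each read
#'   5' to 3' on its own strand.
#' @param min_len Minimum region length to report (default 100).
#' @param seed_len Exact seed size (default 12); `min_len >= seed_len`.
#' @param min_identity Identity floor for mismatch extension in (0, 1];
#'   `1` reports exact maximal runs only.
#' @return A `DataFrame` ordered by (a offset, b offset) with columns
#'   `a_start`, `a_end`, `b_start`, `b_end` (1-based inclusive offsets within
#'   each sequence, each 5' to 3' of its own sequence), `length`, `identity`.
#' @examples
#' a <- paste(rep("ACGTT", 60), collapse = "")
#' b <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(substr(a, 51, 200))))
#' findComplementaryRegions(a, b, min_len = 100)
#' @export
findComplementaryRegions <- function(a, b, min_len = 100, seed_len = 12,
                                     min_identity = 0.8) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  empty <- DataFrame(a_start = integer(0), a_end = integer(0),
                     b_start = integer(0), b_end = integer(0),
                     length = integer(0), identity = numeric(0))
  na <- nchar(a); nb <- nchar(b)
  if (min_len < seed_len) stop("min_len must be >= seed_len")
  if (na < seed_len || nb < seed_len) return(empty)
  rcb <- .revcomp(b)
  ac <- .chars(a); bc <- .chars(rcb)

  # seed table: positions of each seed_len-mer of rcb
  kb <- substring(rcb, seq_len(nb - seed_len + 1L),
                  seq_len(nb - seed_len + 1L) + seed_len - 1L)
  ka <- substring(a, seq_len(na - seed_len + 1L),
                  seq_len(na - seed_len + 1L) + seed_len - 1L)
  keep <- !grepl("N", kb, fixed = TRUE)
  tab <- split(which(keep), kb[keep])
  hit_a <- which(ka %in% names(tab) & !grepl("N", ka, fixed = TRUE))
  if (!length(hit_a)) return(empty)
  diags <- unique(unlist(lapply(hit_a, function(i) i - tab[[ka[i]]]),
                         use.names = FALSE))
  diags <- sort(diags)

  res <- list()
  for (d in diags) {
    # positions i in a aligned to i - d in rcb
    lo <- max(1L, 1L + d); hi <- min(na, nb + d)
    if (hi - lo + 1L < min_len) next
    ia <- lo:hi
    m <- ac[ia] == bc[ia - d] & ac[ia] != "N"
    # maximal exact runs >= seed_len are cores
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    core <- which(r$values & r$lengths >= seed_len)
    if (!length(core)) next
    regions <- lapply(core, function(k) c(starts[k], ends[k]))
    if (min_identity < 1) {
      regions <- lapply(regions, function(rg) {
        repeat {
          grew <- FALSE
          # bridge a single mismatch on the right, then on the left
          k_right <- which(starts == rg[2L] + 1L)
          if (length(k_right) && !r$values[k_right] && r$lengths[k_right] == 1L &&
              k_right < length(r$values)) {
            cand_end <- ends[k_right + 1L]
            len <- cand_end - rg[1L] + 1L
            mm <- sum(!m[rg[1L]:cand_end])
            if ((len - mm) / len >= min_identity) { rg[2L] <- cand_end; grew <- TRUE }
          }
          k_left <- which(ends == rg[1L] - 1L)
          if (length(k_left) && !r$values[k_left] && r$lengths[k_left] == 1L &&
              k_left > 1L) {
            cand_start <- starts[k_left - 1L]
            len <- rg[2L] - cand_start + 1L
            mm <- sum(!m[cand_start:rg[2L]])
            if ((len - mm) / len >= min_identity) { rg[1L] <- cand_start; grew <- TRUE }
          }
          if (!grew) break
        }
        rg
      })
      # merge overlapping/adjacent extended regions on this diagonal
      regions <- regions[order(vapply(regions, `[`, 0L, 1L))]
      merged <- list(regions[[1L]])
      for (rg in regions[-1L]) {
        last <- merged[[length(merged)]]
        if (rg[1L] <= last[2L] + 1L)
          merged[[length(merged)]] <- c(last[1L], max(last[2L], rg[2L]))
        else merged[[length(merged) + 1L]] <- rg
      }
      regions <- unique(merged)
    }
    for (rg in regions) {
      len <- rg[2L] - rg[1L] + 1L
      if (len < min_len) next
      a_start <- ia[rg[1L]]; a_end <- ia[rg[2L]]
      ident <- mean(m[rg[1L]:rg[2L]])
      # map rcb offsets back to b: rcb position p <-> b position nb - p + 1
      rc_start <- a_start - d; rc_end <- a_end - d
      res[[length(res) + 1L]] <- data.frame(
        a_start = a_start, a_end = a_end,
        b_start = nb - rc_end + 1L, b_end = nb - rc_start + 1L,
        length = len, identity = ident)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  as(out, "DFrame")
}

#' Anneal two transcripts over a seed complementary region
#'
#' Models RNA-RNA duplex formation as a local hybridization alignment of the
#' seed's neighborhood in `a` against the reverse complement of the seed's
#' neighborhood in `b` (match +1, mismatch -1, gap opening -2, gap extension
#' -0.5). The annealed region is the maximal-scoring aligned block; bubbles
#' are maximal interior runs of non-paired columns (mismatches or gaps),
#' their length counted in alignment columns; terminal overhangs are not
#' bubbles. The duplex passes when the annealed block coincides with the
#' seed region on both sequences and no bubble is longer than
#' `bubble_max_frac` of the annealed block length (bubbles included).
#'
#' @param a,b Nucleotide sequences, 5' to 3' each.
#' @param seed One row of [findComplementaryRegions()] output (or a list with
#'   `a_start`, `a_end`, `b_start`, `b_end`).
#' @param bubble_max_frac Maximum bubble fraction (default 0.10).
#' @param flank Neighborhood extension around the seed on both sequences
#'   (default 150 nt).
#' @return A list of class `duplexResult`: `annealed_a`, `annealed_b`
#'   (integer start/end pairs on each sequence), `region_len` (alignment
#'   columns), `bubbles` (integer vector of bubble lengths), `max_bubble_frac`,
#'   `coincides`, `passes`, `score`.
#' @export
annealDuplex <- function(a, b, seed, bubble_max_frac = 0.10, flank = 150) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  na <- nchar(a); nb <- nchar(b)
  sa <- c(seed$a_start, seed$a_end); sb <- c(seed$b_start, seed$b_end)
  a_lo <- max(1L, sa[1L] - flank); a_hi <- min(na, sa[2L] + flank)
  b_lo <- max(1L, sb[1L] - flank); b_hi <- min(nb, sb[2L] + flank)
  aN <- substr(a, a_lo, a_hi)
  bN <- substr(b, b_lo, b_hi)
  rcbN <- .revcomp(bN)
  nbN <- nchar(bN)

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  mat["N", ] <- -1; mat[, "N"] <- -1  # N never pairs
  al <- Biostrings::pairwiseAlignment(aN, rcbN, substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 0.5,
                                      type = "local")
  pa <- .chars(as.character(Biostrings::alignedPattern(al)))
  ps <- .chars(as.character(Biostrings::alignedSubject(al)))
  paired <- pa == ps & pa != "-" & pa != "N"
  ncols <- length(paired)

  # block bounds on each sequence (local alignment is already match-trimmed)
  a_start <- a_lo + start(Biostrings::pattern(al)) - 1L
  a_end <- a_lo + end(Biostrings::pattern(al)) - 1L
  rc_s <- start(Biostrings::subject(al)); rc_e <- end(Biostrings::subject(al))
  b_start <- b_lo + (nbN - rc_e + 1L) - 1L
  b_end <- b_lo + (nbN - rc_s + 1L) - 1L

  bubbles <- integer(0)
  if (ncols) {
    r <- rle(paired)
    inner <- seq_along(r$values)
    if (!r$values[1L]) inner <- inner[-1L]
    if (length(r$values) && !r$values[length(r$values)])
      inner <- setdiff(inner, length(r$values))
    bubbles <- r$lengths[inner][!r$values[inner]]
  }
  max_bfrac <- if (length(bubbles) && ncols) max(bubbles) / ncols else 0
  coincides <- ncols > 0 &&
    a_start <= sa[2L] && a_end >= sa[1L] &&
    b_start <= sb[2L] && b_end >= sb[1L]
  passes <- coincides && all(bubbles <= bubble_max_frac * ncols)
  structure(list(
    annealed_a = c(a_start, a_end), annealed_b = c(b_start, b_end),
    region_len = ncols, bubbles = as.integer(bubbles),
    max_bubble_frac = max_bfrac, coincides = coincides, passes = passes,
    score = Biostrings::score(al)), class = "duplexResult")
}

#' @export
print.duplexResult <- function(x, ...) {
  cat("duplex: a[", x$annealed_a[1L], "-", x$annealed_a[2L], "] ~ b[",
      x$annealed_b[1L], "-", x$annealed_b[2L], "], ", x$region_len,
      " columns, ", length(x$bubbles), " bubble(s)",
      if (length(x$bubbles)) paste0(" (max ", round(100 * x$max_bubble_frac, 1), "%)"),
      ", ", if (x$passes) "passes" else "fails", "\n", sep = "")
  invisible(x)
}

#' Find candidate trans-NAT pairs
#'
#' Chains the three trans criteria over all (predicted gene, assembled
#' transcript) pairs from different, non-overlapping loci ("located
#' remotely": different transcript units and zero genomic span overlap,
#' strand ignored). A pair is reported when (i) the spliced sequences share a
#' continuous complementary region longer than `config@trans_min_complement_nt`;
#' (ii) the pair is high-coverage: the region is longer than
#' `config@trans_coverage_frac` of at least one of the two sequences
#' (`coverage_rule = "any"`; `"both"` requires both); and (iii) the duplex
#' anneals over the region with every bubble within
#' `config@bubble_max_frac` of the annealed length. Only transcripts whose
#' unit contains no predicted gene are candidate NATs. When several regions
#' qualify for a pair, the longest (then leftmost) is reported.
#'
#' Pairs are shortlisted by a shared 12-mer seed index before the full
#' region search, so the all-vs-all comparison stays near-linear in practice.
#'
#' @param genes A `TranscriptSet` of predicted genes.
#' @param transcripts A `TranscriptSet` of assembled transcripts.
#' @param genome Named `DNAStringSet` of scaffolds.
#' @param config A [PipelineConfig-class]; thresholds read from it.
#' @param units Optional precomputed [TranscriptUnits-class] over
#'   `c(genes, transcripts)`; built internally when missing.
#' @return A `TransPairs` table with columns `st_id`, `nat_id`, `a_start`,
#'   `a_end`, `b_start`, `b_end`, `region_len`, `identity`, `coverage_st`,
#'   `coverage_nat`, `n_bubbles`, `max_bubble_frac`, `passes` (all `TRUE`).
#' @export
findTransCandidates <- function(genes, transcripts, genome, config = natConfig(),
                                units = NULL) {
  stopifnot(methods::is(config, "PipelineConfig"))
  empty <- methods::new("TransPairs", DataFrame(
    st_id = character(0), nat_id = character(0),
    a_start = integer(0), a_end = integer(0),
    b_start = integer(0), b_end = integer(0),
    region_len = integer(0), identity = numeric(0),
    coverage_st = numeric(0), coverage_nat = numeric(0),
    n_bubbles = integer(0), max_bubble_frac = numeric(0), passes = logical(0)))
  if (!length(genes) || !length(transcripts)) return(empty)
  all_models <- c(genes, transcripts)
  if (is.null(units)) units <- buildTranscriptUnits(all_models)
  u_of <- unitOf(all_models, units)
  cg <- containsGene(units)
  cand_tx <- txIds(transcripts)[!cg[u_of[txIds(transcripts)]]]
  if (!length(cand_tx)) return(empty)

  gseq <- as.character(extractTranscriptSeq(genes, genome))
  tseq <- as.character(extractTranscriptSeq(transcripts[cand_tx], genome))
  gspan <- txSpans(genes); tspan <- txSpans(transcripts[cand_tx])

  # 12-mer shortlist: genes sharing a seed with the reverse complement of a tx
  seed_len <- 12L
  kmers <- function(s) {
    n <- nchar(s)
    if (n < seed_len) return(character(0))
    unique(substring(s, seq_len(n - seed_len + 1L),
                     seq_len(n - seed_len + 1L) + seed_len - 1L))
  }
  km_all <- lapply(gseq, kmers)
  gene_kmer <- split(rep(seq_along(gseq), lengths(km_all)),
                     unlist(km_all, use.names = FALSE))
  min_nt <- config@trans_min_complement_nt
  cov_frac <- config@trans_coverage_frac
  res <- list()
  for (ti in seq_along(tseq)) {
    rk <- kmers(.revcomp(tseq[ti]))
    rk <- rk[rk %in% names(gene_kmer)]
    gis <- sort(unique(unlist(gene_kmer[rk], use.names = FALSE)))
    for (gi in gis) {
      # remote requirement: different units and zero genomic span overlap
      if (u_of[names(gseq)[gi]] == u_of[names(tseq)[ti]]) next
      if (length(GenomicRanges::findOverlaps(gspan[gi], tspan[ti],
                                             ignore.strand = TRUE))) next
      regs <- findComplementaryRegions(gseq[gi], tseq[ti],
                                       min_len = max(seed_len, min_nt + 1L))
      regs <- regs[regs$length > min_nt, , drop = FALSE]
      if (!nrow(regs)) next
      regs <- regs[order(-regs$length, regs$a_start), , drop = FALSE]
      reg <- regs[1L, ]
      cov_st <- reg$length / nchar(gseq[gi])
      cov_nat <- reg$length / nchar(tseq[ti])
      high <- if (config@coverage_rule == "any") cov_st > cov_frac || cov_nat > cov_frac
              else cov_st > cov_frac && cov_nat > cov_frac
      if (!high) next
      dup <- annealDuplex(gseq[gi], tseq[ti], reg,
                          bubble_max_frac = config@bubble_max_frac)
      if (!dup$passes) next
      res[[length(res) + 1L]] <- data.frame(
        st_id = names(gseq)[gi], nat_id = names(tseq)[ti],
        a_start = reg$a_start, a_end = reg$a_end,
        b_start = reg$b_start, b_end = reg$b_end,
        region_len = reg$length, identity = reg$identity,
        coverage_st = cov_st, coverage_nat = cov_nat,
        n_bubbles = length(dup$bubbles),
        max_bubble_frac = dup$max_bubble_frac, passes = TRUE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$st_id, out$nat_id), , drop = FALSE]
  rownames(out) <- NULL
  methods::new("TransPairs", as(out, "DFrame"))
}
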