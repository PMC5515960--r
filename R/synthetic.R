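## Internal: random uniform-GC nucleotide string.
.randSeq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

## Internal: random open reading frame of `aa` amino acids (ATG .. stop),
## built from non-stop codons so the planted length is exact.
.randOrf <- function(aa) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(codons, aa - 1L, replace = TRUE), collapse = ""), "TAA")
}

#' Synthetic fixture configuration
#'
#' Counts and sizes of the planted study conditions. The `"full"` preset
#' plants all four cis configurations, the three multiplex relationship
#' motifs (1:n, n:1, n:n), three passing trans pairs, one decoy per filter
#' criterion (each violating exactly one criterion by a stated margin),
#' background genes for the enrichment universe, and sense/intergenic
#' transcripts that must never surface as NATs. `"smoke"` halves the counts.
#'
#' @param preset `"full"` or `"smoke"`.
#' @param ... Named overrides of the returned list elements.
#' @return A named list of generator settings.
#' @export
fixtureConfig <- function(preset = c("full", "smoke"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_divergent = 6L, n_convergent = 5L, n_s_contains_n = 4L, n_n_contains_s = 3L,
    multiplex = TRUE,
    n_trans = 3L,
    n_background_genes = 20L, n_intergenic_tx = 3L, n_sense_tx = 3L,
    n_scaffolds = 3L, gc = 0.5,
    n_terms = 8L, enriched_term_size = 10L, enriched_term_st = 9L,
    n_corr_pos = 4L, n_corr_neg = 2L)
  if (preset == "smoke") {
    cfg$n_divergent <- 3L; cfg$n_convergent <- 2L
    cfg$n_s_contains_n <- 2L; cfg$n_n_contains_s <- 1L
    cfg$n_trans <- 2L; cfg$n_background_genes <- 10L
    cfg$n_intergenic_tx <- 2L; cfg$n_sense_tx <- 2L
    cfg$n_corr_pos <- 2L; cfg$n_corr_neg <- 1L
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Generate a seeded synthetic fixture with planted ground truth
#'
#' Emits a small multi-scaffold genome (FASTA), stranded predicted genes
#' (GFF3), assembled transcripts (GTF), a 3-stage RPKM matrix (TSV), the four
#' evidence tables (TSV) and a gene-to-term annotation map (TSV), together
#' with a truth record of everything planted. The same seed always yields a
#' byte-identical bundle. Planted antisense transcripts cover all four cis
#' configurations and the 1:n / n:1 / n:n relationship motifs; remote
#' reverse-complement segments yield trans pairs; decoys each violate exactly
#' one pipeline criterion:
#' \itemize{
#'   \item cis overlap decoy: 5 percent overlap of both transcripts (rule: >= 10 percent of either);
#'   \item length decoy: 150 nt (rule: > 200 nt);
#'   \item ORF decoy: a planted 150-aa ORF (rule: <= 100 aa);
#'   \item protein-hit decoy: nr e-value 1e-5 (cutoff 1e-3);
#'   \item coding-potential decoy: score +1.5 (keep requires < 0);
#'   \item housekeeping decoy: e-value 1e-12 and small-RNA decoy: 1e-15 (cutoff 1e-10);
#'   \item trans 90-nt decoy: complementary region of 90 nt (rule: > 100 nt);
#'   \item trans coverage decoy: 120-nt region covering 20 percent of both (rule: > 50 percent of either);
#'   \item trans bubble decoy: a 40-column bubble in a 280-column duplex, 14.3 percent (rule: <= 10 percent).
#' }
#' Every planted transcript sequence is rejection-sampled to carry no ORF
#' longer than 100 aa, so only the ORF decoy exercises that filter.
#'
#' @param config A [fixtureConfig()] list.
#' @param seed Integer seed fixing all randomness.
#' @param dir Output directory (created if needed).
#' @return A [SyntheticFixture-class] with `files` (named paths: `genome`,
#'   `genes`, `transcripts`, `expression`, `nr`, `cpc`, `housekeeping`,
#'   `smallrna`, `annotation`) and `truth` (tables `cis`, `trans`,
#'   `candidates`, `presence`, `correlations`, plus `enriched_term`,
#'   `st_ids`, `total_genes`).
#' @examples
#' \donttest{
#' fx <- generateFixture(fixtureConfig("smoke"), seed = 1L, dir = tempfile())
#' fx
#' }
#' @export
generateFixture <- function(config = fixtureConfig(), seed = 1L,
                            dir = tempfile("natfix")) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  gl_n <- 0L; at_n <- 0L
  newGL <- function() { gl_n <<- gl_n + 1L; sprintf("GL%05d", gl_n) }
  newAT <- function() { at_n <<- at_n + 1L; sprintf("AT%05d", at_n) }
  segs <- list()
  cis_truth <- list(); trans_truth <- list(); cand_truth <- list()

  addSeg <- function(seq, feats) segs[[length(segs) + 1L]] <<- list(seq = seq, feats = feats)
  feat <- function(id, ftype, start, end, strand, exon2 = NULL)
    data.frame(id = id, ftype = ftype, start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)

  # own-strand sequence of a feature within a segment
  ownSeq <- function(seq, f) {
    s <- substr(seq, f$start, f$end)
    if (f$strand == "-") .revcomp(s) else s
  }
  # regenerate a segment's random sequence until no listed feature carries
  # an ORF longer than 100 aa (keeps the ORF filter exercised only by its decoy)
  scrub <- function(len, feats_chk, gc) {
    for (i in 1:200) {
      seq <- .randSeq(len, gc)
      ok <- all(vapply(seq_len(nrow(feats_chk)), function(k)
        maxOrfLength(ownSeq(seq, feats_chk[k, ])) <= 100L, logical(1)))
      if (ok) return(seq)
    }
    stop("could not scrub ORFs from a segment; genome too small for requested counts")
  }

  cisLocus <- function(type, decoy = NA_character_) {
    st <- newGL(); nat <- newAT()
    if (type == "divergent") {
      nat_len <- sample(250:700, 1L); st_len <- sample(800:1500, 1L)
      ov <- max(30L, round(stats::runif(1, 0.15, 0.5) * nat_len))
      ns <- 51L; ne <- ns + nat_len - 1L
      ss <- ne - ov + 1L; se <- ss + st_len - 1L
    } else if (type == "convergent") {
      nat_len <- sample(250:700, 1L); st_len <- sample(800:1500, 1L)
      ov <- max(30L, round(stats::runif(1, 0.15, 0.5) * nat_len))
      ss <- 51L; se <- ss + st_len - 1L
      ns <- se - ov + 1L; ne <- ns + nat_len - 1L
    } else if (type == "S_contains_N") {
      nat_len <- sample(250:600, 1L); st_len <- nat_len + sample(400:900, 1L)
      ss <- 51L; se <- ss + st_len - 1L
      ns <- ss + sample(20:(st_len - nat_len - 20L), 1L); ne <- ns + nat_len - 1L
      ov <- nat_len
    } else if (type == "N_contains_S") {
      st_len <- sample(300:600, 1L); nat_len <- st_len + sample(400:900, 1L)
      ns <- 51L; ne <- ns + nat_len - 1L
      ss <- ns + sample(20:(nat_len - st_len - 20L), 1L); se <- ss + st_len - 1L
      ov <- st_len
    } else if (type == "overlap_decoy") {
      st_len <- 1000L; nat_len <- 900L; ov <- 50L   # 5% of ST, 5.6% of NAT
      ss <- 51L; se <- ss + st_len - 1L
      ns <- se - ov + 1L; ne <- ns + nat_len - 1L
      type <- "convergent"
    } else if (type == "orf_decoy") {
      # long enough to hold the 456-nt ORF cassette intact
      st_len <- 1200L; nat_len <- 550L; ov <- 150L
      ss <- 51L; se <- ss + st_len - 1L
      ns <- se - ov + 1L; ne <- ns + nat_len - 1L
      type <- "convergent"
    } else if (type == "length_decoy") {
      st_len <- 900L; nat_len <- 150L; ov <- 60L    # admitted (40% of NAT), fails length
      ss <- 51L; se <- ss + st_len - 1L
      ns <- se - ov + 1L; ne <- ns + nat_len - 1L
      type <- "convergent"
    } else stop("unknown cis locus type")
    fts <- rbind(feat(st, "gene", ss, se, "+"), feat(nat, "tx", ns, ne, "-"))
    len <- max(fts$end) + 50L
    sq <- scrub(len, fts[fts$ftype == "tx", , drop = FALSE], config$gc)
    if (!is.na(decoy) && decoy == "orf") {
      # overwrite the NAT's own-strand sequence with a 150-aa ORF cassette
      orf <- .randOrf(150L)
      natseq <- ownSeq(sq, fts[2L, ])
      substr(natseq, 21L, 20L + nchar(orf)) <- orf
      repl <- if (fts$strand[2L] == "-") .revcomp(natseq) else natseq
      substr(sq, fts$start[2L], fts$end[2L]) <- repl
    }
    addSeg(sq, fts)
    cis_truth[[length(cis_truth) + 1L]] <<- data.frame(
      st_id = st, nat_id = nat, config = type, overlap_len = ov,
      frac_of_st = ov / st_len, frac_of_nat = ov / nat_len,
      relation = "1:1",
      admitted = max(ov / st_len, ov / nat_len) >= 0.10,
      stringsAsFactors = FALSE)
    cand_truth[[length(cand_truth) + 1L]] <<- data.frame(
      id = nat, kind = "cis", decoy = decoy,
      expect_candidate = max(ov / st_len, ov / nat_len) >= 0.10,
      expect_final = is.na(decoy), stringsAsFactors = FALSE)
    nat
  }

  # --- simple cis pairs, four configurations -------------------------------
  plain_nats <- character(0)
  for (i in seq_len(config$n_divergent)) plain_nats <- c(plain_nats, cisLocus("divergent"))
  for (i in seq_len(config$n_convergent)) plain_nats <- c(plain_nats, cisLocus("convergent"))
  for (i in seq_len(config$n_s_contains_n)) plain_nats <- c(plain_nats, cisLocus("S_contains_N"))
  for (i in seq_len(config$n_n_contains_s)) plain_nats <- c(plain_nats, cisLocus("N_contains_S"))

  # --- multiplex relationship motifs ---------------------------------------
  if (isTRUE(config$multiplex)) {
    # 1:n — one ST, two embedded NATs
    st <- newGL(); a1 <- newAT(); a2 <- newAT()
    fts <- rbind(feat(st, "gene", 51L, 2050L, "+"),
                 feat(a1, "tx", 151L, 450L, "-"),
                 feat(a2, "tx", 651L, 950L, "-"))
    addSeg(scrub(2100L, fts[-1L, ], config$gc), fts)
    for (a in c(a1, a2)) {
      cis_truth[[length(cis_truth) + 1L]] <- data.frame(
        st_id = st, nat_id = a, config = "S_contains_N", overlap_len = 300L,
        frac_of_st = 300 / 2000, frac_of_nat = 1, relation = "1:n",
        admitted = TRUE, stringsAsFactors = FALSE)
      cand_truth[[length(cand_truth) + 1L]] <- data.frame(
        id = a, kind = "cis", decoy = NA_character_,
        expect_candidate = TRUE, expect_final = TRUE, stringsAsFactors = FALSE)
    }
    # n:1 — one NAT bridging two STs
    g1 <- newGL(); g2 <- newGL(); a <- newAT()
    fts <- rbind(feat(g1, "gene", 51L, 850L, "+"),
                 feat(g2, "gene", 1051L, 1850L, "+"),
                 feat(a, "tx", 751L, 1150L, "-"))
    addSeg(scrub(1900L, fts[3L, , drop = FALSE], config$gc), fts)
    cis_truth[[length(cis_truth) + 1L]] <- data.frame(
      st_id = g1, nat_id = a, config = "convergent", overlap_len = 100L,
      frac_of_st = 100 / 800, frac_of_nat = 100 / 400, relation = "n:1",
      admitted = TRUE, stringsAsFactors = FALSE)
    cis_truth[[length(cis_truth) + 1L]] <- data.frame(
      st_id = g2, nat_id = a, config = "divergent", overlap_len = 100L,
      frac_of_st = 100 / 800, frac_of_nat = 100 / 400, relation = "n:1",
      admitted = TRUE, stringsAsFactors = FALSE)
    cand_truth[[length(cand_truth) + 1L]] <- data.frame(
      id = a, kind = "cis", decoy = NA_character_,
      expect_candidate = TRUE, expect_final = TRUE, stringsAsFactors = FALSE)
    # n:n — two overlapping STs, two NATs each bridging both
    g1 <- newGL(); g2 <- newGL(); a1 <- newAT(); a2 <- newAT()
    fts <- rbind(feat(g1, "gene", 51L, 1350L, "+"),
                 feat(g2, "gene", 951L, 2250L, "+"),
                 feat(a1, "tx", 851L, 1100L, "-"),
                 feat(a2, "tx", 1111L, 1360L, "-"))
    addSeg(scrub(2300L, fts[3:4, ], config$gc), fts)
    nn <- rbind(
      data.frame(st_id = g1, nat_id = a1, config = "S_contains_N",
                 overlap_len = 250L, frac_of_st = 250 / 1300, frac_of_nat = 1),
      data.frame(st_id = g2, nat_id = a1, config = "divergent",
                 overlap_len = 150L, frac_of_st = 150 / 1300, frac_of_nat = 150 / 250),
      data.frame(st_id = g1, nat_id = a2, config = "convergent",
                 overlap_len = 240L, frac_of_st = 240 / 1300, frac_of_nat = 240 / 250),
      data.frame(st_id = g2, nat_id = a2, config = "S_contains_N",
                 overlap_len = 250L, frac_of_st = 250 / 1300, frac_of_nat = 1))
    nn$relation <- "n:n"; nn$admitted <- TRUE
    for (k in seq_len(nrow(nn)))
      cis_truth[[length(cis_truth) + 1L]] <- nn[k, ]
    for (a in c(a1, a2))
      cand_truth[[length(cand_truth) + 1L]] <- data.frame(
        id = a, kind = "cis", decoy = NA_character_,
        expect_candidate = TRUE, expect_final = TRUE, stringsAsFactors = FALSE)
  }

  # --- cis decoys -----------------------------------------------------------
  cisLocus("overlap_decoy", decoy = "overlap")
  cisLocus("overlap_decoy", decoy = "overlap")
  cisLocus("length_decoy", decoy = "length")
  orf_decoy <- cisLocus("orf_decoy", decoy = "orf")
  nr_decoy <- cisLocus("divergent", decoy = "nr")
  cpc_decoy <- cisLocus("convergent", decoy = "cpc")
  hk_decoy <- cisLocus("divergent", decoy = "housekeeping")
  sm_decoy <- cisLocus("convergent", decoy = "smallrna")

  # --- trans pairs and decoys ----------------------------------------------
  transLocus <- function(class) {
    st <- newGL(); nat <- newAT()
    if (class == "pass") {
      g_len <- 300L; w <- c(51L, 250L); fl <- 30L
      for (i in 1:200) {
        gseq <- .randSeq(g_len, config$gc)
        tseq <- paste0(.randSeq(fl, config$gc),
                       .revcomp(substr(gseq, w[1L], w[2L])),
                       .randSeq(fl, config$gc))
        if (maxOrfLength(tseq) <= 100L && maxOrfLength(gseq) <= 100L) break
      }
      region_len <- 200L
    } else if (class == "trans_short") {
      g_len <- 300L; w <- c(106L, 195L); fl <- 40L   # 90-nt complement, 52.9% coverage
      for (i in 1:200) {
        gseq <- .randSeq(g_len, config$gc)
        tseq <- paste0(.randSeq(fl, config$gc),
                       .revcomp(substr(gseq, w[1L], w[2L])),
                       .randSeq(fl, config$gc))
        if (maxOrfLength(tseq) <= 100L) break
      }
      region_len <- 90L
    } else if (class == "trans_coverage") {
      g_len <- 600L; w <- c(241L, 360L); fl <- 240L  # 120-nt region, 20% of both
      for (i in 1:200) {
        gseq <- .randSeq(g_len, config$gc)
        tseq <- paste0(.randSeq(fl, config$gc),
                       .revcomp(substr(gseq, w[1L], w[2L])),
                       .randSeq(fl, config$gc))
        if (maxOrfLength(tseq) <= 100L) break
      }
      region_len <- 120L
    } else if (class == "trans_bubble") {
      # 160-nt clean region (53% of the transcript) + 40-nt insert + 80-nt
      # continuation: duplex bubble 40/280 = 14.3% > 10%
      g_len <- 320L
      for (i in 1:200) {
        gseq <- .randSeq(g_len, config$gc)
        w_full <- substr(gseq, 31L, 270L)            # 240 nt contiguous window
        rcw <- .revcomp(w_full)
        tseq <- paste0(.randSeq(10L, config$gc), substr(rcw, 1L, 160L),
                       .randSeq(40L, config$gc), substr(rcw, 161L, 240L),
                       .randSeq(10L, config$gc))
        if (maxOrfLength(tseq) <= 100L) break
      }
      region_len <- 160L
    } else stop("unknown trans class")
    g_id <- st; t_id <- nat
    addSeg(gseq, feat(g_id, "gene", 1L, nchar(gseq), "+"))
    addSeg(tseq, feat(t_id, "tx", 1L, nchar(tseq), "+"))
    trans_truth[[length(trans_truth) + 1L]] <<- data.frame(
      st_id = g_id, nat_id = t_id, region_len = region_len,
      coverage_st = region_len / nchar(gseq),
      coverage_nat = region_len / nchar(tseq),
      class = class, expect_pair = class == "pass", stringsAsFactors = FALSE)
    cand_truth[[length(cand_truth) + 1L]] <<- data.frame(
      id = t_id, kind = "trans", decoy = if (class == "pass") NA_character_ else class,
      expect_candidate = class == "pass", expect_final = class == "pass",
      stringsAsFactors = FALSE)
    t_id
  }
  for (i in seq_len(config$n_trans)) transLocus("pass")
  transLocus("trans_short"); transLocus("trans_coverage"); transLocus("trans_bubble")

  # --- background genes, sense and intergenic transcripts -------------------
  bg_genes <- character(0)
  for (i in seq_len(config$n_background_genes)) {
    id <- newGL(); bg_genes <- c(bg_genes, id)
    len <- sample(600:2000, 1L)
    if (i <= 2L) {  # two spliced genes for format realism
      e1 <- sample(200:500, 1L); gap <- sample(60:120, 1L)
      f <- feat(id, "gene", 51L, 50L + len, sample(c("+", "-"), 1L))
      f$exon_starts <- paste(c(51L, 51L + e1 + gap), collapse = ",")
      f$exon_ends <- paste(c(50L + e1, 50L + len), collapse = ",")
      addSeg(.randSeq(len + 100L, config$gc), f)
    } else {
      addSeg(.randSeq(len + 100L, config$gc),
             feat(id, "gene", 51L, 50L + len, sample(c("+", "-"), 1L)))
    }
  }
  for (i in seq_len(config$n_sense_tx)) {
    # same-strand transcript over a gene: merges into the gene's unit
    id <- newGL(); tx <- newAT()
    len <- sample(700:1200, 1L)
    fts <- rbind(feat(id, "gene", 51L, 50L + len, "+"),
                 feat(tx, "tx", 101L, 150L + len, "+"))
    addSeg(.randSeq(len + 250L, config$gc), fts)
    bg_genes <- c(bg_genes, id)
  }
  for (i in seq_len(config$n_intergenic_tx)) {
    tx <- newAT()
    len <- sample(300:900, 1L)
    sq <- NULL
    fts <- feat(tx, "tx", 51L, 50L + len, sample(c("+", "-"), 1L))
    addSeg(scrub(len + 100L, fts, config$gc), fts)
  }

  # --- place segments on scaffolds -----------------------------------------
  nsc <- config$n_scaffolds
  sc_seq <- rep("", nsc); sc_feats <- vector("list", nsc)
  for (k in seq_along(segs)) {
    sc <- ((k - 1L) %% nsc) + 1L
    spacer <- .randSeq(sample(300:800, 1L), config$gc)
    off <- nchar(sc_seq[sc]) + nchar(spacer)
    sc_seq[sc] <- paste0(sc_seq[sc], spacer, segs[[k]]$seq)
    f <- segs[[k]]$feats
    f$start <- f$start + off; f$end <- f$end + off
    if (!is.null(f$exon_starts)) {
      f$exon_starts <- vapply(f$exon_starts, function(s)
        paste(as.integer(strsplit(s, ",")[[1L]]) + off, collapse = ","), "")
      f$exon_ends <- vapply(f$exon_ends, function(s)
        paste(as.integer(strsplit(s, ",")[[1L]]) + off, collapse = ","), "")
    }
    f$scaffold <- sprintf("scaffold_%d", sc)
    sc_feats[[sc]] <- c(sc_feats[[sc]], list(f))
  }
  feats <- do.call(rbind, lapply(unlist(sc_feats, recursive = FALSE), function(f) {
    if (is.null(f$exon_starts)) { f$exon_starts <- NA_character_; f$exon_ends <- NA_character_ }
    f[, c("id", "ftype", "scaffold", "start", "end", "strand", "exon_starts", "exon_ends")]
  }))
  genome <- Biostrings::DNAStringSet(sc_seq)
  names(genome) <- sprintf("scaffold_%d", seq_len(nsc))

  toSet <- function(df, origin) {
    ex <- lapply(seq_len(nrow(df)), function(k) {
      r <- df[k, ]
      if (!is.na(r$exon_starts)) {
        s <- as.integer(strsplit(r$exon_starts, ",")[[1L]])
        e <- as.integer(strsplit(r$exon_ends, ",")[[1L]])
      } else { s <- r$start; e <- r$end }
      GRanges(r$scaffold, IRanges(s, e), strand = r$strand)
    })
    names(ex) <- df$id
    TranscriptSet(GenomicRanges::GRangesList(ex), origin = origin)
  }
  genes <- toSet(feats[feats$ftype == "gene", ], "predicted_gene")
  txs <- toSet(feats[feats$ftype == "tx", ], "assembled")

  cis <- do.call(rbind, cis_truth)
  trans <- do.call(rbind, trans_truth)
  cands <- do.call(rbind, cand_truth)
  cands$is_decoy <- !is.na(cands$decoy)

  # --- expression: presence classes and planted correlations ---------------
  stages_v <- c("M", "P", "FB")
  final_cis <- unique(cands$id[cands$kind == "cis" & cands$expect_final])
  final_trans <- unique(cands$id[cands$kind == "trans" & cands$expect_final])
  # correlation pairs drawn from the simple 1:1 cis pairs
  ok11 <- cis[cis$relation == "1:1" & cis$admitted &
                cis$nat_id %in% final_cis, c("st_id", "nat_id")]
  n_pos <- min(config$n_corr_pos, nrow(ok11))
  n_neg <- min(config$n_corr_neg, nrow(ok11) - n_pos)
  corr <- data.frame(st_id = ok11$st_id[seq_len(n_pos + n_neg)],
                     nat_id = ok11$nat_id[seq_len(n_pos + n_neg)],
                     sign = rep(c(1L, -1L), c(n_pos, n_neg)),
                     stringsAsFactors = FALSE)
  all_ids <- c(txIds(genes), txIds(txs))
  expr <- matrix(0, length(all_ids), 3L,
                 dimnames = list(all_ids, stages_v))
  jit <- function(v) v * exp(stats::rnorm(length(v), 0, 0.05))
  for (id in all_ids) expr[id, ] <- jit(stats::runif(3, 3, 60))
  up <- c(4, 16, 64)   # monotone, comfortably above the RPKM >= 2 cutoff
  for (k in seq_len(nrow(corr))) {
    expr[corr$st_id[k], ] <- jit(if (corr$sign[k] > 0) up else rev(up))
    expr[corr$nat_id[k], ] <- jit(up * stats::runif(1, 0.8, 2))
  }
  regions7 <- c("M", "P", "FB", "M&P", "M&FB", "P&FB", "M&P&FB")
  presence <- data.frame(id = character(0), region = character(0))
  corr_nats <- corr$nat_id
  other_nats <- setdiff(c(final_cis, final_trans), corr_nats)
  assignRegion <- function(id, region) {
    on <- strsplit(region, "&", fixed = TRUE)[[1L]]
    v <- stats::setNames(jit(stats::runif(3, 0.1, 1.2)), stages_v)
    v[on] <- jit(stats::runif(length(on), 5, 60))
    expr[id, ] <<- v[stages_v]
    presence <<- rbind(presence, data.frame(id = id, region = region))
  }
  for (k in seq_along(other_nats))
    assignRegion(other_nats[k], regions7[((k - 1L) %% 7L) + 1L])
  for (id in corr_nats)
    presence <- rbind(presence, data.frame(id = id, region = "M&P&FB"))
  se <- StageExpression(round(expr, 4), unit = "RPKM")

  # --- evidence tables ------------------------------------------------------
  all_cands <- cands$id[cands$expect_candidate | cands$kind == "cis"]
  cpc_tab <- data.frame(id = sort(unique(all_cands)),
                        score = round(stats::runif(length(unique(all_cands)), -3, -0.2), 3))
  cpc_tab$score[cpc_tab$id == cpc_decoy] <- 1.5
  boundary_ids <- utils::head(plain_nats, 2L)   # near-cutoff non-hits must be kept
  nr_tab <- data.frame(id = c(nr_decoy, boundary_ids),
                       evalue = c(1e-5, 1e-2, 5e-1))
  hk_tab <- data.frame(id = c(hk_decoy, utils::head(plain_nats, 1L)),
                       evalue = c(1e-12, 1e-8))
  sm_tab <- data.frame(id = sm_decoy, evalue = 1e-15)

  # --- annotation map with one over-represented term ------------------------
  st_ids <- unique(cis$st_id[cis$admitted & cis$nat_id %in% final_cis])
  gene_ids <- txIds(genes)
  n_st_in <- min(config$enriched_term_st, length(st_ids))
  enr_genes <- c(st_ids[seq_len(n_st_in)],
                 sample(setdiff(gene_ids, st_ids),
                        config$enriched_term_size - n_st_in))
  ann <- data.frame(gene_id = enr_genes, term_id = "T0001",
                    term_name = "planted enriched category",
                    stringsAsFactors = FALSE)
  for (t in seq_len(config$n_terms - 1L)) {
    sz <- sample(8:16, 1L)
    ann <- rbind(ann, data.frame(
      gene_id = sample(setdiff(gene_ids, enr_genes), sz),
      term_id = sprintf("T%04d", t + 1L),
      term_name = sprintf("background category %d", t),
      stringsAsFactors = FALSE))
  }

  # --- write the bundle -----------------------------------------------------
  files <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             transcripts = file.path(dir, "transcripts.gtf"),
             expression = file.path(dir, "expression.tsv"),
             nr = file.path(dir, "nr.tsv"),
             cpc = file.path(dir, "cpc.tsv"),
             housekeeping = file.path(dir, "housekeeping.tsv"),
             smallrna = file.path(dir, "smallrna.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  Biostrings::writeXStringSet(genome, files["genome"], width = 80L)
  writeGeneModels(genes, files["genes"])
  writeTranscriptsGTF(txs, files["transcripts"])
  writeExpression(se, files["expression"])
  .writeTsv(nr_tab, files["nr"])
  .writeTsv(cpc_tab, files["cpc"])
  .writeTsv(hk_tab, files["housekeeping"])
  .writeTsv(sm_tab, files["smallrna"])
  .writeTsv(ann, files["annotation"])

  methods::new("SyntheticFixture", dir = dir, files = files, seed = seed,
    truth = list(
      cis = cis, trans = trans, candidates = cands,
      presence = presence, correlations = corr,
      enriched_term = "T0001", st_ids = st_ids,
      total_genes = length(gene_ids)))
}
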