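# Independent brute-force oracles and small fixture builders shared by the
# suite. Oracles deliberately use different mechanics than the implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(x) as.character(reverseComplement(DNAString(x)))

# single-exon TranscriptSet from a coordinate table
make_models <- function(df, origin = "assembled") {
  ex <- lapply(seq_len(nrow(df)), function(k)
    GRanges(df$scaffold[k], IRanges(df$start[k], df$end[k]), strand = df$strand[k]))
  names(ex) <- df$id
  TranscriptSet(GRangesList(ex), origin = origin)
}

# random single-exon interval table
rand_intervals <- function(n, scaffolds = 2L, max_pos = 5000L) {
  st <- sample(seq_len(max_pos), n, replace = TRUE)
  w <- sample(50:800, n, replace = TRUE)
  data.frame(id = sprintf("x%04d", seq_len(n)),
             scaffold = sample(paste0("s", seq_len(scaffolds)), n, TRUE),
             start = st, end = st + w - 1L,
             strand = sample(c("+", "-"), n, TRUE),
             stringsAsFactors = FALSE)
}

# --- oracle: connected overlap components by breadth-first search -----------
bf_cluster <- function(df) {
  n <- nrow(df)
  adj <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (df$scaffold[i] == df$scaffold[j] && df$strand[i] == df$strand[j] &&
        df$start[i] <= df$end[j] && df$start[j] <= df$end[i])
      adj[[i]] <- c(adj[[i]], j)
  }
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  split(df$id, comp)
}

# --- oracle: all-pairs cis admission ----------------------------------------
bf_cis <- function(genes_df, nats_df, min_frac = 0.10, rule = "any") {
  out <- list()
  for (i in seq_len(nrow(genes_df))) for (j in seq_len(nrow(nats_df))) {
    g <- genes_df[i, ]; u <- nats_df[j, ]
    if (g$scaffold != u$scaffold || g$strand == u$strand) next
    os <- max(g$start, u$start); oe <- min(g$end, u$end)
    if (oe < os) next
    ov <- oe - os + 1L
    fs <- ov / (g$end - g$start + 1L); fn <- ov / (u$end - u$start + 1L)
    ok <- if (rule == "any") fs >= min_frac || fn >= min_frac
          else fs >= min_frac && fn >= min_frac
    if (ok) out[[length(out) + 1L]] <- data.frame(st_id = g$id, nat_id = u$id,
                                                  overlap_len = ov,
                                                  frac_of_st = fs, frac_of_nat = fn)
  }
  if (!length(out)) return(data.frame(st_id = character(0), nat_id = character(0)))
  do.call(rbind, out)
}

# --- oracle: exact reverse-complement runs by substring hashing -------------
# enumerates all min_len-mers of a and of revcomp(b), pairs equal strings,
# chains diagonal-adjacent pairs and reports maximal runs >= min_len
bf_complementary <- function(a, b, min_len) {
  na <- nchar(a); nb <- nchar(b)
  if (na < min_len || nb < min_len)
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0), length = integer(0)))
  rcb <- revcomp_chr(b)
  ka <- substring(a, 1:(na - min_len + 1L), min_len:na)
  kb <- substring(rcb, 1:(nb - min_len + 1L), min_len:nb)
  hits <- which(outer(ka, kb, "=="), arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0), length = integer(0)))
  d <- hits[, 1L] - hits[, 2L]
  out <- list()
  for (dg in sort(unique(d))) {
    ii <- sort(hits[d == dg, 1L])
    # maximal chains of consecutive window starts
    brk <- c(0L, which(diff(ii) != 1L), length(ii))
    for (k in seq_len(length(brk) - 1L)) {
      run <- ii[(brk[k] + 1L):brk[k + 1L]]
      a_start <- run[1L]; a_end <- run[length(run)] + min_len - 1L
      rc_start <- a_start - dg; rc_end <- a_end - dg
      out[[length(out) + 1L]] <- data.frame(
        a_start = a_start, a_end = a_end,
        b_start = nb - rc_end + 1L, b_end = nb - rc_start + 1L,
        length = a_end - a_start + 1L)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- oracle: every ATG..stop pair in the three forward frames ---------------
bf_max_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (s in seq_len(max(0L, n - 5L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    p <- s + 3L
    while (p + 2L <= n) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (p - s) %/% 3L)
        break
      }
      p <- p + 3L
    }
  }
  best
}

# --- oracle: exact hypergeometric upper tail by term enumeration ------------
# choose() products stay exactly representable for population <= 24
bf_hyper_tail <- function(pop, succ, draws, x) {
  i <- x:min(succ, draws)
  sum(choose(succ, i) * choose(pop - succ, draws - i)) / choose(pop, draws)
}

# compare exon structure of two TranscriptSets (ignoring factor levels)
expect_same_models <- function(a, b) {
  expect_setequal(txIds(a), txIds(b))
  for (id in txIds(a)) {
    ea <- txExons(a)[[id]]; eb <- txExons(b)[[id]]
    expect_equal(start(ea), start(eb))
    expect_equal(end(ea), end(eb))
    expect_equal(as.character(seqnames(ea)), as.character(seqnames(eb)))
    expect_equal(as.character(strand(ea)), as.character(strand(eb)))
  }
}

# shared smoke fixture, generated once per test run
smoke_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- generateFixture(fixtureConfig("smoke"), seed = 42L,
                                            dir = file.path(tempdir(), "natseek_smoke"))
    fx
  }
})
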