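test_that("planted exact complements are found with correct coordinates", {
  set.seed(41)
  a <- rand_dna(500)
  b <- paste0(rand_dna(60), revcomp_chr(substr(a, 201, 350)), rand_dna(40))
  r <- findComplementaryRegions(a, b, min_len = 100)
  expect_equal(nrow(r), 1L)
  expect_gte(r$length, 150L)
  expect_true(r$a_start <= 201 && r$a_end >= 350)
  # in exact mode the reported windows are exact reverse complements
  rx <- findComplementaryRegions(a, b, min_len = 100, min_identity = 1)
  expect_equal(nrow(rx), 1L)
  expect_gte(rx$length, 150L)
  expect_equal(substr(a, rx$a_start, rx$a_end),
               revcomp_chr(substr(b, rx$b_start, rx$b_end)))
})

test_that("min_len threshold semantics: a 90-nt complement needs min_len <= 90", {
  set.seed(42)
  a <- rand_dna(400)
  b <- paste0(rand_dna(50), revcomp_chr(substr(a, 101, 190)), rand_dna(50))
  expect_equal(nrow(findComplementaryRegions(a, b, min_len = 100)), 0L)
  r <- findComplementaryRegions(a, b, min_len = 80)
  expect_equal(nrow(r), 1L)
  expect_gte(r$length, 90L)
})

test_that("independent random sequences share no long complementary region", {
  set.seed(43)
  hits <- vapply(1:120, function(i) {
    nrow(findComplementaryRegions(rand_dna(500), rand_dna(500), min_len = 100))
  }, 0L)
  expect_true(all(hits == 0L))
})

test_that("exact-mode search equals the brute-force all-substring scan", {
  set.seed(44)
  for (rep in 1:12) {
    a <- rand_dna(sample(150:300, 1L))
    b <- rand_dna(sample(150:300, 1L))
    # plant 0-2 complements of varying length
    for (k in seq_len(sample(0:2, 1L))) {
      len <- sample(30:80, 1L)
      ai <- sample(seq_len(nchar(a) - len), 1L)
      bi <- sample(seq_len(nchar(b) - len), 1L)
      substr(b, bi, bi + len - 1L) <- revcomp_chr(substr(a, ai, ai + len - 1L))
    }
    got <- findComplementaryRegions(a, b, min_len = 25, seed_len = 12,
                                    min_identity = 1)
    want <- bf_complementary(a, b, min_len = 25)
    expect_equal(as.data.frame(got)[, c("a_start", "a_end", "b_start", "b_end")],
                 want[, c("a_start", "a_end", "b_start", "b_end")])
  }
})

test_that("single mismatches are bridged only while identity stays at the floor", {
  set.seed(45)
  a <- rand_dna(400)
  core <- substr(a, 101, 250)  # 150 nt
  b_clean <- paste0(rand_dna(50), revcomp_chr(core), rand_dna(50))
  # corrupt one interior base of the complement
  b <- b_clean
  pos <- 50 + 75
  substr(b, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                 substr(b, pos, pos))[1L]
  r <- findComplementaryRegions(a, b, min_len = 100, min_identity = 0.8)
  expect_equal(nrow(r), 1L)
  expect_gte(r$length, 150L)
  expect_lt(r$identity, 1)
  # with identity floor 1 the mismatch splits the region below min_len
  r2 <- findComplementaryRegions(a, b, min_len = 100, min_identity = 1)
  expect_equal(nrow(r2), 0L)
})

test_that("duplex annealing applies the 10% bubble rule arithmetic", {
  set.seed(46)
  gene <- rand_dna(300)
  # perfect 200-nt complement: no bubbles, passes
  tx <- paste0(rand_dna(30), revcomp_chr(substr(gene, 51, 250)), rand_dna(30))
  seed <- findComplementaryRegions(gene, tx, min_len = 100)[1L, ]
  d <- annealDuplex(gene, tx, seed)
  expect_true(d$passes)
  expect_true(d$coincides)

  # 200-nt complement with a 15-nt unpaired insertion: 15/215 = 7.0% passes
  rc <- revcomp_chr(substr(gene, 51, 250))
  tx15 <- paste0(rand_dna(30), substr(rc, 1, 100), rand_dna(15),
                 substr(rc, 101, 200), rand_dna(30))
  seed15 <- findComplementaryRegions(gene, tx15, min_len = 80)
  seed15 <- seed15[order(-seed15$length), ][1L, ]
  d15 <- annealDuplex(gene, tx15, seed15)
  expect_true(d15$coincides)
  expect_true(any(d15$bubbles >= 15L))
  expect_lte(max(d15$bubbles) / d15$region_len, 0.10)
  expect_true(d15$passes)

  # a 25-nt bubble: 25/225 = 11.1% fails
  tx25 <- paste0(rand_dna(30), substr(rc, 1, 100), rand_dna(25),
                 substr(rc, 101, 200), rand_dna(30))
  seed25 <- findComplementaryRegions(gene, tx25, min_len = 80)
  seed25 <- seed25[order(-seed25$length), ][1L, ]
  d25 <- annealDuplex(gene, tx25, seed25)
  expect_gt(max(d25$bubbles) / d25$region_len, 0.10)
  expect_false(d25$passes)
})

test_that("trans candidate search enforces remoteness, length, coverage and bubbles", {
  fx <- smoke_fixture()
  genome <- readGenome(fx@files["genome"])
  genes <- readGeneModels(fx@files["genes"])
  txs <- readAssembledTranscripts(fx@files["transcripts"])
  pairs <- findTransCandidates(genes, txs, genome)

  truth <- fx@truth$trans
  want <- truth[truth$expect_pair, c("st_id", "nat_id")]
  expect_setequal(paste(pairs$st_id, pairs$nat_id),
                  paste(want$st_id, want$nat_id))
  # filter soundness on every reported pair
  expect_true(all(pairs$region_len > 100))
  expect_true(all(pairs$passes))
  expect_true(all(pairs$coverage_st > 0.5 | pairs$coverage_nat > 0.5))
  # decoys (90-nt, low-coverage, bubbled) are all rejected
  decoys <- truth$nat_id[!truth$expect_pair]
  expect_length(intersect(pairs$nat_id, decoys), 0L)
  # cis-overlapping antisense loci are excluded by the remote requirement
  expect_length(intersect(pairs$nat_id,
                          fx@truth$candidates$id[fx@truth$candidates$kind == "cis"]), 0L)
})

test_that("raising min_len never adds pairs; raising the bubble cap never removes them", {
  fx <- smoke_fixture()
  genome <- readGenome(fx@files["genome"])
  genes <- readGeneModels(fx@files["genes"])
  txs <- readAssembledTranscripts(fx@files["transcripts"])
  key <- function(p) paste(p$st_id, p$nat_id)
  base <- findTransCandidates(genes, txs, genome, natConfig())
  longer <- findTransCandidates(genes, txs, genome,
                                natConfig(trans_min_complement_nt = 180))
  expect_true(all(key(longer) %in% key(base)))
  looser <- findTransCandidates(genes, txs, genome,
                                natConfig(bubble_max_frac = 0.2))
  expect_true(all(key(base) %in% key(looser)))
})
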