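gr <- function(start, end, strand = "+", scaffold = "s1")
  GRanges(scaffold, IRanges(start, end), strand = strand)

test_that("configuration classification matches the four published classes", {
  # ST [100,500)+ with NAT at its 3' end -> convergent (tail-to-tail)
  expect_equal(classifyCisPair(gr(101, 500), gr(401, 600, "-")), "convergent")
  # NAT at the ST's 5' end -> divergent (head-to-head)
  expect_equal(classifyCisPair(gr(101, 500), gr(51, 150, "-")), "divergent")
  expect_equal(classifyCisPair(gr(101, 500), gr(151, 450, "-")), "S_contains_N")
  expect_equal(classifyCisPair(gr(101, 500), gr(51, 600, "-")), "N_contains_S")
  # minus-strand ST: 5' end is the right end
  expect_equal(classifyCisPair(gr(101, 500, "-"), gr(401, 600, "+")), "divergent")
  expect_equal(classifyCisPair(gr(101, 500, "-"), gr(51, 150, "+")), "convergent")

  expect_error(classifyCisPair(gr(101, 500), gr(601, 700, "-")), "overlap")
  expect_error(classifyCisPair(gr(101, 500), gr(401, 600, "+")), "opposite")
})

test_that("classification returns exactly one class and mirrors under strand flip", {
  set.seed(21)
  classes <- c("divergent", "convergent", "S_contains_N", "N_contains_S")
  for (i in 1:200) {
    s <- sort(sample(1:1000, 2L)); n <- sort(sample(1:1000, 2L))
    if (n[1L] > s[2L] || s[1L] > n[2L]) next  # need overlap
    st_strand <- sample(c("+", "-"), 1L)
    nat_strand <- setdiff(c("+", "-"), st_strand)
    cls <- classifyCisPair(gr(s[1L], s[2L], st_strand), gr(n[1L], n[2L], nat_strand))
    expect_true(cls %in% classes)
    # mirror the whole locus (reverse coordinates, flip strands): class preserved
    L <- 1001L
    mirrored <- classifyCisPair(gr(L - s[2L], L - s[1L], nat_strand),
                                gr(L - n[2L], L - n[1L], st_strand))
    expect_identical(cls, mirrored)
  }
})

test_that("cis admission follows the 10%-of-either rule", {
  genes <- make_models(data.frame(id = "g1", scaffold = "s1", start = 1,
                                  end = 1000, strand = "+"),
                       origin = "predicted_gene")
  # overlap 100 = 10% of gene, 33% of unit -> admitted
  nat <- make_models(data.frame(id = "t1", scaffold = "s1", start = 901,
                                end = 1200, strand = "-"))
  u <- buildTranscriptUnits(c(genes, nat))
  pairs <- findCisCandidates(u, genes)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$overlap_len, 100L)
  expect_equal(pairs$frac_of_st, 0.10)

  # overlap 5 bp = 0.5% and 0.25% -> rejected
  nat2 <- make_models(data.frame(id = "t1", scaffold = "s1", start = 996,
                                 end = 3000, strand = "-"))
  u2 <- buildTranscriptUnits(c(genes, nat2))
  expect_equal(nrow(findCisCandidates(u2, genes)), 0L)

  expect_error(findCisCandidates(u, genes, min_frac = 0), "min_frac")
  expect_error(findCisCandidates(u, genes, min_frac = 1.5), "min_frac")
})

test_that("admitted pairs equal the brute-force all-pairs filter", {
  set.seed(31)
  for (rep in 1:4) {
    gdf <- rand_intervals(40); gdf$id <- sprintf("g%03d", seq_len(nrow(gdf)))
    tdf <- rand_intervals(60); tdf$id <- sprintf("t%03d", seq_len(nrow(tdf)))
    genes <- make_models(gdf, origin = "predicted_gene")
    txs <- make_models(tdf, origin = "assembled")
    units <- buildTranscriptUnits(c(genes, txs))
    for (rule in c("any", "both")) {
      got <- findCisCandidates(units, genes, overlap_rule = rule)
      # oracle works on NAT-side units (gene-free units), like the method
      usp <- unitSpans(units)
      nat_units <- usp[!S4Vectors::mcols(usp)$contains_gene]
      udf <- data.frame(id = S4Vectors::mcols(nat_units)$unit_id,
                        scaffold = as.character(seqnames(nat_units)),
                        start = start(nat_units), end = end(nat_units),
                        strand = as.character(strand(nat_units)))
      want <- bf_cis(gdf, udf, rule = rule)
      expect_setequal(paste(got$st_id, got$nat_id),
                      paste(want$st_id, want$nat_id))
      if (nrow(got)) {
        key <- match(paste(got$st_id, got$nat_id), paste(want$st_id, want$nat_id))
        expect_equal(got$overlap_len, want$overlap_len[key])
        expect_equal(got$frac_of_st, want$frac_of_st[key])
        expect_equal(got$frac_of_nat, want$frac_of_nat[key])
      }
    }
  }
})

test_that("'both' rule admissions are a subset of 'any' rule admissions", {
  set.seed(32)
  gdf <- rand_intervals(40); gdf$id <- sprintf("g%03d", seq_len(nrow(gdf)))
  tdf <- rand_intervals(60); tdf$id <- sprintf("t%03d", seq_len(nrow(tdf)))
  genes <- make_models(gdf, origin = "predicted_gene")
  units <- buildTranscriptUnits(c(genes, make_models(tdf)))
  any_p <- findCisCandidates(units, genes, overlap_rule = "any")
  both_p <- findCisCandidates(units, genes, overlap_rule = "both")
  expect_true(all(paste(both_p$st_id, both_p$nat_id) %in%
                  paste(any_p$st_id, any_p$nat_id)))
})

test_that("overlap ratios are consistent and containment forces frac_of_nat = 1", {
  genes <- make_models(data.frame(id = "g1", scaffold = "s1", start = 1,
                                  end = 1000, strand = "+"),
                       origin = "predicted_gene")
  nat <- make_models(data.frame(id = "t1", scaffold = "s1", start = 301,
                                end = 600, strand = "-"))
  u <- buildTranscriptUnits(c(genes, nat))
  pairs <- findCisCandidates(u, genes)
  prof <- overlapRatioProfile(pairs)
  expect_equal(prof$frac_of_st, 0.3)
  expect_equal(prof$frac_of_nat, 1.0)
  expect_equal(prof$config, "S_contains_N")
  h <- configHistogram(pairs)
  expect_equal(sum(h$count), nrow(pairs))
})
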