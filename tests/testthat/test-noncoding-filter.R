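test_that("ORF scanning obeys the genetic code and the brute-force oracle", {
  expect_equal(maxOrfLength("ATGAAATAA"), 2L)      # Met-Lys
  expect_equal(maxOrfLength("CCCCCCCCC"), 0L)      # no ATG
  expect_equal(maxOrfLength("ATGAAAAAA"), 0L)      # no stop: not an ORF
  expect_equal(maxOrfLength("TATGAAATAAC"), 2L)    # frame 1

  set.seed(51)
  for (i in 1:500) {
    s <- rand_dna(600)
    expect_equal(maxOrfLength(s), bf_max_orf(s))
  }

  # planted ORFs of exact length are recovered on both strands when asked
  set.seed(52)
  orf <- natseek:::.randOrf(150L)
  s <- paste0(rand_dna(20), orf, rand_dna(20))
  expect_equal(maxOrfLength(s), 150L)
  rc <- revcomp_chr(s)
  expect_equal(maxOrfLength(rc, both_strands = TRUE), 150L)
})

test_that("the cascade enforces every boundary exactly", {
  cfg <- natConfig()
  mk <- function(len) paste(rep("C", len), collapse = "")  # no ORF, no ATG
  cand <- data.frame(
    id = c("len200", "len201", "orf100", "orf101"),
    kind = "cis",
    sequence = c(mk(200), mk(201),
                 paste0(mk(100), natseek:::.randOrf(100L), mk(100)),
                 paste0(mk(100), natseek:::.randOrf(101L), mk(100))),
    stringsAsFactors = FALSE)
  set.seed(53)
  rec <- applyNoncodingFilters(cand, evidenceTables(
    nr = c(none = 1), cpc = c(len200 = -1, len201 = -1, orf100 = -1, orf101 = -1),
    housekeeping = c(none = 1), smallrna = c(none = 1)), cfg)
  r <- as.data.frame(rec)
  rownames(r) <- r$id
  # "shorter than 200 bp removed" + criterion "length > 200": exactly 200 fails
  expect_false(r["len200", "step1_length"])
  expect_true(is.na(r["len200", "step2_orf"]))    # cascade stopped
  expect_equal(r["len200", "failed_at"], "length")
  expect_true(r["len201", "final"])
  # "more than 100 aa removed": exactly 100 passes, 101 fails
  expect_true(r["orf100", "final"])
  expect_equal(r["orf100", "max_orf_aa"], 100L)
  expect_false(r["orf101", "step2_orf"])
  expect_equal(r["orf101", "failed_at"], "orf")

  long <- mk(300)
  ev <- evidenceTables(
    nr = c(at_cut = 1e-3, above = 1.0001e-3),
    cpc = c(zero = 0, neg = -1e-9, at_cut = -1, above = -1, hk = -1, sm = -1),
    housekeeping = c(hk = 1e-10),
    smallrna = c(sm = 1e-11))
  cand2 <- data.frame(id = c("at_cut", "above", "zero", "neg", "hk", "sm"),
                      kind = "cis", sequence = long, stringsAsFactors = FALSE)
  r2 <- as.data.frame(applyNoncodingFilters(cand2, ev, cfg))
  rownames(r2) <- r2$id
  # nr hit at exactly the cutoff disqualifies; just above keeps
  expect_equal(r2["at_cut", "failed_at"], "nr_hit")
  expect_true(r2["above", "final"])
  # CPC score exactly 0 fails (keep requires < 0)
  expect_equal(r2["zero", "failed_at"], "coding_potential")
  expect_true(r2["neg", "final"])
  # housekeeping/small-RNA hits at the 1e-10 cutoff disqualify
  expect_equal(r2["hk", "failed_at"], "ncrna_hit")
  expect_equal(r2["sm", "failed_at"], "ncrna_hit")
})

test_that("a clean candidate with boundary-safe evidence passes all five steps", {
  set.seed(54)
  s <- rand_dna(300)
  while (maxOrfLength(s) > 40L) s <- rand_dna(300)
  rec <- applyNoncodingFilters(
    data.frame(id = "ok", kind = "cis", sequence = s),
    evidenceTables(nr = c(ok = 1e-2), cpc = c(ok = -0.5),
                   housekeeping = c(none = 1), smallrna = c(none = 1)),
    natConfig())
  expect_true(rec$final)
  expect_true(all(unlist(rec[1, c("step1_length", "step2_orf", "step3_nr",
                                  "step4_cpc", "step5_ncrna")])))
})

test_that("all 32 pass/fail combinations resolve to the first failing step", {
  cfg <- natConfig()
  set.seed(55)
  base <- rand_dna(400)
  while (maxOrfLength(base) > 100L) base <- rand_dna(400)
  grid <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                      f3 = c(FALSE, TRUE), f4 = c(FALSE, TRUE),
                      f5 = c(FALSE, TRUE))  # TRUE = make the step fail
  steps <- c("length", "orf", "nr_hit", "coding_potential", "ncrna_hit")
  for (k in seq_len(nrow(grid))) {
    f <- unlist(grid[k, ])
    seqk <- if (f[1L]) substr(base, 1, 150)
            else if (f[2L]) paste0(base, natseek:::.randOrf(120L))
            else base
    id <- "c"
    ev <- evidenceTables(
      nr = c(c = if (f[3L]) 1e-5 else 1),
      cpc = c(c = if (f[4L]) 0.5 else -0.5),
      housekeeping = c(c = if (f[5L]) 1e-12 else 1e-3),
      smallrna = c(none = 1))
    rec <- applyNoncodingFilters(data.frame(id = id, kind = "cis", sequence = seqk),
                                 ev, cfg)
    expect_equal(rec$final, !any(f))
    if (any(f)) {
      first <- which(f)[1L]
      expect_equal(rec$failed_at, steps[first])
      # steps after the first failure were never evaluated
      later <- c("step1_length", "step2_orf", "step3_nr", "step4_cpc",
                 "step5_ncrna")[seq_len(5L) > first]
      expect_true(all(is.na(unlist(rec[1, later]))))
    }
  }
})

test_that("absent evidence tables pass vacuously with a warning, or error in strict mode", {
  s <- paste(rep("C", 300), collapse = "")
  cand <- data.frame(id = "c", kind = "cis", sequence = s)
  expect_warning(rec <- applyNoncodingFilters(cand, evidenceTables(), natConfig()),
                 "absent")
  expect_true(rec$final)
  expect_error(applyNoncodingFilters(cand, evidenceTables(), natConfig(),
                                     strict = TRUE), "absent")
})

test_that("funnel counts are cumulative, split by kind, and non-increasing", {
  set.seed(56)
  s300 <- rand_dna(300)
  while (maxOrfLength(s300) > 100L) s300 <- rand_dna(300)
  cand <- data.frame(
    id = c("a", "b", "c", "d"),
    kind = c("cis", "cis", "trans", "trans"),
    sequence = c(s300, substr(s300, 1, 150), s300, s300),
    stringsAsFactors = FALSE)
  ev <- evidenceTables(nr = c(c = 1e-9), cpc = c(a = -1, c = -1, d = -1),
                       housekeeping = c(none = 1), smallrna = c(none = 1))
  fun <- filterFunnelCounts(applyNoncodingFilters(cand, ev, natConfig()))
  comb <- fun[fun$kind == "combined", ]
  expect_equal(comb$retained, c(3L, 3L, 2L, 2L, 2L))
  expect_equal(comb$entered - comb$retained, comb$discarded)
  expect_true(all(diff(comb$retained) <= 0))
  cis <- fun[fun$kind == "cis", ]
  expect_equal(cis$retained[1L], 1L)  # "b" fails length
  trans <- fun[fun$kind == "trans", ]
  expect_equal(trans$retained[3L], 1L)  # "c" has the nr hit
})
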