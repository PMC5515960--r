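test_that("GFF3 gene reading converts coordinates and handles edge cases", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scaf1\t.\tgene\t101\t200\t.\t+\t.\tID=g1"), gff)
  ts <- readGeneModels(gff)
  expect_equal(length(ts), 1L)
  sp <- txSpans(ts)
  # GFF3 101..200 is a 100-bp feature (0-based half-open [100, 200))
  expect_equal(start(sp), 101L)
  expect_equal(end(sp), 200L)
  expect_equal(width(sp), 100L)
  expect_equal(as.character(strand(sp)), "+")
  expect_equal(unname(txOrigin(ts)), "predicted_gene")

  # headers only -> empty set
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(length(readGeneModels(empty)), 0L)

  # unstranded record rejected with a warning
  writeLines(c("##gff-version 3",
               "scaf1\t.\tgene\t101\t200\t.\t.\t.\tID=g1",
               "scaf1\t.\tgene\t501\t900\t.\t-\t.\tID=g2"), gff)
  expect_warning(ts2 <- readGeneModels(gff), "without strand")
  expect_equal(txIds(ts2), "g2")

  # duplicate ID is a hard error
  writeLines(c("##gff-version 3",
               "scaf1\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
               "scaf1\t.\tgene\t501\t900\t.\t-\t.\tID=g1"), gff)
  expect_error(readGeneModels(gff), "duplicate")
})

test_that("GTF transcript reading groups and canonicalizes exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'scaf1\tasm\texon\t501\t600\t.\t+\t.\ttranscript_id "t1"; gene_id "t1";',
    'scaf1\tasm\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "t1";'), gtf)
  ts <- readAssembledTranscripts(gtf)
  expect_equal(length(ts), 1L)
  e <- txExons(ts)[["t1"]]
  expect_equal(start(e), c(101L, 501L))  # out-of-order exons sorted by start
  expect_equal(unname(txLengths(ts)), 200L)

  writeLines(c(
    'scaf1\tasm\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "t1";',
    'scaf1\tasm\texon\t501\t600\t.\t-\t.\ttranscript_id "t1"; gene_id "t1";'), gtf)
  expect_error(readAssembledTranscripts(gtf), "strands disagree")
})

test_that("GFF3 and GTF round-trips are the identity on well-formed models", {
  set.seed(11)
  mk <- function(n, origin) {
    ex <- lapply(seq_len(n), function(i) {
      ne <- sample(1:4, 1L)
      w <- sample(80:400, ne, replace = TRUE)
      gaps <- sample(60:250, ne, replace = TRUE)
      st <- sample(1:5000, 1L) + cumsum(c(0L, (w + gaps)[-ne]))
      GRanges(sample(paste0("s", 1:3), 1L), IRanges(st, st + w - 1L),
              strand = sample(c("+", "-"), 1L))
    })
    names(ex) <- sprintf("%s%03d", if (origin == "assembled") "t" else "g", seq_len(n))
    TranscriptSet(GRangesList(ex), origin = origin)
  }
  ts <- mk(100, "predicted_gene")
  p <- tempfile(fileext = ".gff3")
  writeGeneModels(ts, p)
  expect_same_models(ts, readGeneModels(p))

  ta <- mk(100, "assembled")
  p2 <- tempfile(fileext = ".gtf")
  writeTranscriptsGTF(ta, p2)
  expect_same_models(ta, readAssembledTranscripts(p2))
})

test_that("spliced sequence extraction reads 5' to 3' on the model's strand", {
  genome <- Biostrings::DNAStringSet(c(s1 = "AAGTTT"))
  plus <- make_models(data.frame(id = "p", scaffold = "s1", start = 1, end = 4,
                                 strand = "+"))
  minus <- make_models(data.frame(id = "m", scaffold = "s1", start = 1, end = 4,
                                  strand = "-"))
  expect_equal(as.character(extractTranscriptSeq(plus, genome)[["p"]]), "AAGT")
  expect_equal(as.character(extractTranscriptSeq(minus, genome)[["m"]]), "ACTT")

  # spliced minus-strand model equals revcomp of concatenated genomic slices
  set.seed(3)
  chr <- rand_dna(600)
  genome2 <- Biostrings::DNAStringSet(c(s1 = chr))
  ex <- GRangesList(t1 = GRanges("s1", IRanges(c(21, 201), c(80, 360)), strand = "-"))
  tm <- TranscriptSet(ex, "assembled")
  want <- revcomp_chr(paste0(substr(chr, 21, 80), substr(chr, 201, 360)))
  expect_equal(as.character(extractTranscriptSeq(tm, genome2)[["t1"]]), want)

  # + and - extraction of one exon set are exact reverse complements
  plus2 <- TranscriptSet(GRangesList(
    t1 = GRanges("s1", IRanges(c(21, 201), c(80, 360)), strand = "+")), "assembled")
  expect_equal(as.character(extractTranscriptSeq(tm, genome2)[["t1"]]),
               revcomp_chr(as.character(extractTranscriptSeq(plus2, genome2)[["t1"]])))

  # out-of-bounds exon is a hard error
  bad <- make_models(data.frame(id = "b", scaffold = "s1", start = 590, end = 700,
                                strand = "+"))
  expect_error(extractTranscriptSeq(bad, genome2), "bounds")
})

test_that("expression matrix I/O validates and round-trips", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tM\tP\tFB", "t1\t5\t2\t0", "t2\t0\t0\t0"), p)
  se <- readExpression(p)
  expect_equal(stages(se), c("M", "P", "FB"))
  expect_equal(exprValues(se)["t1", "P"], 2)
  expect_equal(unname(exprValues(se)["t2", ]), c(0, 0, 0))

  set.seed(4)
  m <- matrix(round(runif(150, 0, 50), 4), 50, 3,
              dimnames = list(sprintf("t%02d", 1:50), c("M", "P", "FB")))
  se2 <- StageExpression(m, "RPKM")
  writeExpression(se2, p)
  expect_equal(exprValues(readExpression(p)), m)

  writeLines(c("transcript_id\tM\tP\tFB", "t1\t5\t-2\t0"), p)
  expect_error(readExpression(p), "negative")
  writeLines(c("transcript_id\tM\tP\tFB", "t1\t5\t2\t0", "t1\t1\t1\t1"), p)
  expect_error(readExpression(p), "duplicated")
})

test_that("evidence tables validate e-values and tolerate absent files", {
  d <- tempfile(); dir.create(d)
  write.table(data.frame(id = "t1", evalue = 1e-5), file.path(d, "nr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- readEvidenceTables(d)
  expect_equal(unname(ev$nr["t1"]), 1e-5)
  expect_null(ev$cpc)
  expect_error(evidenceTables(nr = c(t1 = -1)), "> 0")
})
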