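test_that("BED reading sorts, deduplicates and validates", {
  f <- withr::local_tempfile()
  writeLines(c("chr2\t0\t50", "chr1\t150\t250", "chr1\t100\t200",
               "chr1\t100\t200"), f)
  ps <- read_intervals(f)
  expect_equal(nrow(ps), 3)
  expect_equal(ps$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(ps$start, c(100, 150, 0))

  writeLines("chr1\t200\t100", f)
  expect_error(read_intervals(f), "start >= end at line 1")
  writeLines("chr1\t100", f)
  expect_error(read_intervals(f), "malformed line 1")
  writeLines(character(0), f)
  expect_warning(ps <- read_intervals(f), "empty")
  expect_equal(nrow(ps), 0)
})

test_that("broadPeak parsing keeps column 7 as the score", {
  f <- withr::local_tempfile()
  writeLines(paste("chr1", 100, 900, "peak1", 850, ".",
                   "12.75", "30.1", "25.2", sep = "\t"), f)
  ps <- read_intervals(f, format = "broadPeak")
  expect_equal(ps$score, 12.75)
  expect_equal(ps$name, "peak1")
  writeLines("chr1\t100\t900\tp\t850\t.", f)
  expect_error(read_intervals(f, format = "broadPeak"), "9 columns")
})

test_that("interval and signal writers round-trip exactly", {
  withr::local_seed(11)
  f <- withr::local_tempfile()
  for (rep in 1:5) {
    ps <- random_peaks(200)
    ps$name <- sprintf("p%d", seq_len(nrow(ps)))
    ps$score <- round(runif(nrow(ps)), 3)
    write_intervals(ps, f)
    back <- read_intervals(f)
    expect_equal(back$start, ps$start)
    expect_equal(back$end, ps$end)
    expect_equal(back$score, ps$score)

    tr <- random_track(100)
    write_signal(tr, f)
    tr2 <- read_signal(tr2_path <- f, library_size = tr$library_size)
    expect_identical(tr2$runs, tr$runs)
    expect_equal(tr2$total_signal, tr$total_signal)
  }
  # empty set -> empty file, no header
  write_intervals(peak_set(), f)
  expect_identical(readLines(f), character(0))
})

test_that("BED coordinates agree with rtracklayer's import convention", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), f)
  ours <- read_intervals(f)
  theirs <- rtracklayer::import(f)
  expect_equal(ours$start + 1, GenomicRanges::start(theirs))
  expect_equal(ours$end, GenomicRanges::end(theirs))
})

test_that("signal tracks validate values and overlap", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t10\t2.0", "chr1\t10\t20\t0.0"), f)
  expect_equal(read_signal(f)$total_signal, 20.0)
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), f)
  expect_error(read_signal(f), "overlapping")
  writeLines("chr1\t0\t10\t-1", f)
  expect_error(read_signal(f), "negative value")
})

test_that("TSS derivation follows strand and formats agree", {
  g <- gene_annotation(c("a", "b"), c("chr1", "chr1"),
                       c(1000, 1000), c(2000, 2000), c("+", "-"))
  expect_equal(g$tss[g$gene_id == "a"], 1000)
  expect_equal(g$tss[g$gene_id == "b"], 1999)
  expect_error(gene_annotation(c("a", "a"), "chr1", 1, 2, "+"),
               "duplicate gene_id: a")

  bed <- withr::local_tempfile()
  gtf <- withr::local_tempfile()
  writeLines(c("chr1\t1000\t2000\tgeneA\t0\t+",
               "chr1\t5000\t9000\tgeneB\t0\t-"), bed)
  writeLines(c(paste("chr1", "src", "gene", 1001, 2000, ".", "+", ".",
                     'gene_id "geneA";', sep = "\t"),
               paste("chr1", "src", "transcript", 1001, 1500, ".", "+",
                     ".", 'gene_id "geneA";', sep = "\t"),
               paste("chr1", "src", "gene", 5001, 9000, ".", "-", ".",
                     'gene_id "geneB";', sep = "\t")), gtf)
  a <- read_gene_annotation(bed, "bed6")
  b <- read_gene_annotation(gtf, "gtf")
  expect_equal(a$tss, b$tss)
  expect_equal(a$start, b$start)
  writeLines("chr1\t1000\t2000\tgeneA\t0", bed)
  expect_error(read_gene_annotation(bed, "bed6"), "strand missing")
})

test_that("count matrices enforce integers and the group map", {
  f <- withr::local_tempfile()
  writeLines(c("gene_id\tlength\tn1\tn2\tt1\tt2",
               "g1\t2000\t5\t6\t20\t22",
               "g2\t1500\t0\t1\t0\t2"), f)
  groups <- c(n1 = "normal", n2 = "normal", t1 = "tumor", t2 = "tumor")
  cm <- read_count_matrix(f, groups)
  expect_equal(dim(cm$counts), c(2, 4))
  expect_equal(unname(cm$gene_lengths), c(2000, 1500))

  writeLines(c("gene_id\tlength\tn1\tn2\tt1\tt2",
               "g1\t2000\t5\t3.7\t20\t22"), f)
  expect_error(read_count_matrix(f, groups), "non-integer")
  writeLines(c("gene_id\tlength\tn1\tn2\tt1\torphan",
               "g1\t2000\t5\t6\t20\t22"), f)
  expect_error(read_count_matrix(f, groups), "orphan")
  # round trip
  f2 <- withr::local_tempfile()
  writeLines(c("gene_id\tlength\tn1\tn2\tt1\tt2",
               "g1\t2000\t5\t6\t20\t22",
               "g2\t1500\t0\t1\t0\t2"), f)
  cm <- read_count_matrix(f, groups)
  write_count_matrix(cm, f2)
  cm2 <- read_count_matrix(f2, groups)
  expect_identical(cm2$counts, cm$counts)
})
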