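test_that("JASPAR parsing produces normalised PWMs", {
  f <- withr::local_tempfile()
  writeLines(c(">MA0001 TEST",
               "A [ 3 0 10 2 1 0 4 ]",
               "C [ 1 9  0 2 1 0 2 ]",
               "G [ 4 1  0 2 1 10 2 ]",
               "T [ 2 0  0 4 7 0 2 ]"), f)
  p <- read_jaspar(f)[[1]]
  expect_equal(ncol(p$matrix), 7)
  expect_equal(colSums(p$matrix), rep(1, 7), tolerance = 1e-9)
  expect_equal(p$tf_name, "TEST")

  # uniform counts give zero log odds against a uniform background
  writeLines(c(">U uniform", "A 2 2 2 2", "C 2 2 2 2", "G 2 2 2 2",
               "T 2 2 2 2"), f)
  u <- read_jaspar(f)[[1]]
  expect_equal(u$log_odds, matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), NULL)),
               tolerance = 1e-12)

  writeLines(c(">B bad", "A 1 2", "C 1 2", "G 1 2", "T 1 2 3"), f)
  expect_error(read_jaspar(f), "row lengths differ")
})

test_that("JASPAR write/read round-trips", {
  withr::local_seed(6)
  f <- withr::local_tempfile()
  pwms <- c(list(AP1 = ap1_pwm()), decoy_pwms(3, seed = 2))
  write_jaspar(pwms, f)
  back <- read_jaspar(f)
  expect_equal(names(back), names(pwms))
  for (nm in names(pwms)) {
    expect_equal(back[[nm]]$counts, pwms[[nm]]$counts)
    expect_equal(back[[nm]]$log_odds, pwms[[nm]]$log_odds,
                 tolerance = 1e-12)
  }
})

test_that("scanning finds planted consensus sites on both strands", {
  withr::local_seed(19)
  p <- ap1_pwm()
  base <- paste(sample(c("A", "C", "G"), 300, replace = TRUE),
                collapse = "")  # no T: cannot contain TGACTCA or TGAGTCA
  planted <- base
  substr(planted, 101, 107) <- "TGACTCA"
  res <- scan_pwm(c(s = planted), p)
  expect_true(res$has_hit[["s"]])
  expect_true(any(res$hits$start == 100 & res$hits$strand == "+"))

  rc <- base
  substr(rc, 101, 107) <- "TGAGTCA"  # reverse complement of TGACTCA
  res2 <- scan_pwm(c(s = rc), p)
  expect_true(any(res2$hits$start == 100 & res2$hits$strand == "-"))

  expect_warning(scan_pwm(c(tiny = "ACG"), p), "shorter than")
})

test_that("scan hit counts equal per-window rescoring on random DNA", {
  withr::local_seed(33)
  p <- consensus_pwm("ACGTGCA", strength = 20)
  seqs <- random_dna(10, 1000)
  seqs[3] <- paste0(substr(seqs[3], 1, 400), "NNNN",
                    substr(seqs[3], 405, 1000))
  for (thr in c(0.7, 0.8, 0.95)) {
    res <- scan_pwm(seqs, p, thr)
    oracle <- vapply(seqs, scan_oracle_hits, 0, p = p,
                     threshold_fraction = thr)
    impl <- as.integer(table(factor(res$hits$seq_id,
                                    levels = names(seqs))))
    expect_equal(impl, as.integer(oracle))
  }
})

test_that("scan scores are strand symmetric", {
  withr::local_seed(41)
  p <- ap1_pwm()
  for (s in random_dna(5, 500)) {
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    a <- scan_pwm(c(x = s), p, 0.75)
    b <- scan_pwm(c(x = rc), p, 0.75)
    expect_equal(nrow(a$hits), nrow(b$hits))
    expect_equal(sort(a$hits$score), sort(b$hits$score), tolerance = 1e-9)
  }
})

test_that("enrichment p-values are exact hypergeometric tail sums", {
  # engineered sequences: consensus planted in 9/10 fg and 1/10 bg
  withr::local_seed(55)
  p <- consensus_pwm("ACGTGCA", strength = 50)
  clean <- function() {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      if (!grepl("ACGTGCA", s) && !grepl("TGCACGT", s)) return(s)
    }
  }
  plant <- function(s) { substr(s, 21, 27) <- "ACGTGCA"; s }
  fg <- vapply(1:10, function(i) clean(), "")
  bg <- vapply(1:10, function(i) clean(), "")
  fg[1:9] <- vapply(fg[1:9], plant, "")
  bg[1] <- plant(bg[1])
  names(fg) <- paste0("f", 1:10); names(bg) <- paste0("b", 1:10)
  res <- enrich_motifs(fg, bg, list(p), threshold_fraction = 0.9)
  expect_equal(res$fg_hits, 9)
  expect_equal(res$bg_hits, 1)
  # brute-force enumeration over 2x2 tables with fixed margins
  enum <- sum(vapply(9:10, function(k)
    choose(10, k) * choose(10, 10 - k), 0)) / choose(20, 10)
  expect_equal(res$p_value, enum, tolerance = 1e-12)

  # equal hit fractions are not enriched
  res2 <- enrich_motifs(fg[1:9], fg[1:9], list(p), 0.9)
  expect_gt(res2$p_value, 0.5)
})

test_that("dinucleotide shuffle preserves composition and is seeded", {
  withr::local_seed(62)
  fg <- random_dna(6, 400)
  bg <- make_background(fg, "dinucleotide_shuffle", seed = 11)
  for (i in seq_along(fg)) {
    expect_equal(dinuc_counts(bg[[i]]), dinuc_counts(fg[[i]]))
    expect_equal(nchar(bg[[i]]), nchar(fg[[i]]))
    expect_equal(sort(strsplit(bg[[i]], "")[[1]]),
                 sort(strsplit(fg[[i]], "")[[1]]))
  }
  again <- make_background(fg, "dinucleotide_shuffle", seed = 11)
  expect_identical(bg, again)
  other <- make_background(fg, "dinucleotide_shuffle", seed = 12)
  expect_false(identical(bg, other))
})

test_that("genomic background sampling is length matched and avoids loci", {
  withr::local_seed(70)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                           collapse = ""))
  fg <- c(a = substr(genome[["chr1"]], 1001, 1400))
  excl <- data.frame(chrom = "chr1", start = 0, end = 5000)
  bg <- make_background(fg, "genomic_sample", seed = 3, genome = genome,
                        exclude = excl)
  expect_equal(nchar(bg[[1]]), 400)
  expect_error(make_background(fg, "genomic_sample", seed = 3), "genome")
})
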