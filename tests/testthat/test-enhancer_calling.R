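genes_at <- function(tss_pos, chrom = "chr1") {
  gene_annotation(sprintf("g%02d", seq_along(tss_pos)),
                  rep(chrom, length(tss_pos)),
                  tss_pos, tss_pos + 500, rep("+", length(tss_pos)))
}

test_that("distal filter applies the boundary/center rules per TSS", {
  genes <- genes_at(10000)
  keep <- filter_distal(peak_set("chr1", 5000, 5200), genes)
  expect_equal(nrow(keep), 1)  # boundary distance 4800 >= 1500

  inside <- filter_distal(peak_set("chr1", 5000, 5200), genes_at(5100))
  expect_equal(nrow(inside), 0)  # TSS inside the peak: distance 0

  # boundary 1400 away but center 3100 away: kept under OR, dropped by AND
  p <- peak_set("chr1", 5000, 8400)  # center 6700, TSS at 3600
  g <- genes_at(3600)
  expect_equal(nrow(filter_distal(p, g, distal_filter_rules())), 1)
  expect_equal(nrow(filter_distal(
    p, g, distal_filter_rules(combine = "and"))), 0)

  expect_error(filter_distal(p, genes_at(integer(0))), "empty gene")
})

test_that("distal filter is idempotent and matches the all-TSS oracle", {
  withr::local_seed(5)
  peaks <- random_peaks(300, n_chroms = 2, span = 2e5)
  tsspos <- sample.int(2e5, 40)
  genes <- gene_annotation(sprintf("g%02d", 1:40),
                           sprintf("chr%d", sample.int(2, 40, TRUE)),
                           tsspos, tsspos + 200,
                           sample(c("+", "-"), 40, TRUE))
  for (mode in c("or", "and")) {
    rules <- distal_filter_rules(combine = mode)
    kept <- filter_distal(peaks, genes, rules)
    oracle <- distal_oracle_keep(peaks, genes, 1500, 3000, mode)
    expect_equal(nrow(kept), sum(oracle))
    expect_equal(kept$start, peaks$start[oracle])
    again <- filter_distal(kept, genes, rules)
    expect_equal(again$start, kept$start)
  }
})

test_that("stitching merges on strict sub-12.5 kb gaps", {
  ps <- peak_set(c("chr1", "chr1"), c(100, 12699), c(200, 12800))
  st <- stitch(ps)
  expect_equal(nrow(st), 1)  # gap 12499 < 12500
  expect_equal(c(st$start, st$end), c(100, 12800))
  ps2 <- peak_set(c("chr1", "chr1"), c(100, 12700), c(200, 12800))
  expect_equal(nrow(stitch(ps2)), 2)  # gap exactly 12500 splits
})

test_that("stitching equals the transitive-closure oracle and is idempotent", {
  withr::local_seed(42)
  for (rep in 1:5) {
    peaks <- random_peaks(120, n_chroms = 2, span = 3e5, max_w = 20000)
    st <- stitch(peaks)
    expect_identical(
      canonical_partition(stitch_result_partition(st, peaks)),
      canonical_partition(stitch_oracle_partition(peaks, 12500)))
    st2 <- stitch(st)
    expect_equal(st2$start, st$start)
    expect_equal(st2$end, st$end)
  }
})

test_that("RPKM quantification is exact and scale invariant", {
  tr <- signal_track(data.frame(chrom = "chr1", start = 1000, end = 3000,
                                value = 0.2), library_size = 1e6)
  enh <- data.frame(chrom = "chr1", start = 1000, end = 3000)
  q <- quantify(enh, tr)
  expect_equal(q$raw_signal, 400, tolerance = 1e-12)
  expect_equal(q$rpkm, 200, tolerance = 1e-12)  # 400 / (2 kb x 1 M)

  tr2 <- signal_track(transform(tr$runs, value = value * 2),
                      library_size = 2e6)
  expect_equal(quantify(enh, tr2)$rpkm, q$rpkm)
  expect_error(quantify(enh, signal_track(tr$runs, library_size = 0)),
               "library_size")
})

test_that("block overlap sums equal the per-bp oracle", {
  withr::local_seed(9)
  tr <- random_track(60, span = 5e4)
  enh <- data.frame(chrom = "chrA",
                    start = sample.int(4e4, 30))
  enh$end <- enh$start + sample.int(8000, 30)
  q <- quantify(enh, tr)
  expect_equal(q$raw_signal,
               overlap_signal_oracle(tr, enh$chrom, enh$start, enh$end),
               tolerance = 1e-9)
})

test_that("rank-curve cutoff matches the analytic tangent point of x^3", {
  n <- 1001
  sig <- ((seq_len(n) - 1) / (n - 1))^3
  enh <- data.frame(chrom = "chr1", start = seq_len(n) * 10,
                    end = seq_len(n) * 10 + 5)
  res <- call_super(enh, signal = sig)
  frac <- (attr(res$curve, "cutoff_rank") - 1) / (n - 1)
  expect_gte(frac, 0.57)  # closed form: 3 x^2 = 1 at x = 3^(-1/2)
  expect_lte(frac, 0.59)
  expect_equal(mean(res$enhancers$is_super), 1 - frac, tolerance = 0.01)
})

test_that("rank-curve degenerate cases are handled", {
  enh <- data.frame(chrom = "chr1", start = 1:5 * 10, end = 1:5 * 10 + 5)
  # slope exactly 1 everywhere never strictly exceeds 1: no supers
  res <- call_super(enh, signal = (0:4) / 4)
  expect_false(any(res$enhancers$is_super))
  expect_warning(res2 <- call_super(enh, signal = rep(3, 5)), "equal")
  expect_false(any(res2$enhancers$is_super))
  expect_error(call_super(enh[1:2, ], signal = c(1, 2)), ">= 3")
})

test_that("super calls are monotone in signal", {
  withr::local_seed(3)
  sig <- c(runif(200, 0, 10), runif(10, 200, 400))
  enh <- data.frame(chrom = "chr1", start = seq_along(sig) * 10,
                    end = seq_along(sig) * 10 + 5)
  res <- call_super(enh, signal = sig)
  expect_true(any(res$enhancers$is_super))
  expect_lt(max(sig[!res$enhancers$is_super]),
            min(sig[res$enhancers$is_super]))
  # raising the top enhancer never demotes it
  top <- which.max(sig)
  sig[top] <- sig[top] + 100
  res2 <- call_super(enh, signal = sig)
  expect_true(res2$enhancers$is_super[top])
})

test_that("active-enhancer support filter respects the overlap fraction", {
  k27 <- peak_set("chr1", c(100, 5000), c(600, 5400))
  k4 <- peak_set("chr1", 550, 2000)
  kept <- filter_active(k27, k4)
  expect_equal(kept$start, 100)  # 50 bp overlap is enough at frac 0
  expect_equal(nrow(filter_active(k27, k4, min_overlap_frac = 0.5)), 0)
})
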