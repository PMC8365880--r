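test_that("replicate pooling sums values and is linear under quantify", {
  tr <- signal_track(data.frame(chrom = "chr1", start = c(0, 100),
                                end = c(50, 300), value = c(2, 1)),
                     library_size = 1000)
  pooled <- pool_replicates(list(tr, tr))
  expect_equal(pooled$runs$value, c(4, 2))
  expect_equal(pooled$library_size, 2000)
  expect_identical(pool_replicates(list(tr))$runs, tr$runs)
  expect_error(pool_replicates(list()), "empty")

  withr::local_seed(21)
  reps <- lapply(1:3, function(i) random_track(40, span = 2e4))
  pooled <- pool_replicates(reps)
  enh <- data.frame(chrom = "chrA", start = c(0, 5000, 12000),
                    end = c(4000, 11000, 20000))
  per_rep <- sapply(reps, function(t) quantify(enh, t)$raw_signal)
  expect_equal(quantify(enh, pooled)$raw_signal, rowSums(per_rep),
               tolerance = 1e-9)
})

test_that("union catalog merges across conditions with provenance flags", {
  a <- data.frame(chrom = "chr1", start = c(0, 100, 500),
                  end = c(50, 200, 700), is_super = c(FALSE, TRUE, FALSE))
  b <- data.frame(chrom = c("chr1", "chr2"), start = c(150, 0),
                  end = c(260, 90), is_super = c(FALSE, FALSE))
  u <- build_union_catalog(a, b)
  expect_equal(nrow(u), 4)  # [100,200) and [150,260) merge
  merged <- u[u$start == 100, ]
  expect_equal(merged$end, 260)
  expect_true(merged$in_normal && merged$in_tumor)
  expect_true(merged$super_in_normal)
  expect_false(merged$super_in_tumor)

  # identical catalogs give the catalog back; disjoint ones concatenate
  u2 <- build_union_catalog(a, a)
  expect_equal(u2$start, a$start)
  d1 <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(50, 150, 250), is_super = FALSE)
  d2 <- data.frame(chrom = "chr2", start = c(0, 100, 200, 300),
                   end = c(50, 150, 250, 350), is_super = FALSE)
  expect_equal(nrow(build_union_catalog(d1, d2)), 7)
})

test_that("union merging equals interval-graph connected components", {
  withr::local_seed(14)
  a <- as.data.frame(random_peaks(60, span = 5e4, max_w = 3000))
  b <- as.data.frame(random_peaks(60, span = 5e4, max_w = 3000))
  a$is_super <- FALSE; b$is_super <- FALSE
  u <- build_union_catalog(a, b)
  comb <- rbind(a[1:3], b[1:3])
  comb <- comb[order(comb$chrom, comb$start, comb$end, method = "radix"), ]
  oracle <- overlap_oracle_partition(comb)
  expect_equal(nrow(u), length(oracle))
  spans <- t(vapply(oracle, function(ix)
    c(min(comb$start[ix]), max(comb$end[ix])), c(0, 0)))
  expect_equal(sort(u$start), sort(spans[, 1]))
  expect_equal(sort(u$end), sort(spans[, 2]))
})

make_cond_track <- function(vals, lib) {
  signal_track(data.frame(chrom = "chr1",
                          start = seq(0, by = 1000,
                                      length.out = length(vals)),
                          end = seq(1000, by = 1000,
                                    length.out = length(vals)),
                          value = vals), library_size = lib)
}

test_that("VEL fold-change classification follows the thresholds", {
  cat <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                    end = c(1000, 2000, 3000),
                    name = c("u1", "u2", "u3"))
  # per-bp values of x/1000 over 1 kb loci at lib 1e6 give RPKM = x
  tum <- make_cond_track(c(10, 5, 1) / 1000, 1e6)
  nor <- make_cond_track(c(4, 5, 10) / 1000, 1e6)
  v <- call_vels(cat, tum, nor, pseudocount = 1)
  v <- v[order(v$name), ]
  expect_equal(v$fold_change[1], 11 / 5)  # (10+1)/(4+1) = 2.2 -> gain
  expect_equal(v$status, c("gain", "stable", "lost"))
  expect_error(call_vels(cat, tum, nor, pseudocount = 0), "pseudocount")
})

test_that("VEL calls are symmetric and scale invariant", {
  withr::local_seed(31)
  cat <- data.frame(chrom = "chr1",
                    start = seq(0, by = 1000, length.out = 40),
                    end = seq(1000, by = 1000, length.out = 40),
                    name = sprintf("u%02d", 1:40))
  tum <- make_cond_track(runif(40, 0, 30), 1e6)
  nor <- make_cond_track(runif(40, 0, 30), 1e6)
  fwd <- call_vels(cat, tum, nor, fc_up = 2, fc_down = 0.5)
  rev <- call_vels(cat, nor, tum, fc_up = 2, fc_down = 0.5)
  fwd <- fwd[order(fwd$name), ]; rev <- rev[order(rev$name), ]
  expect_equal(fwd$status == "gain", rev$status == "lost")
  expect_equal(fwd$status == "lost", rev$status == "gain")

  tum2 <- make_cond_track(tum$runs$value * 3, 3e6)
  nor2 <- make_cond_track(nor$runs$value * 3, 3e6)
  sc <- call_vels(cat, tum2, nor2)
  expect_equal(sc[order(sc$name), ]$status, fwd$status)
})

test_that("VSEL direction requires the super flag in the right condition", {
  cat <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                    name = c("a", "b"),
                    super_in_normal = c(FALSE, TRUE),
                    super_in_tumor = c(TRUE, FALSE))
  tum <- make_cond_track(c(30, 30), 1e6)
  nor <- make_cond_track(c(5, 5), 1e6)   # FC ~ 5 for both loci
  v <- call_vsels(cat, tum, nor)
  v <- v[order(v$name), ]
  expect_equal(v$status, c("gain", "stable"))  # b fails super_in_tumor
  expect_equal(v$condition_of_super, c("tumor", "normal"))
  v2 <- call_vsels(cat, tum, nor, directional = FALSE)
  expect_equal(v2[order(v2$name), ]$status, c("gain", "gain"))
  # every VSEL fold change agrees with the VEL logic on the same locus
  vel <- call_vels(cat, tum, nor)
  expect_equal(v[order(v$name), ]$fold_change,
               vel[order(vel$name), ]$fold_change)
})

test_that("FPKM normalisation is exact, scale invariant and elementwise", {
  counts <- matrix(c(100L, 50L, 200L, 100L), 2,
                   dimnames = list(c("g1", "g2"), c("n1", "t1")))
  cm <- count_matrix(counts, c(n1 = "normal", t1 = "tumor"),
                     c(g1 = 2000, g2 = 1000))
  # force the library total to 1e6 by padding with a dummy gene
  counts2 <- rbind(counts, other = c(1e6L - 150L, 1e6L - 300L))
  cm2 <- count_matrix(counts2, c(n1 = "normal", t1 = "tumor"),
                      c(g1 = 2000, g2 = 1000, other = 1000))
  expect_equal(normalize_fpkm(cm2)["g1", "n1"], 50, tolerance = 1e-12)

  f1 <- normalize_fpkm(cm)
  cm_scaled <- count_matrix(cbind(n1 = counts[, 1] * 2L, t1 = counts[, 2]),
                            cm$groups, cm$gene_lengths)
  expect_equal(normalize_fpkm(cm_scaled)[, "n1"], f1[, "n1"])

  withr::local_seed(8)
  rc <- matrix(rpois(60, 50), 10,
               dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  lens <- setNames(sample(500:5000, 10), rownames(rc))
  cmr <- count_matrix(rc, setNames(rep(c("normal", "tumor"), each = 3),
                                   colnames(rc)), lens)
  fp <- normalize_fpkm(cmr)
  for (g in rownames(rc)) for (s in colnames(rc))
    expect_equal(fp[g, s],
                 rc[g, s] / ((lens[[g]] / 1000) * sum(rc[, s]) / 1e6),
                 tolerance = 1e-12)
})

test_that("DEG calling applies the |log2FC| and p-value rule", {
  counts <- matrix(rep(c(100L, 10L), each = 6), 2, 6, byrow = TRUE,
                   dimnames = list(c("flat", "weak"),
                                   c(paste0("n", 1:3), paste0("t", 1:3))))
  cm <- count_matrix(counts,
                     setNames(rep(c("normal", "tumor"), each = 3),
                              colnames(counts)),
                     c(flat = 1000, weak = 1000))
  d <- call_degs(cm)
  expect_equal(d$log2fc, c(0, 0))
  expect_equal(d$status, c("null", "null"))
  cm_small <- count_matrix(counts[, c(1, 4), drop = FALSE],
                           setNames(c("normal", "tumor"),
                                    colnames(counts)[c(1, 4)]),
                           c(flat = 1000, weak = 1000))
  expect_error(call_degs(cm_small), ">= 2 samples")
})

test_that("the vectorised Welch test matches stats::t.test", {
  withr::local_seed(77)
  x <- matrix(rnorm(50 * 4, 5), 50)
  y <- matrix(rnorm(50 * 3, 5.5, 2), 50)
  p <- enhancerscape:::.welch_p(x, y)
  p_ref <- vapply(1:50, function(i)
    stats::t.test(x[i, ], y[i, ])$p.value, 0)
  expect_equal(p, p_ref, tolerance = 1e-12)
})
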