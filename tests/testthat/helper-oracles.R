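# Independent brute-force oracles used to cross-check the package's
# interval machinery, plus small random-fixture builders.

random_peaks <- function(n, n_chroms = 2, span = 1e6, max_w = 5000) {
  chrom <- sprintf("chr%d", sample.int(n_chroms, n, replace = TRUE))
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(max_w, n, replace = TRUE)
  peak_set(chrom, start, start + width)
}

random_track <- function(n_runs = 50, span = 1e5, chrom = "chrA",
                         digits = 4) {
  bounds <- sort(sample.int(span, 2 * n_runs))
  start <- bounds[seq(1, 2 * n_runs, by = 2)]
  end <- bounds[seq(2, 2 * n_runs, by = 2)]
  keep <- end > start
  signal_track(data.frame(chrom = chrom, start = start[keep],
                          end = end[keep],
                          value = round(stats::runif(sum(keep), 0, 10),
                                        digits)))
}

# transitive-closure stitching: O(n^2) union-find over the
# "inter-interval distance < gap" relation
stitch_oracle_partition <- function(df, gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || df$chrom[i] != df$chrom[j]) next
    d <- max(0, df$start[i] - df$end[j], df$start[j] - df$end[i])
    if (d < gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

# same transitive closure, with the O(n^2) distance matrix vectorised so
# the 1,000-peak acceptance check stays fast; union-find over the edges
stitch_oracle_partition_fast <- function(df, gap) {
  n <- nrow(df)
  d <- pmax(0, pmax(outer(df$start, df$end, "-"),
                    t(outer(df$start, df$end, "-"))))
  adj <- d < gap & outer(df$chrom, df$chrom, "==")
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

# connected components of the ">= 1 bp overlap" interval graph
overlap_oracle_partition <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || df$chrom[i] != df$chrom[j]) next
    if (df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

# partition implied by a stitch() result, as sorted index groups over the
# sorted input peaks
stitch_result_partition <- function(stitched, peaks) {
  key <- paste(peaks$chrom, peaks$start, peaks$end)
  groups <- lapply(stitched$constituents, function(cd)
    sort(match(paste(cd$chrom, cd$start, cd$end), key)))
  groups[order(vapply(groups, min, 0L))]
}

canonical_partition <- function(p)
  unname(lapply(p[order(vapply(p, min, 0L))],
                function(x) as.integer(sort(unname(x)))))

# all-TSS distal decision, straight from the rule
distal_oracle_keep <- function(peaks, genes, boundary_min, center_min,
                               combine) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ctr <- floor((peaks$start[i] + peaks$end[i]) / 2)
    tss <- genes$tss[genes$chrom == peaks$chrom[i]]
    if (length(tss) == 0) return(TRUE)
    bd <- pmax(0, pmax(peaks$start[i] - tss, tss - peaks$end[i]))
    cd <- abs(ctr - tss)
    ok <- if (combine == "or") bd >= boundary_min | cd >= center_min
    else bd >= boundary_min & cd >= center_min
    all(ok)
  }, NA)
}

# per-bp signal sum over an interval
overlap_signal_oracle <- function(track, chrom, start, end) {
  vapply(seq_along(chrom), function(i) {
    r <- track$runs[track$runs$chrom == chrom[i], , drop = FALSE]
    total <- 0
    for (k in seq_len(nrow(r))) {
      w <- min(end[i], r$end[k]) - max(start[i], r$start[k])
      if (w > 0) total <- total + w * r$value[k]
    }
    total
  }, 0)
}

# all-pairs nearest-TSS scan with the lexicographic tie rule
proximal_oracle <- function(loci, genes) {
  vapply(seq_len(nrow(loci)), function(i) {
    g <- genes[genes$chrom == loci$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    ctr <- floor((loci$start[i] + loci$end[i]) / 2)
    d <- abs(g$tss - ctr)
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, "")
}

# per-window PWM rescoring, straight from the definition
scan_oracle_hits <- function(seq, p, threshold_fraction) {
  lo <- p$log_odds
  m <- ncol(lo)
  score_one <- function(s) {
    n <- nchar(s)
    if (n < m) return(numeric(0))
    vapply(seq_len(n - m + 1), function(i) {
      sum(vapply(seq_len(m), function(j) {
        b <- substr(s, i + j - 1, i + j - 1)
        if (b == "N") min(lo[, j]) else lo[match(b, c("A", "C", "G", "T")), j]
      }, 0))
    }, 0)
  }
  thr <- threshold_fraction * sum(apply(lo, 2, max))
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  sum(score_one(seq) >= thr) + sum(score_one(rc) >= thr)
}

random_dna <- function(n, len) {
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), ""),
    sprintf("s%d", seq_len(n)))
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(factor(paste0(ch[-length(ch)], ch[-1]),
               levels = as.vector(outer(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"), paste0))))
}

# small simulation configs keeping unit tests fast
small_sim <- function(seed = 1, ...) {
  args <- list(n_chroms = 1, chrom_length = 6e6, n_genes = 150,
               n_typical = 60, n_super = 8, n_gain_vel = 20,
               n_lost_vel = 20, n_gain_vsel = 2, n_lost_vsel = 2,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
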