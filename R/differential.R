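# Tumor-vs-normal differential layer: replicate pooling, the union
# enhancer catalog, variant enhancer loci (VELs) and variant super enhancer
# loci (VSELs) by H3K27ac fold change, FPKM normalisation and DEG calling.

#' Pool replicate signal tracks
#'
#' Per-bp values are summed across replicates and library sizes added, so
#' downstream quantification of the pooled track equals the sum of
#' per-replicate quantifications.
#'
#' @param tracks A list of [signal_track()]s on a shared chromosome
#'   namespace.
#' @return A [signal_track()].
#' @export
pool_replicates <- function(tracks) {
  if (length(tracks) == 0) stop("cannot pool an empty list of tracks")
  if (length(tracks) == 1) return(tracks[[1]])
  runs <- do.call(rbind, lapply(tracks, function(t) t$runs))
  gr <- .as_granges(runs$chrom, runs$start, runs$end)
  d <- GenomicRanges::disjoin(gr)
  ov <- GenomicRanges::findOverlaps(d, gr)
  val <- rowsum(runs$value[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(d)),
                    start = GenomicRanges::start(d) - 1,
                    end = GenomicRanges::end(d),
                    value = 0, stringsAsFactors = FALSE)
  out$value[as.integer(rownames(val))] <- val[, 1]
  signal_track(out,
               library_size = sum(vapply(tracks, `[[`, 0, "library_size")))
}

#' Merge per-condition catalogs into a union catalog
#'
#' Enhancer spans from the two conditions are merged wherever they overlap
#' by at least 1 bp; each union locus carries provenance flags saying which
#' condition(s) it came from and whether it was super there.
#'
#' @param normal_enhancers,tumor_enhancers Per-condition catalogs from
#'   [call_enhancers()] (data frames with `is_super`).
#' @return A `data.frame` of class `union_catalog` with flags `in_normal`,
#'   `in_tumor`, `super_in_normal`, `super_in_tumor`.
#' @export
build_union_catalog <- function(normal_enhancers, tumor_enhancers) {
  pn <- attr(normal_enhancers, "params")
  pt <- attr(tumor_enhancers, "params")
  if (!is.null(pn) && !is.null(pt) && !identical(pn, pt))
    stop("catalogs were built with different parameters")
  comb <- rbind(
    data.frame(chrom = normal_enhancers$chrom,
               start = normal_enhancers$start, end = normal_enhancers$end,
               cond = "normal", is_super = normal_enhancers$is_super,
               stringsAsFactors = FALSE),
    data.frame(chrom = tumor_enhancers$chrom,
               start = tumor_enhancers$start, end = tumor_enhancers$end,
               cond = "tumor", is_super = tumor_enhancers$is_super,
               stringsAsFactors = FALSE))
  if (nrow(comb) == 0)
    stop("both catalogs are empty")
  o <- .sort_order(comb$chrom, comb$start, comb$end)
  comb <- comb[o, , drop = FALSE]
  grp <- .stitch_groups(comb$chrom, comb$start, comb$end, gap = 0)
  idx <- split(seq_len(nrow(comb)), grp)
  out <- data.frame(
    chrom = vapply(idx, function(i) comb$chrom[i[1]], ""),
    start = vapply(idx, function(i) min(comb$start[i]), 0),
    end = vapply(idx, function(i) max(comb$end[i]), 0),
    stringsAsFactors = FALSE)
  out$name <- sprintf("union_%d", seq_len(nrow(out)))
  out$in_normal <- vapply(idx, function(i) any(comb$cond[i] == "normal"), NA)
  out$in_tumor <- vapply(idx, function(i) any(comb$cond[i] == "tumor"), NA)
  out$super_in_normal <- vapply(idx, function(i)
    any(comb$is_super[i] & comb$cond[i] == "normal"), NA)
  out$super_in_tumor <- vapply(idx, function(i)
    any(comb$is_super[i] & comb$cond[i] == "tumor"), NA)
  rownames(out) <- NULL
  class(out) <- c("union_catalog", "data.frame")
  out
}

.classify_fc <- function(fc, fc_up, fc_down) {
  ifelse(fc >= fc_up, "gain", ifelse(fc <= fc_down, "lost", "stable"))
}

#' Call variant enhancer loci (VELs)
#'
#' Each union-catalog locus is quantified (RPKM) on the pooled tumor and
#' normal H3K27ac tracks; the fold change
#' `(tumor + pseudocount) / (normal + pseudocount)` classifies it as gain
#' (fold change >= `fc_up`), lost (<= `fc_down`) or stable. Records are
#' sorted by `|log2 fold change|`, largest first.
#'
#' @param catalog A [build_union_catalog()] result (or interval frame).
#' @param tumor_track,normal_track Pooled per-condition [signal_track()]s.
#' @param fc_up,fc_down Fold-change thresholds (defaults 2 and 0.5).
#' @param pseudocount RPKM pseudocount (> 0) guarding zero-signal loci.
#' @return `data.frame` of class `vel_records` with columns tumor_rpkm,
#'   normal_rpkm, fold_change, log2fc, status.
#' @export
call_vels <- function(catalog, tumor_track, normal_track,
                      fc_up = 2.0, fc_down = 0.5, pseudocount = 1.0) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  stopifnot(fc_up > fc_down)
  tq <- quantify(as.data.frame(catalog), tumor_track)
  nq <- quantify(as.data.frame(catalog), normal_track)
  out <- as.data.frame(catalog)
  out$tumor_rpkm <- tq$rpkm
  out$normal_rpkm <- nq$rpkm
  out$fold_change <- (out$tumor_rpkm + pseudocount) /
    (out$normal_rpkm + pseudocount)
  out$log2fc <- log2(out$fold_change)
  out$status <- .classify_fc(out$fold_change, fc_up, fc_down)
  out <- out[order(-abs(out$log2fc), out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vel_records", "data.frame")
  out
}

#' Call variant super enhancer loci (VSELs)
#'
#' The VEL fold-change logic restricted to loci that are super in at least
#' one condition. With `directional = TRUE` (default) a gain VSEL must be
#' super in tumor and a lost VSEL super in normal — a locus super only in
#' the other condition is reported as stable. `directional = FALSE` keeps
#' the pure fold-change classification on super loci.
#'
#' @inheritParams call_vels
#' @param directional Require the super flag in the gained/lost condition.
#' @return `data.frame` of class `vsel_records` with an added
#'   `condition_of_super` column (`normal`, `tumor` or `both`).
#' @export
call_vsels <- function(catalog, tumor_track, normal_track,
                       fc_up = 2.0, fc_down = 0.5, pseudocount = 1.0,
                       directional = TRUE) {
  if (!all(c("super_in_normal", "super_in_tumor") %in% names(catalog)))
    stop("catalog lacks super flags; build it with build_union_catalog()")
  sub <- catalog[catalog$super_in_normal | catalog$super_in_tumor, ,
                 drop = FALSE]
  out <- call_vels(sub, tumor_track, normal_track, fc_up, fc_down,
                   pseudocount)
  out$condition_of_super <- ifelse(
    out$super_in_normal & out$super_in_tumor, "both",
    ifelse(out$super_in_tumor, "tumor", "normal"))
  if (directional) {
    out$status[out$status == "gain" & !out$super_in_tumor] <- "stable"
    out$status[out$status == "lost" & !out$super_in_normal] <- "stable"
  }
  class(out) <- c("vsel_records", "data.frame")
  out
}

#' FPKM normalisation of a count matrix
#'
#' `fpkm[g, s] = counts[g, s] / (length_kb[g] * total[s] / 1e6)`.
#'
#' @param cm A [count_matrix()].
#' @return Numeric gene-by-sample matrix of FPKM values.
#' @export
normalize_fpkm <- function(cm) {
  totals <- colSums(cm$counts)
  if (any(totals <= 0)) stop("zero library total in sample(s): ",
                             paste(colnames(cm$counts)[totals <= 0],
                                   collapse = ", "))
  len_kb <- cm$gene_lengths / 1000
  sweep(cm$counts / len_kb, 2, totals / 1e6, "/")
}

# Vectorised Welch two-sample test; returns two-sided p-values.
# Zero pooled standard error: p = 1 when the means agree, 0 otherwise.
.welch_p <- function(x_mat, y_mat) {
  n1 <- ncol(x_mat); n2 <- ncol(y_mat)
  m1 <- rowMeans(x_mat); m2 <- rowMeans(y_mat)
  v1 <- apply(x_mat, 1, stats::var); v2 <- apply(y_mat, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(m1))
  nz <- se2 > 0
  tt <- (m1[nz] - m2[nz]) / sqrt(se2[nz])
  df <- se2[nz]^2 / ((v1[nz] / n1)^2 / (n1 - 1) + (v2[nz] / n2)^2 / (n2 - 1))
  p[nz] <- 2 * stats::pt(-abs(tt), df)
  p[!nz] <- ifelse(m1[!nz] == m2[!nz], 1, 0)
  p
}

#' Call differentially expressed genes
#'
#' FPKM-normalises the counts, computes
#' `log2fc = log2((mean tumor FPKM + pseudocount) /
#' (mean normal FPKM + pseudocount))` and a two-sided Welch test on
#' `log2(FPKM + pseudocount)`, then applies the DEG rule: up when
#' `log2fc >= lfc_min` and `p < alpha`, down symmetrically, else null.
#'
#' @param cm A [count_matrix()] with >= 2 samples per group.
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param alpha Significance threshold on the (raw) p-value (default 0.05).
#' @param pseudocount FPKM pseudocount (default 1).
#' @param fdr If `TRUE`, threshold Benjamini-Hochberg adjusted p-values
#'   instead of raw ones (off by default; the stated rule uses raw p).
#' @return `data.frame` of class `deg_records` with columns gene_id,
#'   normal_mean_fpkm, tumor_mean_fpkm, log2fc, p_value, status.
#' @export
call_degs <- function(cm, lfc_min = 1.0, alpha = 0.05, pseudocount = 1.0,
                      fdr = FALSE) {
  tum <- names(cm$groups)[cm$groups == "tumor"]
  nor <- names(cm$groups)[cm$groups == "normal"]
  if (length(tum) < 2 || length(nor) < 2)
    stop("need >= 2 samples per group for differential expression")
  fpkm <- normalize_fpkm(cm)
  t_mean <- rowMeans(fpkm[, tum, drop = FALSE])
  n_mean <- rowMeans(fpkm[, nor, drop = FALSE])
  log2fc <- log2((t_mean + pseudocount) / (n_mean + pseudocount))
  lf <- log2(fpkm + pseudocount)
  p <- .welch_p(lf[, tum, drop = FALSE], lf[, nor, drop = FALSE])
  p_thr <- if (fdr) stats::p.adjust(p, "BH") else p
  status <- ifelse(log2fc >= lfc_min & p_thr < alpha, "up",
                   ifelse(log2fc <= -lfc_min & p_thr < alpha, "down",
                          "null"))
  out <- data.frame(gene_id = rownames(cm$counts),
                    normal_mean_fpkm = n_mean, tumor_mean_fpkm = t_mean,
                    log2fc = log2fc, p_value = p, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("deg_records", "data.frame")
  out
}
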