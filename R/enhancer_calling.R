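# Typical/super enhancer identification: TSS-distal filtering of H3K27ac
# peaks, 12.5 kb stitching into enhancer loci, signal quantification (RPKM),
# and the rank-curve tangent-slope-1 cutoff separating super from typical
# enhancers.

#' Distal-filter rules
#'
#' A peak is kept only if, for every TSS, its boundary is at least
#' `boundary_min_dist` away or its center at least `center_min_dist` away
#' (`combine = "or"`), or both (`combine = "and"`). A TSS inside the peak
#' has boundary distance 0. `active_enhancer_tss_dist` is the separate,
#' stricter pre-filter distance used by [filter_tss_proximal()] when
#' building the active-enhancer catalog.
#'
#' @param boundary_min_dist Minimum TSS-to-boundary distance in bp.
#' @param center_min_dist Minimum TSS-to-center distance in bp.
#' @param combine `"or"` (default, as the rule is stated) or `"and"`.
#' @param active_enhancer_tss_dist bp, for the active-enhancer pre-filter.
#' @return A list of class `distal_filter_rules`.
#' @export
distal_filter_rules <- function(boundary_min_dist = 1500,
                                center_min_dist = 3000,
                                combine = c("or", "and"),
                                active_enhancer_tss_dist = 2000) {
  combine <- match.arg(combine)
  stopifnot(boundary_min_dist >= 0, center_min_dist >= 0,
            active_enhancer_tss_dist >= 0)
  structure(list(boundary_min_dist = boundary_min_dist,
                 center_min_dist = center_min_dist,
                 combine = combine,
                 active_enhancer_tss_dist = active_enhancer_tss_dist),
            class = "distal_filter_rules")
}

# boundary distance from a TSS position to a 0-based half-open interval;
# 0 if the TSS lies inside. Matches the convention distance = tss - end
# for a TSS right of the interval.
.boundary_dist <- function(start, end, tss) {
  pmax(0, pmax(start - tss, tss - end))
}

#' Keep peaks distal to every transcription start site
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_annotation()].
#' @param rules A [distal_filter_rules()].
#' @return The retained subset, still a `peak_set`.
#' @export
filter_distal <- function(peaks, genes, rules = distal_filter_rules()) {
  if (!inherits(genes, "gene_annotation") || nrow(genes) == 0)
    stop("empty gene annotation: cannot define 'distal'")
  if (nrow(peaks) == 0) return(peaks)
  keep <- logical(nrow(peaks))
  center <- floor((peaks$start + peaks$end) / 2)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    tss <- genes$tss[genes$chrom == ch]
    if (length(tss) == 0) { keep[pi] <- TRUE; next }
    for (i in pi) {
      bd <- .boundary_dist(peaks$start[i], peaks$end[i], tss)
      cd <- abs(center[i] - tss)
      ok_per_tss <- if (rules$combine == "or")
        bd >= rules$boundary_min_dist | cd >= rules$center_min_dist
      else
        bd >= rules$boundary_min_dist & cd >= rules$center_min_dist
      keep[i] <- all(ok_per_tss)
    }
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_label") <- attr(peaks, "source_label")
  class(out) <- class(peaks)
  out
}

#' Remove peaks closer than `min_dist` to any TSS
#'
#' The coarser pre-filter used when defining the active-enhancer catalog
#' (boundary distance to the nearest TSS must be at least `min_dist`).
#'
#' @inheritParams filter_distal
#' @param min_dist bp (default 2000).
#' @export
filter_tss_proximal <- function(peaks, genes, min_dist = 2000) {
  filter_distal(peaks, genes,
                distal_filter_rules(boundary_min_dist = min_dist,
                                    center_min_dist = 0, combine = "and"))
}

#' Keep peaks supported by a second mark
#'
#' Active enhancers carry both H3K27ac and H3K4me1; a peak enters the
#' catalog only if it overlaps a peak of the other mark by at least
#' `min_overlap_frac` of its own width (0 means any overlap of >= 1 bp).
#'
#' @param peaks A [peak_set()] (e.g. H3K27ac).
#' @param support A [peak_set()] of the supporting mark (e.g. H3K4me1).
#' @param min_overlap_frac Fraction of the peak that must be covered.
#' @export
filter_active <- function(peaks, support, min_overlap_frac = 0) {
  if (nrow(peaks) == 0 || nrow(support) == 0)
    return(peaks[integer(0), , drop = FALSE])
  q <- .as_granges(peaks$chrom, peaks$start, peaks$end)
  s <- .as_granges(support$chrom, support$start, support$end)
  ov <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- pmin(peaks$end[qh], support$end[sh]) -
    pmax(peaks$start[qh], support$start[sh])
  cov <- rowsum(w, qh)  # upper bound on covered bp; exact if support disjoint
  keep <- logical(nrow(peaks))
  idx <- as.integer(rownames(cov))
  need <- min_overlap_frac * (peaks$end[idx] - peaks$start[idx])
  keep[idx] <- cov[, 1] >= pmax(1, need)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_label") <- attr(peaks, "source_label")
  class(out) <- class(peaks)
  out
}

# Group ids for single-linkage merging of sorted intervals: consecutive
# intervals on one chromosome join a group when the gap to the running
# group end is strictly smaller than `gap`.
.stitch_groups <- function(chrom, start, end, gap) {
  n <- length(chrom)
  if (n == 0) return(integer(0))
  grp <- integer(n)
  grp[1] <- 1L
  run_end <- end[1]
  for (i in seq_len(n)[-1]) {
    if (chrom[i] == chrom[i - 1] && start[i] - run_end < gap) {
      grp[i] <- grp[i - 1]
      run_end <- max(run_end, end[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      run_end <- end[i]
    }
  }
  grp
}

#' Stitch peaks into enhancer loci
#'
#' Single-linkage merge per chromosome: consecutive peaks whose gap
#' (next start minus running maximum end) is strictly shorter than
#' `stitch_gap` join one enhancer; a gap of exactly `stitch_gap` splits.
#'
#' @param peaks A [peak_set()] (sorted; the constructor guarantees it).
#' @param stitch_gap Maximum gap in bp (default 12500).
#' @return A `data.frame` of class `stitched_enhancers` with columns chrom,
#'   start, end, name, n_constituents, and a list-column `constituents` of
#'   per-locus constituent peak data frames.
#' @export
stitch <- function(peaks, stitch_gap = 12500) {
  stopifnot(stitch_gap >= 0)
  df <- as.data.frame(peaks)
  grp <- .stitch_groups(df$chrom, df$start, df$end, stitch_gap)
  if (length(grp) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      n_constituents = integer())
    out$constituents <- list()
  } else {
    idx <- split(seq_len(nrow(df)), grp)
    out <- data.frame(
      chrom = vapply(idx, function(i) df$chrom[i[1]], ""),
      start = vapply(idx, function(i) min(df$start[i]), 0),
      end = vapply(idx, function(i) max(df$end[i]), 0),
      stringsAsFactors = FALSE)
    out$name <- sprintf("enh_%d", seq_len(nrow(out)))
    out$n_constituents <- lengths(idx)
    out$constituents <- lapply(idx, function(i)
      df[i, c("chrom", "start", "end"), drop = FALSE])
    rownames(out) <- NULL
  }
  attr(out, "stitch_gap") <- stitch_gap
  class(out) <- c("stitched_enhancers", "data.frame")
  out
}

#' Quantify enhancer signal (raw and RPKM)
#'
#' Raw signal is the integral of the track over the enhancer span
#' (`sum(value * overlap width)`); RPKM divides by span length in kb and
#' library size in millions.
#'
#' @param enhancers A [stitch()] result (or any data frame of intervals).
#' @param track A [signal_track()] with `library_size > 0`.
#' @return `enhancers` with columns `raw_signal` and `rpkm` added.
#' @export
quantify <- function(enhancers, track) {
  if (!is.finite(track$library_size) || track$library_size <= 0)
    stop("library_size must be > 0")
  raw <- .overlap_signal(track, enhancers$chrom, enhancers$start,
                         enhancers$end)
  len_kb <- (enhancers$end - enhancers$start) / 1000
  enhancers$raw_signal <- raw
  enhancers$rpkm <- raw / (len_kb * track$library_size / 1e6)
  enhancers
}

#' Super-enhancer cutoff on the signal rank curve
#'
#' Enhancers are sorted ascending by signal; ranks are scaled to `[0, 1]`
#' by `(i - 1)/(N - 1)` and signal by its maximum. The local slope is
#' estimated by central finite differences (forward/backward at the ends)
#' and the cutoff is the first rank, scanning left to right, whose slope
#' strictly exceeds 1 — the tangent-slope-1 point of the curve. Enhancers
#' with signal strictly greater than the cutoff signal are super enhancers.
#'
#' @param enhancers Quantified enhancers (see [quantify()]).
#' @param signal Numeric signal used for ranking; defaults to the raw
#'   total signal (`raw_signal`). Ranking by total signal — not per-kb
#'   density — is what separates super enhancers, whose stitched spans
#'   accumulate signal across many constituents.
#' @return A list with `enhancers` (columns `rank` ascending in signal and
#'   `is_super` added) and `curve`, a `data.frame` of class `rank_curve`
#'   (rank, signal, scaled x/y, slope) with attributes `cutoff_rank` and
#'   `cutoff_signal`.
#' @export
call_super <- function(enhancers, signal = enhancers$raw_signal) {
  n <- length(signal)
  if (n < 3) stop("need >= 3 quantified enhancers for the rank curve")
  if (any(is.na(signal)) || any(signal < 0))
    stop("signal must be non-negative and complete")
  ord <- order(signal)
  y <- signal[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  if (max(y) == 0 || all(y == y[1])) {
    warning("all enhancer signals equal; no super enhancers called")
    ys <- rep(0, n); slope <- rep(0, n)
    cutoff_rank <- n; cutoff_signal <- max(y)
  } else {
    ys <- y / max(y)
    slope <- numeric(n)
    slope[1] <- (ys[2] - ys[1]) / (x[2] - x[1])
    slope[n] <- (ys[n] - ys[n - 1]) / (x[n] - x[n - 1])
    mid <- 2:(n - 1)
    slope[mid] <- (ys[mid + 1] - ys[mid - 1]) / (x[mid + 1] - x[mid - 1])
    crossing <- which(slope > 1)
    if (length(crossing) == 0) {
      cutoff_rank <- n; cutoff_signal <- max(y)
    } else {
      cutoff_rank <- crossing[1]
      cutoff_signal <- y[cutoff_rank]
    }
  }
  rank_vec <- integer(n)
  rank_vec[ord] <- seq_len(n)
  enhancers$rank <- rank_vec
  enhancers$is_super <- signal > cutoff_signal
  curve <- data.frame(rank = seq_len(n), signal = y, x_scaled = x,
                      y_scaled = ys, slope = slope)
  attr(curve, "cutoff_rank") <- cutoff_rank
  attr(curve, "cutoff_signal") <- cutoff_signal
  class(curve) <- c("rank_curve", "data.frame")
  list(enhancers = enhancers, curve = curve)
}

#' Full per-condition enhancer catalog
#'
#' Convenience wrapper: active filter (H3K4me1 support), distal filter,
#' stitching, H3K27ac quantification and super-enhancer calling.
#'
#' @param k27ac_peaks,k4me1_peaks [peak_set()]s for the two marks.
#' @param track Pooled H3K27ac [signal_track()].
#' @param genes A [gene_annotation()].
#' @param rules A [distal_filter_rules()].
#' @param stitch_gap bp (default 12500).
#' @param min_overlap_frac Passed to [filter_active()].
#' @return A list with `enhancers` (quantified, ranked, `is_super`) and
#'   `curve`.
#' @export
call_enhancers <- function(k27ac_peaks, k4me1_peaks, track, genes,
                           rules = distal_filter_rules(),
                           stitch_gap = 12500, min_overlap_frac = 0) {
  active <- filter_active(k27ac_peaks, k4me1_peaks, min_overlap_frac)
  distal <- filter_distal(active, genes, rules)
  enh <- stitch(distal, stitch_gap)
  enh <- quantify(enh, track)
  res <- call_super(enh)
  attr(res$enhancers, "params") <-
    list(stitch_gap = stitch_gap, rules = unclass(rules),
         min_overlap_frac = min_overlap_frac)
  res
}
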