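# Replicate/mark QC: genome-wide binned-track correlation and
# peak-centered metagene aggregate profiles.

#' Bin a signal track into fixed windows
#'
#' Windows tile each chromosome exactly (the last bin may be short); the
#' bin value is the integral of the track over the bin, so binning
#' conserves total signal.
#'
#' @param track A [signal_track()].
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Window size in bp (default 2000).
#' @return List of class `binned_track` with `bins` (chrom, start, end,
#'   value) and `bin_size`.
#' @export
bin_track <- function(track, chrom_sizes, bin_size = 2000) {
  stopifnot(bin_size >= 1)
  missing <- setdiff(unique(track$runs$chrom), names(chrom_sizes))
  if (length(missing) > 0)
    stop(sprintf("chromosome(s) missing from sizes: %s",
                 paste(missing, collapse = ", ")))
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    start <- seq(0, size - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, size),
               stringsAsFactors = FALSE)
  }))
  bins$value <- .overlap_signal(track, bins$chrom, bins$start, bins$end)
  structure(list(bins = bins, bin_size = bin_size,
                 chrom_sizes = chrom_sizes),
            class = "binned_track")
}

#' Correlate two binned tracks
#'
#' Spearman (default) correlation over paired bins; bins that are zero in
#' both tracks are excluded by default so that the empty genome does not
#' dominate the coefficient.
#'
#' @param a,b [bin_track()] results with identical binning.
#' @param method Passed to [stats::cor()] (default `"spearman"`).
#' @param drop_both_zero Exclude bins zero in both tracks (default TRUE).
#' @return The correlation coefficient.
#' @export
correlate_tracks <- function(a, b, method = "spearman",
                             drop_both_zero = TRUE) {
  if (!identical(a$bins[c("chrom", "start", "end")],
                 b$bins[c("chrom", "start", "end")]))
    stop("binning mismatch between tracks")
  x <- a$bins$value; y <- b$bins$value
  if (drop_both_zero) {
    keep <- x != 0 | y != 0
    x <- x[keep]; y <- y[keep]
  }
  stats::cor(x, y, method = method)
}

#' Peak-centered metagene profile
#'
#' For every peak the signal is averaged per base pair in fixed offset
#' bins over `[center - flank, center + flank)`, then averaged across
#' peaks. Bins extending past the chromosome start contribute only their
#' covered part; a peak contributes nothing to a bin that lies entirely
#' off-chromosome.
#'
#' @param peaks A [peak_set()] (non-empty).
#' @param track A [signal_track()].
#' @param flank Half-window in bp (default 3000: a 6 kb view).
#' @param bin_size Offset bin width in bp (default 50).
#' @return `data.frame` of class `meta_profile` with columns
#'   `offset_start`, `offset_end` (relative to peak center),
#'   `mean_signal` (per bp) and `n_peaks` contributing.
#' @export
metagene <- function(peaks, track, flank = 3000, bin_size = 50) {
  if (nrow(peaks) == 0) stop("need at least one peak")
  stopifnot(flank %% bin_size == 0)
  nb <- 2 * flank / bin_size
  offs <- seq(-flank, flank - bin_size, by = bin_size)
  center <- floor((peaks$start + peaks$end) / 2)
  np <- nrow(peaks)
  q_chrom <- rep(peaks$chrom, each = nb)
  q_start0 <- rep(center, each = nb) + rep(offs, np)
  q_end0 <- q_start0 + bin_size
  q_start <- pmax(q_start0, 0)
  covered <- q_end0 - q_start
  ok <- covered > 0
  val <- numeric(length(q_start0))
  val[ok] <- .overlap_signal(track, q_chrom[ok], q_start[ok], q_end0[ok]) /
    covered[ok]
  bin_idx <- rep(seq_len(nb), np)
  mean_signal <- as.numeric(rowsum(val * ok, bin_idx) /
                              pmax(1, rowsum(as.numeric(ok), bin_idx)))
  out <- data.frame(offset_start = offs, offset_end = offs + bin_size,
                    mean_signal = mean_signal,
                    n_peaks = as.integer(rowsum(as.numeric(ok), bin_idx)))
  class(out) <- c("meta_profile", "data.frame")
  out
}
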