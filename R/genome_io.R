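# All coordinates in this package are 0-based half-open (BED convention),
# both in memory and on disk. GTF input is converted on read (start - 1).
# Chromosome names are taken verbatim: no "chr" normalisation is attempted,
# and a namespace mismatch between files surfaces as a validation error in
# the stage that combines them, never as a silent zero overlap.

.split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

.is_comment <- function(lines) {
  grepl("^\\s*(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
}

.sort_order <- function(chrom, start, end) {
  order(chrom, start, end, method = "radix")
}

.check_coords <- function(chrom, start, end, lineno, path) {
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop(sprintf("non-numeric coordinate at line %d of '%s'", lineno[bad[1]], path))
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(sprintf("start >= end at line %d of '%s'", lineno[bad[1]], path))
  bad <- which(start < 0)
  if (length(bad) > 0)
    stop(sprintf("negative start at line %d of '%s'", lineno[bad[1]], path))
  invisible(NULL)
}

#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in 0-based half-open
#' coordinates, canonically sorted by (chrom, start, end) and de-duplicated.
#' It is the universal currency passed between pipeline stages.
#'
#' @param chrom Character vector of chromosome names (taken verbatim).
#' @param start,end Integer vectors, 0-based half-open; `start < end`.
#' @param name Optional interval identifiers.
#' @param score Optional numeric scores.
#' @param strand Optional strand (`+`, `-` or `.`).
#' @param source_label Free-text provenance label (e.g. `"H3K27ac_tumor"`).
#' @return A `data.frame` of class `peak_set` with attribute `source_label`.
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NULL, score = NULL, strand = NULL,
                     source_label = "") {
  if (length(chrom) == 1 && length(start) > 1)
    chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) > 0) {
    if (any(!nzchar(chrom))) stop("empty chromosome name in peak set")
    if (any(is.na(start) | is.na(end))) stop("NA coordinate in peak set")
    if (any(start < 0)) stop("negative start in peak set")
    if (any(start >= end)) stop("start >= end in peak set")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  o <- .sort_order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source_label") <- source_label
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read genomic intervals from BED or broadPeak
#'
#' @param path File path.
#' @param format `"bed"` (>= 3 columns) or `"broadPeak"` (ENCODE 9-column;
#'   the signal-value column 7 is kept as the score).
#' @param source_label Provenance label stored on the result.
#' @return A [peak_set()].
#' @export
read_intervals <- function(path, format = c("bed", "broadPeak"),
                           source_label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  keep <- !.is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warning(sprintf("empty interval file: '%s'", path))
    return(peak_set(source_label = source_label))
  }
  fields <- .split_ws(lines)
  n <- lengths(fields)
  minc <- if (format == "broadPeak") 9L else 3L
  bad <- which(n < minc)
  if (length(bad) > 0)
    stop(sprintf("malformed line %d of '%s': expected >= %d columns, found %d",
                 lineno[bad[1]], path, minc, n[bad[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  .check_coords(chrom, start, end, lineno, path)
  name <- score <- strand <- NULL
  if (format == "broadPeak") {
    name <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  } else {
    if (all(n >= 4)) name <- vapply(fields, `[[`, "", 4L)
    if (all(n >= 5))
      score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (all(n >= 6)) strand <- vapply(fields, `[[`, "", 6L)
  }
  peak_set(chrom, start, end, name = name, score = score, strand = strand,
           source_label = source_label)
}

#' Write a peak set as BED
#'
#' Tab-delimited, 0-based half-open, sorted; the inverse of
#' [read_intervals()] (round trips are identities). Writes 3, 4 or 5+
#' columns depending on which optional fields are present.
#'
#' @param peaks A [peak_set()] (or plain data frame with chrom/start/end).
#' @param path Output path.
#' @export
write_intervals <- function(peaks, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(peaks$name)) cols <- c(cols, "name")
  if (!is.null(peaks$score)) {
    if (is.null(peaks$name))
      peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
    cols <- c("chrom", "start", "end", "name", "score")
  }
  if (!is.null(peaks$strand) && all(c("name", "score") %in% cols))
    cols <- c(cols, "strand")
  df <- as.data.frame(peaks)[, cols, drop = FALSE]
  if ("score" %in% cols) df$score <- sprintf("%.17g", df$score)
  df$start <- sprintf("%d", as.integer(df$start))
  df$end <- sprintf("%d", as.integer(df$end))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                      conditionMessage(e))))
  invisible(ok)
}

#' Construct a signal track
#'
#' A coverage-style track: per-chromosome runs of `(start, end, value)` with
#' non-negative values, value interpreted as reads (or arbitrary signal) per
#' base pair. `total_signal` is the integral `sum(value * width)`;
#' `library_size` is the mapped-read count used for RPKM scaling and
#' defaults to `total_signal`.
#'
#' @param runs Data frame with columns chrom, start, end, value.
#' @param library_size Mapped reads in the library (> 0).
#' @return An object of class `signal_track`: list with elements `runs`,
#'   `total_signal`, `library_size`.
#' @export
signal_track <- function(runs, library_size = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(runs)))
  runs <- as.data.frame(runs)[, c("chrom", "start", "end", "value")]
  runs$chrom <- as.character(runs$chrom)
  runs$start <- as.numeric(runs$start)
  runs$end <- as.numeric(runs$end)
  runs$value <- as.numeric(runs$value)
  if (nrow(runs) > 0) {
    if (any(is.na(runs$value)) || any(!is.finite(runs$value)))
      stop("non-finite signal value")
    if (any(runs$value < 0)) stop("negative signal value")
    if (any(runs$start >= runs$end)) stop("start >= end in signal run")
    o <- .sort_order(runs$chrom, runs$start, runs$end)
    runs <- runs[o, , drop = FALSE]
    same <- runs$chrom[-1] == runs$chrom[-nrow(runs)]
    if (nrow(runs) > 1 && any(same & runs$start[-1] < runs$end[-nrow(runs)]))
      stop("overlapping runs within a chromosome")
    rownames(runs) <- NULL
  }
  total <- sum(runs$value * (runs$end - runs$start))
  if (is.null(library_size)) library_size <- total
  structure(list(runs = runs, total_signal = total,
                 library_size = as.numeric(library_size)),
            class = "signal_track")
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path (4 columns: chrom, start, end, value).
#' @param library_size Optional mapped-read count; defaults to the track
#'   integral.
#' @return A [signal_track()].
#' @export
read_signal <- function(path, library_size = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  keep <- !.is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(signal_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), value = numeric()),
                        library_size))
  fields <- .split_ws(lines)
  bad <- which(lengths(fields) < 4)
  if (length(bad) > 0)
    stop(sprintf("malformed line %d of '%s': bedGraph needs 4 columns",
                 lineno[bad[1]], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  .check_coords(chrom, start, end, lineno, path)
  bad <- which(is.na(value))
  if (length(bad) > 0)
    stop(sprintf("non-numeric value at line %d of '%s'", lineno[bad[1]], path))
  bad <- which(value < 0)
  if (length(bad) > 0)
    stop(sprintf("negative value at line %d of '%s'", lineno[bad[1]], path))
  signal_track(data.frame(chrom = chrom, start = start, end = end,
                          value = value, stringsAsFactors = FALSE),
               library_size)
}

#' Write a signal track as bedGraph
#'
#' Values are written with full precision so that
#' `read_signal(write_signal(x))` reproduces `x` exactly.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @export
write_signal <- function(track, path) {
  r <- track$runs
  out <- data.frame(chrom = r$chrom,
                    start = sprintf("%d", as.integer(r$start)),
                    end = sprintf("%d", as.integer(r$end)),
                    value = sprintf("%.17g", r$value))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(TRUE)
}

#' Construct a gene annotation
#'
#' The transcription start site (TSS) is derived from strand: `start` on
#' `+`, `end - 1` on `-` (0-based coordinates).
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom,start,end 0-based half-open gene bodies.
#' @param strand `+` or `-`.
#' @return A `data.frame` of class `gene_annotation` with a derived `tss`
#'   column.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0)
    stop(sprintf("duplicate gene_id: %s",
                 paste(unique(dup), collapse = ", ")))
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("start >= end in gene annotation")
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   start = start, end = end, strand = as.character(strand),
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  o <- .sort_order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation from BED6 or minimal GTF
#'
#' BED6 columns: chrom, start, end, gene_id, score, strand (0-based).
#' GTF: only `gene` features are used; transcript/exon lines are ignored;
#' 1-based starts are converted to the package's 0-based convention.
#'
#' @param path File path.
#' @param format `"bed6"` or `"gtf"`.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  keep <- !.is_comment(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop(sprintf("empty annotation file: '%s'", path))
  if (format == "bed6") {
    fields <- .split_ws(lines)
    bad <- which(lengths(fields) < 6)
    if (length(bad) > 0)
      stop(sprintf("line %d of '%s': BED6 needs 6 columns (strand missing?)",
                   lineno[bad[1]], path))
    gene_annotation(gene_id = vapply(fields, `[[`, "", 4L),
                    chrom = vapply(fields, `[[`, "", 1L),
                    start = as.numeric(vapply(fields, `[[`, "", 2L)),
                    end = as.numeric(vapply(fields, `[[`, "", 3L)),
                    strand = vapply(fields, `[[`, "", 6L))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9)
    if (length(bad) > 0)
      stop(sprintf("line %d of '%s': GTF needs 9 tab-separated columns",
                   lineno[bad[1]], path))
    feat <- vapply(fields, `[[`, "", 3L)
    fields <- fields[feat == "gene"]
    if (length(fields) == 0)
      stop(sprintf("no 'gene' features in '%s'", path))
    attrs <- vapply(fields, `[[`, "", 9L)
    m <- regmatches(attrs, regexpr('gene_id "?[^";]+', attrs))
    if (length(m) != length(attrs))
      stop(sprintf("GTF gene feature without gene_id in '%s'", path))
    gene_id <- sub('^gene_id "?', "", m)
    gene_annotation(gene_id = gene_id,
                    chrom = vapply(fields, `[[`, "", 1L),
                    start = as.numeric(vapply(fields, `[[`, "", 4L)) - 1,
                    end = as.numeric(vapply(fields, `[[`, "", 5L)),
                    strand = vapply(fields, `[[`, "", 7L))
  }
}

#' Construct a count matrix
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param groups Named character vector mapping every sample id to
#'   `"normal"` or `"tumor"`.
#' @param gene_lengths Named numeric vector of gene lengths in bp.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  orphan <- setdiff(colnames(counts), names(groups))
  if (length(orphan) > 0)
    stop(sprintf("sample(s) missing from group map: %s",
                 paste(orphan, collapse = ", ")))
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("normal", "tumor")))
    stop("groups must be 'normal' or 'tumor'")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0))
    stop("every gene needs a positive length")
  structure(list(counts = counts, groups = groups,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' Read a gene-by-sample count matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' A column named `length` is used for gene lengths; otherwise supply a
#' [gene_annotation()] via `annotation` (lengths = gene-body width).
#'
#' @param path TSV path.
#' @param groups Named character vector (sample -> normal/tumor) or path to
#'   a 2-column TSV `sample<TAB>group`.
#' @param annotation Optional [gene_annotation()] used for gene lengths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, groups, annotation = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    gm <- utils::read.table(groups, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    groups <- stats::setNames(gm[[2]], gm[[1]])
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]
  if ("length" %in% names(tab)) {
    gene_lengths <- stats::setNames(as.numeric(tab[["length"]]), gene_ids)
    tab <- tab[, setdiff(names(tab), "length"), drop = FALSE]
  } else if (!is.null(annotation)) {
    gene_lengths <- stats::setNames(annotation$end - annotation$start,
                                    annotation$gene_id)[gene_ids]
  } else {
    stop("gene lengths needed: add a 'length' column or pass an annotation")
  }
  counts <- as.matrix(tab)
  if (any(counts != round(counts)))
    stop(sprintf("non-integer count for gene '%s'",
                 gene_ids[which(rowSums(counts != round(counts)) > 0)[1]]))
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  count_matrix(counts, groups, gene_lengths)
}

#' Write a count matrix as TSV (inverse of [read_count_matrix()])
#' @param cm A [count_matrix()].
#' @param path Output TSV path.
#' @param groups_path Optional path for the 2-column sample-group map.
#' @export
write_count_matrix <- function(cm, path, groups_path = NULL) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = as.numeric(cm$gene_lengths),
                   cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path))
    utils::write.table(data.frame(names(cm$groups), unname(cm$groups)),
                       groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(TRUE)
}

# data.frame (0-based half-open) -> GRanges (1-based closed), internal
.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1, end = end))
}

# Sum of value * overlap width of track runs over query intervals.
.overlap_signal <- function(track, chrom, start, end) {
  r <- track$runs
  out <- numeric(length(chrom))
  if (nrow(r) == 0 || length(chrom) == 0) return(out)
  q <- .as_granges(chrom, start, end)
  s <- .as_granges(r$chrom, r$start, r$end)
  ov <- GenomicRanges::findOverlaps(q, s)
  if (length(ov) == 0) return(out)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- pmin(end[qh], r$end[sh]) - pmax(start[qh], r$start[sh])
  agg <- rowsum(r$value[sh] * w, group = qh)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
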