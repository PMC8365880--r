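# Known-motif enrichment of gain-VEL sequences: JASPAR PWM parsing,
# log-odds scanning of both strands, one-sided exact enrichment tests
# against a background set, and background construction (dinucleotide
# shuffle or genomic sampling).

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts are converted to probabilities with a pseudocount per cell and a
#' log2 odds matrix against the background is derived.
#'
#' @param counts 4-by-L numeric matrix, rows A/C/G/T.
#' @param motif_id,tf_name Identifiers.
#' @param background Base probabilities (default uniform).
#' @param pseudocount Added to every count cell (default 0.5).
#' @return List of class `pwm` with elements counts, matrix
#'   (probabilities), background, log_odds, motif_id, tf_name.
#' @export
pwm <- function(counts, motif_id, tf_name = motif_id,
                background = rep(0.25, 4), pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM counts need 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("PWM must be at least 4 positions long")
  if (any(counts < 0)) stop("negative count in PWM")
  rownames(counts) <- .BASES
  prob <- sweep(counts + pseudocount, 2,
                colSums(counts) + 4 * pseudocount, "/")
  if (any(abs(colSums(prob) - 1) > 1e-6))
    stop("PWM columns do not sum to 1")
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  lo <- log2(prob / background)
  structure(list(motif_id = motif_id, tf_name = tf_name, counts = counts,
                 matrix = prob, background = background, log_odds = lo),
            class = "pwm")
}

#' Build a sharp PWM from a consensus string
#'
#' @param consensus e.g. `"TGACTCA"`, the TPA-response element bound by
#'   AP-1 family dimers.
#' @param motif_id,tf_name Identifiers.
#' @param strength Count given to the consensus base at each position;
#'   the other three bases get 1.
#' @export
consensus_pwm <- function(consensus, motif_id = consensus,
                          tf_name = motif_id, strength = 97) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% .BASES)) stop("consensus must be over A/C/G/T")
  counts <- matrix(1, 4, length(bases), dimnames = list(.BASES, NULL))
  counts[cbind(match(bases, .BASES), seq_along(bases))] <- strength
  pwm(counts, motif_id, tf_name)
}

#' The canonical AP-1 motif (TPA-response element, TGACTCA)
#' @export
ap1_pwm <- function() consensus_pwm("TGACTCA", "AP1", "AP-1")

#' Read PWMs from JASPAR text
#'
#' Accepts the 2016+ JASPAR flat format: a `>ID NAME` header followed by
#' four rows `A [ 3 5 ... ]` (brackets optional).
#'
#' @param path File path.
#' @param background,pseudocount Passed to [pwm()].
#' @return List of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount = 0.5) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' motif headers found")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[k]]), "\\s+")[[1]]
    motif_id <- hdr[1]
    tf_name <- if (length(hdr) > 1) hdr[2] else hdr[1]
    body <- lines[(starts[k] + 1):(bounds[k + 1] - 1)]
    if (length(body) < 4)
      stop(sprintf("motif '%s': expected 4 base rows", motif_id))
    rows <- lapply(body[1:4], function(l) {
      l <- sub("^\\s*[ACGTacgt]\\b", " ", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    len <- unique(lengths(rows))
    if (length(len) != 1)
      stop(sprintf("motif '%s': row lengths differ", motif_id))
    counts <- do.call(rbind, rows)
    if (any(is.na(counts)))
      stop(sprintf("motif '%s': non-numeric count", motif_id))
    out[[k]] <- pwm(counts, motif_id, tf_name, background, pseudocount)
  }
  names(out) <- vapply(out, `[[`, "", "motif_id")
  out
}

#' Write PWMs in JASPAR text format (counts; inverse of [read_jaspar()])
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$tf_name), con)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", .BASES[b],
                         paste(sprintf("%.17g", p$counts[b, ]),
                               collapse = " ")), con)
  }
  invisible(TRUE)
}

.encode_seq <- function(s) {
  code <- match(strsplit(toupper(s), "")[[1]], c(.BASES, "N"))
  if (any(is.na(code))) stop("sequence contains non-ACGTN characters")
  code
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

# Window log-odds scores of an encoded sequence (codes 1..5, 5 = N).
# N scores as the minimum base log-odds of that position.
.window_scores <- function(code, lo5) {
  m <- ncol(lo5)
  W <- length(code) - m + 1
  if (W < 1) return(numeric(0))
  s <- numeric(W)
  for (j in seq_len(m))
    s <- s + lo5[code[j:(j + W - 1)], j]
  s
}

#' Scan sequences with a PWM
#'
#' Both strands are scanned; a window is a hit when its summed log2-odds
#' score reaches `threshold_fraction` of the maximum attainable score.
#' `N` bases score as the position's minimum base log-odds.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`.
#' @param p A [pwm()].
#' @param threshold_fraction In (0, 1]; default 0.8.
#' @return List: `hits` data frame (seq_id, start 0-based on the forward
#'   strand, strand, score) and `has_hit`, a named logical per sequence.
#' @export
scan_pwm <- function(sequences, p, threshold_fraction = 0.8) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  lo <- p$log_odds
  lo5 <- rbind(lo, apply(lo, 2, min))  # row 5: N
  m <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- threshold_fraction * max_score
  hits <- list()
  has_hit <- stats::setNames(logical(length(sequences)), names(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    n <- nchar(s)
    if (n < m) {
      warning(sprintf("sequence '%s' shorter than motif; skipped",
                      names(sequences)[i]))
      next
    }
    fw <- .window_scores(.encode_seq(s), lo5)
    rv <- .window_scores(.encode_seq(.revcomp(s)), lo5)
    fi <- which(fw >= thr)
    ri <- which(rv >= thr)
    if (length(fi) + length(ri) > 0) {
      has_hit[i] <- TRUE
      hits[[length(hits) + 1]] <- data.frame(
        seq_id = names(sequences)[i],
        start = c(fi - 1, n - m - ri + 1),  # 0-based forward coordinates
        strand = rep(c("+", "-"), c(length(fi), length(ri))),
        score = c(fw[fi], rv[ri]),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_id = character(), start = numeric(),
               strand = character(), score = numeric())
  list(hits = hits, has_hit = has_hit, max_score = max_score)
}

#' Rank motifs by enrichment in foreground vs background sequences
#'
#' For each motif the sequences are dichotomised (>= 1 hit or none) and a
#' one-sided hypergeometric test (Fisher exact, enrichment direction)
#' compares foreground to background hit fractions. Motifs are ranked by
#' ascending p-value, ties by motif id.
#'
#' @param fg,bg Foreground / background sequences (named character vectors
#'   or `DNAStringSet`).
#' @param pwms List of [pwm()]s.
#' @param threshold_fraction Passed to [scan_pwm()].
#' @return `data.frame` of class `enrichment_results`: motif_id, tf_name,
#'   fg_hits, fg_total, bg_hits, bg_total, p_value, rank.
#' @export
enrich_motifs <- function(fg, bg, pwms, threshold_fraction = 0.8) {
  if (length(fg) == 0 || length(bg) == 0)
    stop("foreground and background must be non-empty")
  rows <- lapply(pwms, function(p) {
    fh <- sum(scan_pwm(fg, p, threshold_fraction)$has_hit)
    bh <- sum(scan_pwm(bg, p, threshold_fraction)$has_hit)
    data.frame(motif_id = p$motif_id, tf_name = p$tf_name,
               fg_hits = fh, fg_total = length(fg),
               bg_hits = bh, bg_total = length(bg),
               p_value = stats::phyper(fh - 1, fh + bh,
                                       length(fg) + length(bg) - fh - bh,
                                       length(fg), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$motif_id, method = "radix"), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence.
.dinuc_shuffle_one <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n <= 2) return(s)
  verts <- unique(chars)
  edges <- split(chars[-1], factor(chars[-n], levels = verts))
  last <- chars[n]
  # choose one terminal edge per non-final vertex so that following them
  # always reaches the final vertex (a spanning arborescence into `last`)
  repeat {
    term <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, "")
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(term[[v]])) next
      seen <- v; cur <- v
      repeat {
        cur <- term[[cur]]
        if (is.na(cur) || is.null(cur)) { ok <- cur %in% last; break }
        if (cur == last) break
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  pool <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (is.na(term[[v]])) return(sample(e))
    e <- e[-match(term[[v]], e)]
    c(sample(e), term[[v]])
  })
  names(pool) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- pool[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Build a background sequence set
#'
#' `dinucleotide_shuffle` permutes each foreground sequence while exactly
#' preserving its dinucleotide counts (Euler-path shuffle), hence also
#' length and mononucleotide composition. `genomic_sample` draws
#' length-matched windows from a supplied genome, excluding given loci.
#'
#' @param fg Named character vector (or `DNAStringSet`) of foreground
#'   sequences.
#' @param method `"dinucleotide_shuffle"` or `"genomic_sample"`.
#' @param seed Integer seed; the result is deterministic given it.
#' @param genome Named character vector chrom -> sequence (or a FASTA path)
#'   for `genomic_sample`.
#' @param exclude Optional data frame chrom/start/end of loci to avoid.
#' @return Named character vector of background sequences.
#' @export
make_background <- function(fg, method = c("dinucleotide_shuffle",
                                           "genomic_sample"),
                            seed = 1, genome = NULL, exclude = NULL) {
  method <- match.arg(method)
  if (methods::is(fg, "DNAStringSet"))
    fg <- stats::setNames(as.character(fg), names(fg))
  if (length(fg) == 0) stop("foreground must be non-empty")
  if (is.null(names(fg))) names(fg) <- sprintf("seq_%d", seq_along(fg))
  set.seed(seed)
  if (method == "dinucleotide_shuffle") {
    out <- vapply(fg, .dinuc_shuffle_one, "")
    names(out) <- paste0(names(fg), "_shuf")
    return(out)
  }
  if (is.null(genome))
    stop("genomic_sample needs a genome (FASTA path or named sequences)")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    gss <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(gss), names(gss))
  }
  out <- character(length(fg))
  for (i in seq_along(fg)) {
    len <- nchar(fg[[i]])
    repeat {
      ch <- sample(names(genome), 1)
      L <- nchar(genome[[ch]])
      if (L < len) next
      st <- sample.int(L - len + 1, 1) - 1  # 0-based
      clash <- !is.null(exclude) &&
        any(exclude$chrom == ch & exclude$start < st + len &
              exclude$end > st)
      if (!clash) break
    }
    out[i] <- substr(genome[[ch]], st + 1, st + len)
  }
  names(out) <- paste0(names(fg), "_bg")
  out
}
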