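# Proximal-gene assignment and the set-logic layer: VEL x DEG overlaps,
# multi-TF target intersections, the three-way coordinated-gene overlap,
# and top-n ranking of differentially expressed target genes.

#' Assign each locus its proximal gene
#'
#' The proximal gene is the gene whose TSS is nearest to the locus center;
#' ties are broken by the lexicographically smaller gene id. Loci on a
#' chromosome with no annotated gene, or farther than `max_dist` when set,
#' map to `NA`.
#'
#' @param loci Data frame with chrom/start/end (e.g. VEL records).
#' @param genes A [gene_annotation()].
#' @param max_dist Optional cap on center-to-TSS distance in bp.
#' @return Character vector of gene ids, one per locus.
#' @export
assign_proximal_gene <- function(loci, genes, max_dist = NULL) {
  if (!inherits(genes, "gene_annotation") || nrow(genes) == 0)
    stop("empty gene annotation")
  n <- nrow(loci)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  center <- floor((loci$start + loci$end) / 2)
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    # order TSS, resolving equal-TSS genes to the smaller id up front
    g <- g[order(g$tss, g$gene_id, method = "radix"), , drop = FALSE]
    tss <- g$tss
    pos <- findInterval(center[li], tss)
    for (k in seq_along(li)) {
      j <- pos[k]
      cc <- center[li[k]]
      cand <- unique(pmin(pmax(c(j, j + 1), 1L), length(tss)))
      mind <- min(abs(tss[cand] - cc))
      best <- which(abs(tss - cc) == mind)  # full tie set (shared TSSs)
      if (length(best) > 1)
        best <- best[order(g$gene_id[best], method = "radix")[1]]
      if (is.null(max_dist) || mind <= max_dist)
        out[li[k]] <- g$gene_id[best]
    }
  }
  out
}

#' Overlap VEL proximal genes with DEGs
#'
#' Intersects gain-VEL proximal genes with up-regulated DEGs and lost-VEL
#' proximal genes with down-regulated DEGs, reporting all marginal and
#' intersection cardinalities.
#'
#' @param vels [call_vels()] records carrying a `proximal_gene` column.
#' @param degs [call_degs()] records.
#' @return List of class `gene_set_overlap`: `gain_up`, `lost_down`
#'   (character vectors) and a `counts` vector of cardinalities.
#' @export
overlap_vel_degs <- function(vels, degs) {
  if (nrow(vels) == 0 || nrow(degs) == 0)
    stop("VEL and DEG inputs must be non-empty")
  if (is.null(vels$proximal_gene))
    stop("assign proximal genes first (assign_proximal_gene)")
  gain_genes <- unique(stats::na.omit(vels$proximal_gene[
    vels$status == "gain"]))
  lost_genes <- unique(stats::na.omit(vels$proximal_gene[
    vels$status == "lost"]))
  up <- degs$gene_id[degs$status == "up"]
  down <- degs$gene_id[degs$status == "down"]
  if (length(intersect(unique(stats::na.omit(vels$proximal_gene)),
                       degs$gene_id)) == 0)
    warning("VEL and DEG gene namespaces are disjoint")
  res <- list(gain_up = sort(intersect(gain_genes, up)),
              lost_down = sort(intersect(lost_genes, down)),
              counts = c(n_gain_vel_genes = length(gain_genes),
                         n_lost_vel_genes = length(lost_genes),
                         n_up_degs = length(up),
                         n_down_degs = length(down),
                         n_gain_up = length(intersect(gain_genes, up)),
                         n_lost_down = length(intersect(lost_genes, down))))
  class(res) <- "gene_set_overlap"
  res
}

#' Exclusive Venn-region cardinalities of named sets
#'
#' @param sets Named list of character vectors.
#' @return Named integer vector; names are `&`-joined set labels, one entry
#'   per non-empty membership pattern region (exclusive counts).
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  labels <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  out <- integer(0)
  for (pattern in seq_len(2^length(sets) - 1)) {
    inset <- as.logical(bitwAnd(pattern, 2^(seq_along(sets) - 1)))
    region <- paste(labels[inset], collapse = "&")
    cnt <- sum(apply(memb, 1, function(r) all(r == inset)))
    out[region] <- cnt
  }
  out
}

#' Intersect transcription-factor target lists
#'
#' @param lists Named list (>= 2) of character vectors of target gene ids,
#'   e.g. the proximal-gene targets of BATF, FOS and JUNB binding sites.
#' @return List of class `tf_intersection`: `common` (genes targeted by
#'   all TFs, sorted) and `venn` (exclusive region counts).
#' @export
intersect_tf_targets <- function(lists) {
  if (length(lists) < 2) stop("need >= 2 target lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- sprintf("TF%d", seq_along(lists))
  common <- sort(Reduce(intersect, lists))
  structure(list(common = common, venn = venn_counts(lists)),
            class = "tf_intersection")
}

#' Three-way overlap of TF targets, up DEGs and gain-VEL genes
#'
#' The coordinated-gene analysis: genes that are common TF targets, are
#' up-regulated, and sit proximal to a gain VEL.
#'
#' @param tf_common,up_degs,gain_vel_genes Character vectors of gene ids.
#' @return List of class `triple_overlap`: `genes` (the three-way
#'   intersection, sorted) and `venn` (all seven region counts).
#' @export
triple_overlap <- function(tf_common, up_degs, gain_vel_genes) {
  sets <- list(tf_targets = unique(tf_common),
               up_degs = unique(up_degs),
               gain_vel_genes = unique(gain_vel_genes))
  genes <- sort(Reduce(intersect, sets))
  structure(list(genes = genes, venn = venn_counts(sets)),
            class = "triple_overlap")
}

#' Top differentially expressed genes within a gene set
#'
#' @param degs [call_degs()] records.
#' @param genes Gene ids restricting the ranking (default: all).
#' @param n How many to return (default 10).
#' @return `deg_records` rows ordered by descending log2 fold change (ties
#'   by gene id), first `n`.
#' @export
rank_top <- function(degs, genes = degs$gene_id, n = 10) {
  if (n <= 0) stop("n must be positive")
  sub <- degs[degs$gene_id %in% genes, , drop = FALSE]
  sub <- sub[order(-sub$log2fc, sub$gene_id, method = "radix"), ,
             drop = FALSE]
  out <- utils::head(sub, n)
  rownames(out) <- NULL
  out
}

#' Read a gene-set file (one id per line, `#` comments)
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Write a gene set (one id per line)
#' @param genes Character vector.
#' @param path Output path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(TRUE)
}
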