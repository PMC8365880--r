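# One-config orchestration of the full analysis: simulated or real inputs
# through enhancer calling (per condition), the differential layer,
# integration, motif enrichment and QC, with a run manifest.

#' Pipeline configuration
#'
#' Stage parameters default to the analysis' standard values: 12,500 bp
#' stitching, 1,500/3,000 bp distal rules, fold-change thresholds 2 and
#' 0.5, DEG thresholds |log2FC| >= 1 at p < 0.05, pseudocount 1.
#'
#' @param simulate Generate inputs with the synthetic module.
#' @param outdir Output directory (created if absent).
#' @param sim A [sim_config()] (simulate mode).
#' @param paths Named list of input paths (real mode): genes, counts,
#'   groups, per mark/condition/replicate peak and track files,
#'   sequences FASTA, motifs (JASPAR), tf_targets (named list).
#' @param stitch_gap,rules,min_overlap_frac Enhancer-calling parameters.
#' @param fc_up,fc_down,rpkm_pseudocount VEL parameters.
#' @param lfc_min,alpha,fpkm_pseudocount DEG parameters.
#' @param threshold_fraction,n_decoys Motif parameters.
#' @param bin_size,flank,meta_bin QC parameters.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, outdir = tempfile("escape_"),
                            sim = sim_config(seed = seed), paths = list(),
                            stitch_gap = 12500,
                            rules = distal_filter_rules(),
                            min_overlap_frac = 0,
                            fc_up = 2.0, fc_down = 0.5,
                            rpkm_pseudocount = 1.0,
                            lfc_min = 1.0, alpha = 0.05,
                            fpkm_pseudocount = 1.0,
                            threshold_fraction = 0.8, n_decoys = 10,
                            bin_size = 2000, flank = 3000, meta_bin = 50,
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$sim$seed <- seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `sim` and
#' `rules` may be nested maps.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$rules)) y$rules <- do.call(distal_filter_rules, y$rules)
  do.call(pipeline_config, y)
}

.need_path <- function(paths, key) {
  p <- paths[[key]]
  if (is.null(p))
    stop(sprintf("config$paths$%s is missing", key))
  p
}

.fa_names <- function(name, chrom, start, end)
  sprintf("%s::%s:%d-%d", name, chrom, as.integer(start), as.integer(end))

.parse_fa_coords <- function(nm) {
  m <- regmatches(nm, regexec("^([^:]+)::([^:]+):(\\d+)-(\\d+)$", nm))
  ok <- lengths(m) == 5
  data.frame(seq_id = nm,
             name = vapply(m, function(x) if (length(x) == 5) x[2] else
               NA_character_, ""),
             chrom = vapply(m, function(x) if (length(x) == 5) x[3] else
               NA_character_, ""),
             start = vapply(m, function(x) if (length(x) == 5)
               as.numeric(x[4]) else NA_real_, 0),
             end = vapply(m, function(x) if (length(x) == 5)
               as.numeric(x[5]) else NA_real_, 0),
             stringsAsFactors = FALSE)[ok, , drop = FALSE]
}

# indices of `called` loci matching each truth interval by >= `frac`
# reciprocal overlap (NA where unmatched)
#' Match truth intervals to called loci by reciprocal overlap
#' @param truth_iv,called Data frames with chrom/start/end.
#' @param frac Minimum reciprocal overlap fraction (default 0.5).
#' @return Integer vector: for each truth row, the index of the matching
#'   called row or `NA`.
#' @export
match_loci <- function(truth_iv, called, frac = 0.5) {
  out <- rep(NA_integer_, nrow(truth_iv))
  if (nrow(called) == 0 || nrow(truth_iv) == 0) return(out)
  q <- .as_granges(truth_iv$chrom, truth_iv$start, truth_iv$end)
  s <- .as_granges(called$chrom, called$start, called$end)
  ov <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- pmin(truth_iv$end[qh], called$end[sh]) -
    pmax(truth_iv$start[qh], called$start[sh])
  good <- w >= frac * (truth_iv$end[qh] - truth_iv$start[qh]) &
    w >= frac * (called$end[sh] - called$start[sh])
  for (k in which(good)) out[qh[k]] <- sh[k]
  out
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, NA), drop = FALSE]
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(x)
    ifelse(x == round(x) & abs(x) < 2^31, sprintf("%d", as.integer(round(x))),
           sprintf("%.10g", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.simulate_inputs <- function(config, dir) {
  gen <- simulate_genome(config$sim)
  chip <- simulate_chip_tracks(gen$truth, config$sim)
  expr <- simulate_expression(gen$truth, config$sim)
  seqs <- simulate_sequences(gen$truth, config$sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- gen$genes
  utils::write.table(
    data.frame(g$chrom, sprintf("%d", as.integer(g$start)),
               sprintf("%d", as.integer(g$end)), g$gene_id, 0, g$strand),
    file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  paths <- list(genes = file.path(dir, "genes.bed"))
  for (mk in names(chip$tracks))
    for (cond in names(chip$tracks[[mk]]))
      for (r in seq_along(chip$tracks[[mk]][[cond]])) {
        tp <- file.path(dir, sprintf("%s_%s_rep%d.bedgraph", mk, cond, r))
        pp <- file.path(dir, sprintf("%s_%s_rep%d_peaks.bed", mk, cond, r))
        write_signal(chip$tracks[[mk]][[cond]][[r]], tp)
        write_intervals(chip$peaks[[mk]][[cond]][[r]], pp)
        paths[[sprintf("%s_track_%s_rep%d", mk, cond, r)]] <- tp
        paths[[sprintf("%s_peaks_%s_rep%d", mk, cond, r)]] <- pp
      }
  # bedGraph value column loses the library size; carry it alongside
  libs <- list()
  for (mk in names(chip$tracks))
    for (cond in names(chip$tracks[[mk]]))
      libs[[sprintf("%s_%s", mk, cond)]] <-
        vapply(chip$tracks[[mk]][[cond]], `[[`, 0, "library_size")
  write_count_matrix(expr, file.path(dir, "counts.tsv"),
                     file.path(dir, "groups.tsv"))
  paths$counts <- file.path(dir, "counts.tsv")
  paths$groups <- file.path(dir, "groups.tsv")
  enh <- gen$truth$enhancers
  fa <- seqs$sequences
  names(fa) <- .fa_names(enh$name, enh$chrom, enh$start, enh$end)
  ss <- Biostrings::DNAStringSet(fa)
  Biostrings::writeXStringSet(ss, file.path(dir, "enhancer_sequences.fa"))
  paths$sequences <- file.path(dir, "enhancer_sequences.fa")
  motifs <- c(list(AP1 = ap1_pwm()),
              decoy_pwms(config$n_decoys, seed = config$seed))
  write_jaspar(motifs, file.path(dir, "motifs_synthetic.jaspar"))
  paths$motifs <- file.path(dir, "motifs_synthetic.jaspar")
  # synthetic TF target lists: three AP-1 family members whose shared
  # targets cover every planted up gene plus member-specific extras
  set.seed(.derive_seed(config$seed, 90))
  up_genes <- gen$truth$genes$gene_id[gen$truth$genes$de_status == "up"]
  all_genes <- gen$truth$genes$gene_id
  tf_paths <- list()
  for (tf in c("BATF", "FOS", "JUNB")) {
    extras <- sample(setdiff(all_genes, up_genes),
                     min(60, length(setdiff(all_genes, up_genes))))
    fp <- file.path(dir, sprintf("targets_%s_synthetic.txt", tf))
    write_gene_set(sort(c(up_genes, extras)), fp)
    tf_paths[[tf]] <- fp
  }
  paths$tf_targets <- tf_paths
  .write_tsv(enh, file.path(dir, "truth_enhancers.tsv"))
  .write_tsv(gen$truth$genes, file.path(dir, "truth_genes.tsv"))
  .write_tsv(seqs$placements, file.path(dir, "truth_motif_placements.tsv"))
  list(paths = paths, truth = gen$truth, libs = libs,
       chrom_sizes = gen$truth$chrom_sizes)
}

#' Run the full pipeline
#'
#' Input (or simulation) -> per-condition enhancer catalogs -> union
#' catalog -> VELs/VSELs -> DEGs -> proximal genes and set logic -> motif
#' enrichment -> QC, writing every stage table plus a manifest to
#' `config$outdir`. Deterministic under a fixed seed: two runs with the
#' same config produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return (Invisibly) a list with all stage results; in simulate mode it
#'   also carries `truth`.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- load_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL; libs <- NULL; chrom_sizes <- NULL
  if (isTRUE(config$simulate)) {
    sim <- .simulate_inputs(config, file.path(outdir, "inputs"))
    paths <- sim$paths; truth <- sim$truth; libs <- sim$libs
    chrom_sizes <- sim$chrom_sizes
    n_reps <- config$sim$n_replicates
  } else {
    paths <- config$paths
    n_reps <- config$paths$n_replicates
    if (is.null(n_reps)) n_reps <- 1
    chrom_sizes <- config$paths$chrom_sizes
  }
  genes <- read_gene_annotation(.need_path(paths, "genes"), "bed6")

  read_cond <- function(mk, cond) {
    pk <- list(); tr <- list()
    for (r in seq_len(n_reps)) {
      pk[[r]] <- read_intervals(
        .need_path(paths, sprintf("%s_peaks_%s_rep%d", mk, cond, r)))
      lib <- if (!is.null(libs)) libs[[sprintf("%s_%s", mk, cond)]][r] else
        NULL
      tr[[r]] <- read_signal(
        .need_path(paths, sprintf("%s_track_%s_rep%d", mk, cond, r)), lib)
    }
    merged <- do.call(rbind, lapply(pk, as.data.frame))
    list(peaks = peak_set(merged$chrom, merged$start, merged$end,
                          source_label = sprintf("%s_%s", mk, cond)),
         track = pool_replicates(tr))
  }
  k27 <- list(normal = read_cond("H3K27ac", "normal"),
              tumor = read_cond("H3K27ac", "tumor"))
  k4 <- list(normal = read_cond("H3K4me1", "normal"),
             tumor = read_cond("H3K4me1", "tumor"))

  catalogs <- list()
  for (cond in c("normal", "tumor")) {
    catalogs[[cond]] <- call_enhancers(
      k27[[cond]]$peaks, k4[[cond]]$peaks, k27[[cond]]$track, genes,
      rules = config$rules, stitch_gap = config$stitch_gap,
      min_overlap_frac = config$min_overlap_frac)
    .write_tsv(catalogs[[cond]]$enhancers,
               file.path(outdir, sprintf("enhancers_%s.tsv", cond)))
    .write_tsv(catalogs[[cond]]$curve,
               file.path(outdir, sprintf("rank_curve_%s.tsv", cond)))
  }
  union_cat <- build_union_catalog(catalogs$normal$enhancers,
                                   catalogs$tumor$enhancers)
  vels <- call_vels(union_cat, k27$tumor$track, k27$normal$track,
                    config$fc_up, config$fc_down, config$rpkm_pseudocount)
  vsels <- call_vsels(union_cat, k27$tumor$track, k27$normal$track,
                      config$fc_up, config$fc_down,
                      config$rpkm_pseudocount)
  vels$proximal_gene <- assign_proximal_gene(vels, genes)
  vsels$proximal_gene <- assign_proximal_gene(vsels, genes)
  .write_tsv(union_cat, file.path(outdir, "union_catalog.tsv"))
  .write_tsv(vels, file.path(outdir, "vels.tsv"))
  .write_tsv(vsels, file.path(outdir, "vsels.tsv"))
  for (st in c("gain", "lost")) {
    sub <- vels[vels$status == st, , drop = FALSE]
    write_intervals(peak_set(sub$chrom, sub$start, sub$end,
                             name = sub$name, score = sub$log2fc),
                    file.path(outdir, sprintf("vels_%s.bed", st)))
  }

  cmx <- read_count_matrix(.need_path(paths, "counts"),
                           .need_path(paths, "groups"))
  degs <- call_degs(cmx, config$lfc_min, config$alpha,
                    config$fpkm_pseudocount)
  .write_tsv(degs, file.path(outdir, "degs.tsv"))

  overlap <- overlap_vel_degs(vels, degs)
  .write_tsv(data.frame(metric = names(overlap$counts),
                        value = as.integer(overlap$counts)),
             file.path(outdir, "vel_deg_overlap.tsv"))

  tf_lists <- lapply(paths$tf_targets, read_gene_set)
  tf_int <- NULL; coord <- NULL; top10 <- NULL
  if (length(tf_lists) >= 2) {
    tf_int <- intersect_tf_targets(tf_lists)
    gain_genes <- unique(stats::na.omit(
      vels$proximal_gene[vels$status == "gain"]))
    up <- degs$gene_id[degs$status == "up"]
    coord <- triple_overlap(tf_int$common, up, gain_genes)
    top10 <- rank_top(degs, intersect(tf_int$common, up), n = 10)
    .write_tsv(data.frame(region = names(tf_int$venn),
                          count = as.integer(tf_int$venn)),
               file.path(outdir, "tf_target_venn.tsv"))
    write_gene_set(coord$genes, file.path(outdir, "coordinated_genes.txt"))
    .write_tsv(top10, file.path(outdir, "top10_tf_degs.tsv"))
  }

  enrichment <- NULL
  if (!is.null(paths$sequences) && !is.null(paths$motifs)) {
    fa <- Biostrings::readDNAStringSet(.need_path(paths, "sequences"))
    coords <- .parse_fa_coords(names(fa))
    gain_loci <- vels[vels$status == "gain", , drop = FALSE]
    hit <- match_loci(coords, gain_loci, frac = 0.5)
    fg <- stats::setNames(as.character(fa)[!is.na(hit)],
                          coords$name[!is.na(hit)])
    if (length(fg) > 0) {
      bg <- make_background(fg, "dinucleotide_shuffle",
                            seed = .derive_seed(config$seed, 80))
      pwms <- read_jaspar(.need_path(paths, "motifs"))
      enrichment <- enrich_motifs(fg, bg, pwms, config$threshold_fraction)
      .write_tsv(enrichment, file.path(outdir, "motif_enrichment.tsv"))
    }
  }

  qc <- NULL
  if (!is.null(chrom_sizes)) {
    binned <- list(
      H3K27ac_normal = bin_track(k27$normal$track, chrom_sizes,
                                 config$bin_size),
      H3K27ac_tumor = bin_track(k27$tumor$track, chrom_sizes,
                                config$bin_size),
      H3K4me1_normal = bin_track(k4$normal$track, chrom_sizes,
                                 config$bin_size),
      H3K4me1_tumor = bin_track(k4$tumor$track, chrom_sizes,
                                config$bin_size))
    nms <- names(binned)
    cmat <- matrix(1, length(nms), length(nms), dimnames = list(nms, nms))
    for (i in seq_along(nms))
      for (j in seq_along(nms))
        if (i < j)
          cmat[i, j] <- cmat[j, i] <-
            correlate_tracks(binned[[i]], binned[[j]])
    meta <- metagene(k27$tumor$peaks, k27$tumor$track,
                     flank = config$flank, bin_size = config$meta_bin)
    qc <- list(correlation = cmat, metagene = meta)
    utils::write.table(
      data.frame(track = rownames(cmat),
                 apply(cmat, 2, function(x) sprintf("%.6f", x))),
      file.path(outdir, "qc_correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    .write_tsv(meta, file.path(outdir, "qc_metagene.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("enhancerscape")),
    seed = config$seed,
    parameters = list(
      stitch_gap = config$stitch_gap, rules = unclass(config$rules),
      min_overlap_frac = config$min_overlap_frac,
      fc_up = config$fc_up, fc_down = config$fc_down,
      rpkm_pseudocount = config$rpkm_pseudocount,
      lfc_min = config$lfc_min, alpha = config$alpha,
      fpkm_pseudocount = config$fpkm_pseudocount,
      threshold_fraction = config$threshold_fraction,
      bin_size = config$bin_size, flank = config$flank,
      meta_bin = config$meta_bin,
      sim = if (isTRUE(config$simulate)) unclass(config$sim) else NULL),
    inputs = {
      flat <- unlist(paths)
      flat <- flat[order(names(flat))]
      as.list(stats::setNames(unname(tools::md5sum(flat)), names(flat)))
    })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(catalogs = catalogs, union_catalog = union_cat,
                 vels = vels, vsels = vsels, degs = degs,
                 overlap = overlap, tf_intersection = tf_int,
                 coordinated = coord, top10 = top10,
                 enrichment = enrichment, qc = qc, genes = genes,
                 truth = truth, outdir = outdir, manifest = manifest))
}

#' Score a simulated run against its planted truth
#'
#' @param result A [run_all()] result from a simulate-mode run.
#' @return Named numeric vector of recovery rates: gain/lost VEL status
#'   recovery, stable specificity, super-enhancer recovery (normal
#'   catalog), typical specificity, gain-VSEL and lost-VSEL recovery, DEG
#'   up/down recovery, and the fraction of wired gain-VEL -> up-DEG pairs
#'   recovered by the intersection stage.
#' @export
score_against_truth <- function(result) {
  truth <- result$truth
  if (is.null(truth)) stop("result carries no truth (not a simulated run)")
  enh <- truth$enhancers
  vels <- result$vels
  m <- match_loci(enh, vels)
  st <- ifelse(is.na(m), "unmatched", vels$status[m])
  rate <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  norm_enh <- result$catalogs$normal$enhancers
  ms <- match_loci(enh, norm_enh)
  super_called <- ifelse(is.na(ms), FALSE, norm_enh$is_super[ms])
  vsels <- result$vsels
  mv <- match_loci(enh, vsels)
  vst <- ifelse(is.na(mv), "unmatched", vsels$status[mv])
  dg <- result$degs
  de <- truth$genes$de_status[match(dg$gene_id, truth$genes$gene_id)]
  wired_up <- enh$gene_id[enh$status == "gain" & !is.na(enh$gene_id)]
  c(gain_vel_recovery = rate(st[enh$status == "gain"] == "gain"),
    lost_vel_recovery = rate(st[enh$status == "lost"] == "lost"),
    stable_specificity = rate(st[enh$status == "stable"] == "stable"),
    super_recovery = rate(super_called[enh$class == "super"]),
    typical_specificity = rate(!super_called[enh$class == "typical"]),
    gain_vsel_recovery = rate(
      vst[enh$class == "super" & enh$status == "gain"] == "gain"),
    lost_vsel_recovery = rate(
      vst[enh$class == "super" & enh$status == "lost"] == "lost"),
    deg_up_recovery = rate(dg$status[de == "up"] == "up"),
    deg_down_recovery = rate(dg$status[de == "down"] == "down"),
    wired_pair_recovery = rate(wired_up %in% result$overlap$gain_up))
}
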