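# Synthetic tumor/normal enhancer-landscape generator. Plants typical and
# super enhancers, gain/lost variant loci wired to up/down genes, ChIP
# coverage tracks with negative-binomial noise, an RNA count matrix and
# enhancer sequences with planted motif instances — with the planted
# labels returned as a truth set against which every downstream stage is
# scored.

.BLOCK <- 30000  # one truth feature per 30 kb block; guarantees stitching
                 # never merges two planted records (inter-record gap
                 # > 12.5 kb) and proximal-gene wiring is unambiguous

.derive_seed <- function(seed, salt) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + as.integer(salt)
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale study: a 2 x 12.5 Mb toy genome, 800
#' genes, ~320 planted enhancer records (200 typical-stable, 50 gain and
#' 50 lost variant enhancer loci, 20 super enhancers of which 6 gain and
#' 6 lost), planted tumor/normal signal ratios of 4 (gain) and 0.25
#' (lost) so the truth clears the 2-fold calling thresholds, three
#' replicates per condition and a planted expression log2 fold change
#' of 2. Background reads dominate the simulated libraries and planted
#' differentially expressed genes are a minority of the transcriptome,
#' as in real libraries, so that per-library depth normalisation (RPKM /
#' FPKM) is not distorted by the planted effects themselves.
#'
#' @param n_chroms,chrom_length Toy genome shape.
#' @param n_genes Genes to annotate (>= number of variant loci, so every
#'   gain/lost enhancer can be wired to a gene).
#' @param n_typical,n_super Stable typical enhancers and super enhancers.
#' @param n_gain_vel,n_lost_vel Planted typical-class variant loci.
#' @param n_gain_vsel,n_lost_vsel How many of the supers are planted as
#'   gain / lost (the rest are stable).
#' @param super_constituent_range Constituent peaks per super enhancer.
#' @param gain_fc,lost_fc Planted tumor/normal signal ratios (> 0).
#' @param background_rate,enrichment_rate Reads per bp outside / inside
#'   enhancers.
#' @param super_boost Extra enrichment multiplier on super-enhancer
#'   constituents (supers carry far higher H3K27ac than typical
#'   enhancers; this keeps the two planted classes separable on the rank
#'   curve even when gained typical loci rise several-fold in tumor).
#' @param n_replicates Replicates per condition (ChIP and RNA).
#' @param rna_depth Nominal reads per RNA sample.
#' @param deg_lfc Planted expression log2 fold change.
#' @param noise_dispersion Negative-binomial dispersion (0 recovers
#'   Poisson).
#' @param plant_fraction Fraction of gain-VEL sequences receiving a
#'   planted motif instance.
#' @param seed Master seed; all generators derive their streams from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 12.5e6, n_genes = 800,
                       n_typical = 200, n_super = 20,
                       n_gain_vel = 50, n_lost_vel = 50,
                       n_gain_vsel = 6, n_lost_vsel = 6,
                       super_constituent_range = c(3, 5),
                       gain_fc = 4, lost_fc = 0.25,
                       background_rate = 0.2, enrichment_rate = 2.0,
                       super_boost = 5,
                       n_replicates = 3, rna_depth = 1e6, deg_lfc = 2,
                       noise_dispersion = 0.05, plant_fraction = 0.8,
                       seed = 1) {
  cfg <- as.list(environment())
  # YAML scalars can arrive as strings ("6.0e6"); coerce every field
  cfg <- lapply(cfg, function(x) if (is.character(x)) as.numeric(x) else x)
  list2env(cfg, environment())
  counts <- c(n_chroms, n_genes, n_typical, n_super, n_gain_vel,
              n_lost_vel, n_gain_vsel, n_lost_vsel, n_replicates)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (gain_fc <= 0 || lost_fc <= 0) stop("fold changes must be > 0")
  if (background_rate < 0 || enrichment_rate < 0) stop("rates must be >= 0")
  if (super_boost <= 0) stop("super_boost must be > 0")
  if (noise_dispersion < 0) stop("dispersion must be >= 0")
  if (plant_fraction < 0 || plant_fraction > 1)
    stop("plant_fraction must be in [0, 1]")
  if (n_gain_vsel + n_lost_vsel > n_super)
    stop("n_gain_vsel + n_lost_vsel cannot exceed n_super")
  stopifnot(length(super_constituent_range) == 2,
            super_constituent_range[1] >= 1,
            super_constituent_range[1] <= super_constituent_range[2])
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the toy genome: gene annotation plus enhancer/gene truth
#'
#' Each planted enhancer record occupies its own 30 kb block, with its
#' partner gene's TSS >= 3 kb from every enhancer boundary (so planted
#' enhancers survive the distal filter by construction), super-enhancer
#' constituents spaced < 12.5 kb apart, and > 12.5 kb between records (so
#' stitching never merges two truth records). Gain/lost enhancers are
#' wired to genes planted up/down.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (a [gene_annotation()]) and `truth`, a list
#'   of class `truth_set`: `enhancers` (name, interval, class, status,
#'   gene_id, n_constituents), `constituents`, `genes` (gene_id,
#'   de_status, length) and `chrom_sizes`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(.derive_seed(config$seed, 1))
  rec <- data.frame(
    class = c(rep("typical", config$n_typical + config$n_gain_vel +
                    config$n_lost_vel),
              rep("super", config$n_super)),
    status = c(rep("stable", config$n_typical),
               rep("gain", config$n_gain_vel),
               rep("lost", config$n_lost_vel),
               rep("gain", config$n_gain_vsel),
               rep("lost", config$n_lost_vsel),
               rep("stable", config$n_super - config$n_gain_vsel -
                     config$n_lost_vsel)),
    stringsAsFactors = FALSE)
  n_rec <- nrow(rec)
  n_var <- sum(rec$status != "stable")
  if (config$n_genes < n_var)
    stop("n_genes must cover every gain/lost enhancer record")
  bpc <- floor(config$chrom_length / .BLOCK)
  capacity <- config$n_chroms * bpc
  blocks_needed <- n_rec + max(0, config$n_genes - n_rec)
  if (blocks_needed > capacity)
    stop(sprintf(paste("genome too small: %d feature blocks needed but",
                       "only %d fit; increase chrom_length"),
                 blocks_needed, capacity))
  rec <- rec[sample.int(n_rec), , drop = FALSE]
  block_id <- seq_len(blocks_needed)
  chroms <- sprintf("chr%d", (block_id - 1) %/% bpc + 1)
  b0 <- ((block_id - 1) %% bpc) * .BLOCK

  # genes: variant-record blocks first, then stable-record blocks, then
  # enhancer-free blocks
  gene_order <- c(which(rec$status != "stable"),
                  which(rec$status == "stable"),
                  setdiff(block_id, seq_len(n_rec)))
  gene_blocks <- sort(gene_order[seq_len(config$n_genes)])
  gene_len <- sample(600:3000, config$n_genes, replace = TRUE)
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gtss <- b0[gene_blocks] + 3200
  gstart <- ifelse(gene_strand == "+", gtss, gtss + 1 - gene_len)
  gend <- ifelse(gene_strand == "+", gtss + gene_len, gtss + 1)
  gene_id <- sprintf("gene_%04d", gene_blocks)
  genes <- gene_annotation(gene_id, chroms[gene_blocks], gstart, gend,
                           gene_strand)
  block_gene <- stats::setNames(rep(NA_character_, blocks_needed),
                                block_id)
  block_gene[as.character(gene_blocks)] <- gene_id

  cons <- vector("list", n_rec)
  enh <- data.frame(name = sprintf("truth_%04d", seq_len(n_rec)),
                    chrom = chroms[seq_len(n_rec)], start = 0, end = 0,
                    class = rec$class, status = rec$status,
                    gene_id = block_gene[as.character(seq_len(n_rec))],
                    n_constituents = 1L, stringsAsFactors = FALSE)
  for (i in seq_len(n_rec)) {
    base <- b0[i] + 8000 + sample(0:1000, 1)
    if (rec$class[i] == "super") {
      k <- sample(config$super_constituent_range[1]:
                    config$super_constituent_range[2], 1)
      widths <- sample(800:1200, k, replace = TRUE)
      gaps <- if (k > 1) sample(1000:2200, k - 1, replace = TRUE) else
        integer(0)
      starts <- base + cumsum(c(0, widths[-k] + gaps))
      ends <- starts + widths
    } else {
      w <- sample(800:1600, 1)
      starts <- base; ends <- base + w
    }
    cons[[i]] <- data.frame(name = enh$name[i], chrom = enh$chrom[i],
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
    enh$start[i] <- min(starts); enh$end[i] <- max(ends)
    enh$n_constituents[i] <- length(starts)
  }
  truth_genes <- data.frame(
    gene_id = genes$gene_id,
    length = genes$end - genes$start,
    de_status = "null", stringsAsFactors = FALSE)
  wired <- enh[enh$status != "stable" & !is.na(enh$gene_id), ]
  truth_genes$de_status[match(wired$gene_id[wired$status == "gain"],
                              truth_genes$gene_id)] <- "up"
  truth_genes$de_status[match(wired$gene_id[wired$status == "lost"],
                              truth_genes$gene_id)] <- "down"
  o <- .sort_order(enh$chrom, enh$start, enh$end)
  enh <- enh[o, , drop = FALSE]; cons <- cons[o]
  rownames(enh) <- NULL
  truth <- structure(
    list(enhancers = enh,
         constituents = do.call(rbind, cons),
         genes = truth_genes,
         chrom_sizes = stats::setNames(
           rep(config$chrom_length, config$n_chroms),
           sprintf("chr%d", seq_len(config$n_chroms)))),
    class = "truth_set")
  list(genes = genes, truth = truth)
}

# mean signal rate (reads/bp) for a constituent in one condition
.cond_rate <- function(status, condition, config) {
  mult <- if (condition == "tumor")
    ifelse(status == "gain", config$gain_fc,
           ifelse(status == "lost", config$lost_fc, 1))
  else rep(1, length(status))
  config$enrichment_rate * mult
}

#' Simulate ChIP coverage tracks and peak sets
#'
#' Reads per bin are drawn from a negative binomial with mean
#' `background_rate` outside enhancers and `enrichment_rate` times the
#' status multiplier inside (tumor mean = `gain_fc` / `lost_fc` times
#' normal for gain / lost loci; H3K4me1 enrichment is constant across
#' conditions, marking active enhancers in both). The per-track peak set contains the
#' constituent intervals whose realised coverage exceeds 5 x background —
#' emulating an upstream peak caller without implementing one.
#'
#' @param truth A `truth_set` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List of class `chip_sim`: `tracks[[mark]][[condition]]` (list of
#'   per-replicate [signal_track()]s) and `peaks[[mark]][[condition]]`
#'   (per-replicate [peak_set()]s).
#' @export
simulate_chip_tracks <- function(truth, config = sim_config()) {
  cons <- truth$constituents
  rec_idx <- match(cons$name, truth$enhancers$name)
  status <- truth$enhancers$status[rec_idx]
  boost <- ifelse(truth$enhancers$class[rec_idx] == "super",
                  config$super_boost, 1)
  size <- if (config$noise_dispersion > 0) 1 / config$noise_dispersion else
    Inf
  draw <- function(mu) {
    if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), mu)
  }
  bg_bin <- 5000
  marks <- c(H3K27ac = 1.0, H3K4me1 = 1.0)
  tracks <- peaks <- list()
  salt <- 10L
  for (mk in names(marks)) {
    for (cond in c("normal", "tumor")) {
      tr_list <- pk_list <- list()
      rate <- .cond_rate(status, cond, config) * boost * marks[[mk]]
      if (mk == "H3K4me1")  # active mark present in both conditions
        rate <- rep(config$enrichment_rate * marks[[mk]], length(status))
      for (r in seq_len(config$n_replicates)) {
        set.seed(.derive_seed(config$seed, salt))
        salt <- salt + 1L
        runs <- list()
        for (ch in names(truth$chrom_sizes)) {
          ci <- which(cons$chrom == ch)
          cs <- cons$start[ci]; ce <- cons$end[ci]
          # background chunks between enhancer constituents
          bnd <- c(0, as.vector(rbind(cs, ce)), truth$chrom_sizes[[ch]])
          gap_s <- bnd[seq(1, length(bnd) - 1, by = 2)]
          gap_e <- bnd[seq(2, length(bnd), by = 2)]
          keep <- gap_e > gap_s
          gap_s <- gap_s[keep]; gap_e <- gap_e[keep]
          # split long gaps into <= bg_bin chunks
          nchunk <- pmax(1, ceiling((gap_e - gap_s) / bg_bin))
          bs <- unlist(mapply(function(s, e, k)
            floor(seq(s, e, length.out = k + 1))[-(k + 1)],
            gap_s, gap_e, nchunk, SIMPLIFY = FALSE))
          be <- unlist(mapply(function(s, e, k)
            floor(seq(s, e, length.out = k + 1))[-1],
            gap_s, gap_e, nchunk, SIMPLIFY = FALSE))
          bw <- be - bs
          bg_reads <- draw(config$background_rate * bw)
          enh_reads <- draw(rate[ci] * (ce - cs))
          runs[[ch]] <- data.frame(
            chrom = ch,
            start = c(bs, cs), end = c(be, ce),
            value = c(bg_reads / bw, enh_reads / (ce - cs)),
            reads = c(bg_reads, enh_reads),
            enh = c(rep(NA_integer_, length(bs)), ci),
            stringsAsFactors = FALSE)
        }
        all_runs <- do.call(rbind, runs)
        tr <- signal_track(all_runs[c("chrom", "start", "end", "value")],
                           library_size = sum(all_runs$reads))
        is_enh <- !is.na(all_runs$enh)
        called <- is_enh &
          all_runs$value > 5 * config$background_rate
        pk_list[[r]] <- peak_set(all_runs$chrom[called],
                                 all_runs$start[called],
                                 all_runs$end[called],
                                 name = cons$name[all_runs$enh[called]],
                                 source_label = sprintf("%s_%s_rep%d",
                                                        mk, cond, r))
        tr_list[[r]] <- tr
      }
      tracks[[mk]][[cond]] <- tr_list
      peaks[[mk]][[cond]] <- pk_list
    }
  }
  structure(list(tracks = tracks, peaks = peaks), class = "chip_sim")
}

#' Simulate the RNA count matrix
#'
#' Per-gene baseline abundances are log-normal; counts are negative
#' binomial with tumor means scaled by `2^deg_lfc` for planted up genes
#' and `2^-deg_lfc` for down genes.
#'
#' @param truth A `truth_set` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A [count_matrix()] with `n_replicates` samples per condition.
#' @export
simulate_expression <- function(truth, config = sim_config()) {
  set.seed(.derive_seed(config$seed, 50))
  g <- truth$genes
  n <- nrow(g)
  if (n == 0) stop("truth set has no genes")
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  p_base <- w / sum(w)
  mult <- ifelse(g$de_status == "up", 2^config$deg_lfc,
                 ifelse(g$de_status == "down", 2^-config$deg_lfc, 1))
  size <- if (config$noise_dispersion > 0) 1 / config$noise_dispersion else
    Inf
  samples <- c(sprintf("normal_%d", seq_len(config$n_replicates)),
               sprintf("tumor_%d", seq_len(config$n_replicates)))
  groups <- stats::setNames(rep(c("normal", "tumor"),
                                each = config$n_replicates), samples)
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(g$gene_id, samples))
  for (s in samples) {
    mu <- config$rna_depth * p_base *
      (if (groups[[s]] == "tumor") mult else 1)
    counts[, s] <- if (is.finite(size))
      stats::rnbinom(n, mu = mu, size = size) else stats::rpois(n, mu)
  }
  count_matrix(counts, groups,
               stats::setNames(g$length, g$gene_id))
}

#' Simulate enhancer sequences with planted motif instances
#'
#' One random ACGT sequence per truth enhancer (named by the truth
#' record). A `plant_fraction` of the gain-status enhancers receive one
#' exact instance of the motif consensus (default TGACTCA, the
#' TPA-response element bound by AP-1) at a random offset on a random
#' strand; all placements are reported.
#'
#' @param truth A `truth_set` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @param motif Consensus string to plant.
#' @return List of class `seq_sim`: `sequences` (named character vector)
#'   and `placements` (name, offset 0-based, strand).
#' @export
simulate_sequences <- function(truth, config = sim_config(),
                               motif = "TGACTCA") {
  set.seed(.derive_seed(config$seed, 60))
  enh <- truth$enhancers
  m <- nchar(motif)
  widths <- enh$end - enh$start
  if (any(widths < m)) stop("enhancer shorter than the motif")
  seqs <- vapply(widths, function(w)
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- enh$name
  gain <- which(enh$status == "gain")
  n_plant <- round(config$plant_fraction * length(gain))
  planted <- if (n_plant > 0) sort(sample(gain, n_plant)) else integer(0)
  placements <- data.frame(name = character(), offset = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  for (i in planted) {
    off <- sample.int(widths[i] - m + 1, 1) - 1  # 0-based
    strand <- sample(c("+", "-"), 1)
    inst <- if (strand == "+") motif else .revcomp(motif)
    substr(seqs[i], off + 1, off + m) <- inst
    placements <- rbind(placements,
                        data.frame(name = enh$name[i], offset = off,
                                   strand = strand,
                                   stringsAsFactors = FALSE))
  }
  structure(list(sequences = seqs, placements = placements,
                 motif = motif),
            class = "seq_sim")
}

#' Deterministic decoy PWMs for motif-ranking experiments
#'
#' Random sharp motifs of the given length whose consensus differs from
#' `avoid` (and its reverse complement), for use as competitors when
#' checking that a planted motif ranks first.
#'
#' @param n How many decoys.
#' @param length Motif length (default 7).
#' @param seed Seed.
#' @param avoid Consensus string decoys must not replicate.
#' @return List of [pwm()]s named decoy_1..n.
#' @export
decoy_pwms <- function(n = 10, length = 7, seed = 1, avoid = "TGACTCA") {
  set.seed(.derive_seed(seed, 70))
  out <- list()
  banned <- c(avoid, .revcomp(avoid))
  while (length(out) < n) {
    cons <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
    if (cons %in% banned) next
    id <- sprintf("decoy_%d", length(out) + 1)
    out[[id]] <- consensus_pwm(cons, id, id)
  }
  out
}
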