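#' Simulation configuration for synthetic promoter tiling-array data
#'
#' Builds and validates the configuration object consumed by the generator
#' functions ([generate_genome()], [assign_truth()],
#' [generate_probe_arrays()], [generate_expression()]). Defaults emulate a
#' NimbleGen-style promoter design: probes tiled every 100 bp from 5 kb
#' upstream to 1.5 kb downstream of each TSS, near-Gaussian background log2
#' ratios, rectangular enrichment plateaus over truly bound promoters,
#' 3 biological replicates and 3 time points (0, 1, 6 h), paired with an
#' expression table at 0, 4 and 12 h in RPKM.
#'
#' @param n_genes number of genes to simulate.
#' @param n_chromosomes number of chromosomes genes are distributed over
#'   (round-robin).
#' @param probe_spacing_bp distance between adjacent probe centres, bp.
#' @param tile_window integer pair: tiled extent relative to the TSS in
#'   transcription direction, bp (start < 0 < end).
#' @param noise_sd standard deviation of the Gaussian background log2 ratio.
#' @param enrichment_amplitude log2-ratio offset added over bound regions.
#' @param enrichment_width_bp width of the rectangular enrichment plateau.
#' @param enrichment_center_offset_bp offset of the plateau centre from the
#'   TSS (in transcription direction; negative = upstream). Either a single
#'   value or one value per time point. The preset
#'   [figure1_shift_offsets()] moves 1 h centres closer to the TSS.
#' @param n_replicates biological replicates per time point.
#' @param time_labels ordered ChIP time-point labels.
#' @param replicate_penetrance probability that a truly bound gene shows
#'   enrichment on a given replicate array.
#' @param pattern_proportions named numeric vector of weights for pattern
#'   codes `0:(2^T - 1)`; must sum to 1.
#' @param expression_baseline_log_mean,expression_baseline_log_sd meanlog and
#'   sdlog of the log-normal baseline RPKM distribution.
#' @param de_log2fc_range positive pair: range of |log2 fold change| drawn
#'   for differentially expressed genes.
#' @param p_de_given_bound,p_de_given_unbound probability that a gene is
#'   differentially expressed at a follow-up time given that it is (is not)
#'   bound at the matched earlier binding time.
#' @param expression_time_labels ordered expression time labels; the first is
#'   the baseline.
#' @param time_map named character vector mapping each non-baseline binding
#'   time to its follow-up expression time.
#' @param chrom_length_bp available length per chromosome; generation fails
#'   if the genes do not fit.
#' @param transcript_length_range integer pair: uniform range of transcript
#'   lengths.
#' @param gene_gap_bp extra spacing inserted between consecutive gene
#'   footprints.
#' @param seed integer seed; mandatory. All generator stages derive their
#'   random streams from it.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       n_chromosomes = 2,
                       probe_spacing_bp = 100,
                       tile_window = c(-5000L, 1500L),
                       noise_sd = 0.3,
                       enrichment_amplitude = 2.0,
                       enrichment_width_bp = 600,
                       enrichment_center_offset_bp = 0,
                       n_replicates = 3,
                       time_labels = c("0h", "1h", "6h"),
                       replicate_penetrance = 1.0,
                       pattern_proportions = NULL,
                       expression_baseline_log_mean = 3,
                       expression_baseline_log_sd = 1,
                       expression_pseudocount = 0.1,
                       de_fc_threshold = 2,
                       de_log2fc_range = c(1.0, 3.0),
                       p_de_given_bound = 0.6,
                       p_de_given_unbound = 0.05,
                       expression_time_labels = c("0h", "4h", "12h"),
                       time_map = c("1h" = "4h", "6h" = "12h"),
                       chrom_length_bp = 25e6,
                       transcript_length_range = c(2000L, 10000L),
                       gene_gap_bp = 2000,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory in sim_config()")
  n_times <- length(time_labels)
  n_codes <- 2L^n_times
  if (is.null(pattern_proportions)) {
    pattern_proportions <- c(0.30, rep(0.70 / (n_codes - 1), n_codes - 1))
    names(pattern_proportions) <- as.character(0:(n_codes - 1))
  }
  if (is.null(names(pattern_proportions)))
    names(pattern_proportions) <- as.character(0:(n_codes - 1))
  if (length(enrichment_center_offset_bp) == 1L)
    enrichment_center_offset_bp <- rep(enrichment_center_offset_bp, n_times)
  names(enrichment_center_offset_bp) <- time_labels

  cfg <- list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    probe_spacing_bp = as.integer(probe_spacing_bp),
    tile_window = as.integer(tile_window), noise_sd = noise_sd,
    enrichment_amplitude = enrichment_amplitude,
    enrichment_width_bp = as.integer(enrichment_width_bp),
    enrichment_center_offset_bp = enrichment_center_offset_bp,
    n_replicates = as.integer(n_replicates), time_labels = time_labels,
    replicate_penetrance = replicate_penetrance,
    pattern_proportions = pattern_proportions,
    expression_baseline_log_mean = expression_baseline_log_mean,
    expression_baseline_log_sd = expression_baseline_log_sd,
    expression_pseudocount = expression_pseudocount,
    de_fc_threshold = de_fc_threshold,
    de_log2fc_range = de_log2fc_range,
    p_de_given_bound = p_de_given_bound,
    p_de_given_unbound = p_de_given_unbound,
    expression_time_labels = expression_time_labels,
    time_map = time_map,
    chrom_length_bp = chrom_length_bp,
    transcript_length_range = as.integer(transcript_length_range),
    gene_gap_bp = as.integer(gene_gap_bp),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_chromosomes >= 1L,
            cfg$probe_spacing_bp >= 1L, cfg$noise_sd >= 0,
            cfg$enrichment_width_bp >= 1L, cfg$n_replicates >= 1L)
  if (!(cfg$tile_window[1] < 0 && 0 < cfg$tile_window[2]))
    stop("tile_window must satisfy start < 0 < end")
  if (cfg$probe_spacing_bp >= cfg$enrichment_width_bp)
    stop("probe_spacing_bp must be smaller than enrichment_width_bp")
  probs <- c(cfg$replicate_penetrance, cfg$p_de_given_bound,
             cfg$p_de_given_unbound)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  n_codes <- 2L^length(cfg$time_labels)
  pp <- cfg$pattern_proportions
  if (length(pp) != n_codes)
    stop("pattern_proportions must have one weight per pattern code 0..",
         n_codes - 1L)
  if (abs(sum(pp) - 1) > 1e-9) stop("pattern_proportions must sum to 1")
  if (any(pp < 0)) stop("pattern_proportions must be nonnegative")
  if (any(cfg$de_log2fc_range <= 0) || diff(cfg$de_log2fc_range) < 0)
    stop("de_log2fc_range must be an increasing pair of positive reals")
  tm <- cfg$time_map
  if (anyDuplicated(tm)) stop("time_map must be injective")
  non_base <- setdiff(cfg$time_labels, cfg$time_labels[1])
  if (!all(non_base %in% names(tm)))
    stop("every non-baseline binding time must be mapped in time_map")
  invisible(cfg)
}

#' Enrichment-centre offsets emulating a 1 h shift toward the TSS
#'
#' Preset time-dependent plateau offsets: binding at the intermediate time
#' point sits close to the TSS while flanking time points bind further
#' upstream. Pass the result as `enrichment_center_offset_bp`.
#'
#' @param time_labels ordered time labels (length 3).
#' @param far,near upstream offsets (bp, negative) for the flanking and the
#'   middle time point.
#' @return named numeric vector of offsets per time point.
#' @export
figure1_shift_offsets <- function(time_labels = c("0h", "1h", "6h"),
                                  far = -1500, near = -250) {
  stopifnot(length(time_labels) == 3L)
  stats::setNames(c(far, near, far), time_labels)
}

#' Generate a synthetic gene annotation table
#'
#' Places `n_genes` genes round-robin across chromosomes so that tiled
#' promoter windows and gene regions (5 kb upstream of the TSS to 1.5 kb
#' past the transcript end) are pairwise disjoint. Strands are assigned
#' ~50/50. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()] object.
#' @return data.frame with columns `gene_id`, `refseq_id`, `chrom`, `strand`,
#'   `tss`, `transcript_end` (1-based coordinates).
#' @export
generate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  tl <- cfg$transcript_length_range
  len <- if (tl[1] == tl[2]) rep(tl[1], n) else
    sample(seq(tl[1], tl[2]), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_i <- ((seq_len(n) - 1L) %% cfg$n_chromosomes) + 1L
  chrom <- paste0("chr", chrom_i)
  pad_up <- max(5000L, abs(cfg$tile_window)) + cfg$enrichment_width_bp
  pad_dn <- pad_up + 1500L
  tss <- integer(n); tend <- integer(n)
  for (ci in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom_i == ci)
    cursor <- 10000L
    for (i in idx) {
      a <- cursor + pad_up                     # transcript start coordinate
      b <- a + len[i] - 1L
      if (strand[i] == "+") { tss[i] <- a; tend[i] <- b }
      else                  { tss[i] <- b; tend[i] <- a }
      cursor <- b + pad_dn + cfg$gene_gap_bp
      if (cursor > cfg$chrom_length_bp)
        stop("cannot place ", length(idx), " genes on a chromosome of ",
             cfg$chrom_length_bp, " bp; increase chrom_length_bp or ",
             "n_chromosomes")
    }
  }
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    refseq_id = sprintf("NM_%06d", 100000L + seq_len(n)),
    chrom = chrom, strand = strand, tss = tss, transcript_end = tend,
    stringsAsFactors = FALSE)
}

pattern_bits <- function(code, n_times) {
  # MSB-first: earliest time point is the most significant bit
  vapply(seq_len(n_times),
         function(k) bitwAnd(bitwShiftR(code, n_times - k), 1L),
         integer(1))
}

#' Assign ground-truth binding patterns, enrichment indicators and DE status
#'
#' Draws one pattern code per gene from `pattern_proportions`, expands it to
#' per-(replicate, time) enrichment indicators thinned by
#' `replicate_penetrance`, and draws differential-expression status per
#' follow-up time with probability `p_de_given_bound` /
#' `p_de_given_unbound` according to the gene's pattern bit at the matched
#' binding time. Enrichment indicators are false wherever the pattern bit
#' is 0.
#'
#' @param cfg a [sim_config()] object.
#' @param genes gene table from [generate_genome()].
#' @return list with elements `truth` (data.frame: `gene_id`,
#'   `true_pattern`, `true_log2fc`, one logical `de_<time>` column per
#'   follow-up time) and `enrich` (data.frame: `gene_id`, `replicate`,
#'   `time_label`, `enriched`).
#' @export
assign_truth <- function(cfg, genes) {
  set.seed(cfg$seed + 1L)
  n <- nrow(genes)
  n_times <- length(cfg$time_labels)
  codes <- sample(0:(2L^n_times - 1L), n, replace = TRUE,
                  prob = cfg$pattern_proportions)
  bits <- matrix(vapply(codes, pattern_bits, integer(n_times),
                        n_times = n_times), nrow = n_times)
  bits <- t(bits)
  colnames(bits) <- cfg$time_labels

  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      time_label = cfg$time_labels,
                      stringsAsFactors = FALSE)
  enrich <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    t <- grid$time_label[k]
    on <- bits[, t] == 1L &
      stats::rbinom(n, 1L, cfg$replicate_penetrance) == 1L
    data.frame(gene_id = genes$gene_id, replicate = grid$replicate[k],
               time_label = t, enriched = on, stringsAsFactors = FALSE)
  }))

  sign <- sample(c(-1, 1), n, replace = TRUE)
  mag <- stats::runif(n, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
  truth <- data.frame(gene_id = genes$gene_id, true_pattern = codes,
                      stringsAsFactors = FALSE)
  for (bt in intersect(names(cfg$time_map), cfg$time_labels)) {
    et <- cfg$time_map[[bt]]
    bound <- bits[, bt] == 1L
    p <- ifelse(bound, cfg$p_de_given_bound, cfg$p_de_given_unbound)
    truth[[paste0("de_", et)]] <- stats::rbinom(n, 1L, p) == 1L
  }

  # Baseline expression, and DE effect sizes conditioned on detectability:
  # a gene whose truth says "differentially expressed" must clear the
  # pseudocounted fold-change rule the analysis applies, otherwise the
  # truth table would promise the unrecoverable. The magnitude is redrawn
  # from de_log2fc_range until the measured fold change passes; for
  # low-expressed genes this conditions the effect-size distribution
  # slightly away from the lower bound.
  base <- stats::rlnorm(n, cfg$expression_baseline_log_mean,
                        cfg$expression_baseline_log_sd)
  c0 <- cfg$expression_pseudocount
  thr <- log2(cfg$de_fc_threshold)
  measured <- function(r, s, f)
    abs(log2((r * 2^(s * f) + c0) / (r + c0)))
  de_cols <- grep("^de_", names(truth), value = TRUE)
  any_de <- if (length(de_cols)) Reduce(`|`, truth[de_cols]) else
    rep(FALSE, n)
  need <- which(any_de & measured(base, sign, mag) < thr)
  tries <- 0L
  while (length(need) > 0 && tries < 100L) {
    mag[need] <- stats::runif(length(need), cfg$de_log2fc_range[1],
                              cfg$de_log2fc_range[2])
    need <- need[measured(base[need], sign[need], mag[need]) < thr]
    tries <- tries + 1L
  }
  if (length(need) > 0) {  # deeply down-regulated call undetectable at this
    sign[need] <- 1        # baseline: fall back to maximal up-regulation
    mag[need] <- cfg$de_log2fc_range[2]
  }
  truth$true_log2fc <- sign * mag
  truth$baseline_rpkm <- base
  truth <- truth[c("gene_id", "true_pattern", "true_log2fc",
                   "baseline_rpkm", de_cols)]
  list(truth = truth, enrich = enrich)
}

probe_template <- function(cfg, genes) {
  offs <- seq(cfg$tile_window[1], cfg$tile_window[2],
              by = cfg$probe_spacing_bp)
  n_off <- length(offs)
  sgn <- ifelse(genes$strand == "+", 1L, -1L)
  pos <- rep(genes$tss, each = n_off) + rep(sgn, each = n_off) * offs
  tpl <- data.frame(
    gene_id = rep(genes$gene_id, each = n_off),
    chrom = rep(genes$chrom, each = n_off),
    position = pos,
    offset = rep(offs, nrow(genes)),
    stringsAsFactors = FALSE)
  tpl <- tpl[order(tpl$chrom, tpl$position), ]
  tpl$probe_id <- sprintf("PR_%s_%09d", tpl$chrom, tpl$position)
  rownames(tpl) <- NULL
  tpl
}

#' Generate per-array probe signal tables
#'
#' One table per (replicate, time point). Every probe carries i.i.d.
#' Gaussian background noise; probes within `enrichment_width_bp / 2` of the
#' (possibly time-shifted) enrichment centre of a gene whose truth indicator
#' is on for that array receive `+enrichment_amplitude`. Probe coordinates
#' are identical across arrays.
#'
#' @param cfg a [sim_config()] object.
#' @param genes gene table from [generate_genome()].
#' @param truth result of [assign_truth()].
#' @return named list (`"r<rep>_<time>"`) of probe data.frames with columns
#'   `probe_id`, `chrom`, `position`, `log2_ratio`, `replicate`,
#'   `time_label`.
#' @export
generate_probe_arrays <- function(cfg, genes, truth) {
  set.seed(cfg$seed + 2L)
  tpl <- probe_template(cfg, genes)
  half <- cfg$enrichment_width_bp / 2
  gidx <- match(tpl$gene_id, genes$gene_id)
  sgn <- ifelse(genes$strand[gidx] == "+", 1L, -1L)
  out <- list()
  for (r in seq_len(cfg$n_replicates)) {
    for (t in cfg$time_labels) {
      centre <- genes$tss[gidx] + sgn * cfg$enrichment_center_offset_bp[[t]]
      on_gene <- truth$enrich$gene_id[truth$enrich$replicate == r &
                                      truth$enrich$time_label == t &
                                      truth$enrich$enriched]
      hit <- tpl$gene_id %in% on_gene & abs(tpl$position - centre) <= half
      val <- stats::rnorm(nrow(tpl), 0, cfg$noise_sd) +
        cfg$enrichment_amplitude * hit
      out[[paste0("r", r, "_", t)]] <- data.frame(
        probe_id = tpl$probe_id, chrom = tpl$chrom,
        position = tpl$position, log2_ratio = val,
        replicate = r, time_label = t, stringsAsFactors = FALSE)
    }
  }
  out
}

#' Generate a synthetic expression table in RPKM
#'
#' Baseline RPKM is log-normal (drawn in [assign_truth()] so that DE effect
#' sizes can be conditioned on detectability); at each follow-up time, genes
#' flagged differentially expressed in the ground truth have their baseline
#' RPKM multiplied by `2^true_log2fc`, all other genes keep their baseline
#' value exactly (the downstream analysis consumes already-normalized
#' averages, so no count-level noise is added). This stage is fully
#' deterministic given the truth table.
#'
#' @param cfg a [sim_config()] object.
#' @param genes gene table from [generate_genome()].
#' @param truth result of [assign_truth()].
#' @return data.frame with `gene_id`, `refseq_id` and one `rpkm_<time>`
#'   column per expression time label.
#' @export
generate_expression <- function(cfg, genes, truth) {
  tt <- truth$truth[match(genes$gene_id, truth$truth$gene_id), ]
  base <- tt$baseline_rpkm
  out <- data.frame(gene_id = genes$gene_id, refseq_id = genes$refseq_id,
                    stringsAsFactors = FALSE)
  out[[paste0("rpkm_", cfg$expression_time_labels[1])]] <- base
  for (et in setdiff(cfg$expression_time_labels,
                     cfg$expression_time_labels[1])) {
    de <- tt[[paste0("de_", et)]]
    if (is.null(de))
      stop("no ground-truth DE status for expression time ", et,
           "; check that time_map covers the binding time course")
    out[[paste0("rpkm_", et)]] <- base * ifelse(de, 2^tt$true_log2fc, 1)
  }
  out
}
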