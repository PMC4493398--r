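#' Default end-to-end pipeline configuration
#'
#' Nested configuration with one section per stage; every analysis threshold
#' (FDR 0.05, 2-of-3 replicate consensus, 500 bp window, 4 probes, cutoff
#' scan 0.90 down to 0.15, 20 permutations, 5000 bp TSS cutoff, gene region
#' -5000/+1500, 2-fold expression change) is a named key. Serializable to
#' YAML via [write_pipeline_config()].
#'
#' @param seed integer master seed; every random stage derives its stream
#'   from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed) {
  if (missing(seed)) stop("'seed' is required")
  list(
    seed = as.integer(seed),
    simulate = list(
      n_genes = 200L, n_chromosomes = 2L, probe_spacing_bp = 100L,
      tile_window = c(-5000L, 1500L), noise_sd = 0.3,
      enrichment_amplitude = 2.0, enrichment_width_bp = 600L,
      enrichment_center_offset_bp = 0, n_replicates = 3L,
      time_labels = c("0h", "1h", "6h"), replicate_penetrance = 1.0,
      p_de_given_bound = 0.6, p_de_given_unbound = 0.05),
    peaks = list(window_bp = 500L, min_probes = 4L,
                 cutoff_hi = 0.90, cutoff_lo = 0.15, cutoff_step = 0.05,
                 n_permutations = 20L, fdr_threshold = 0.05,
                 sd_multiplier = 6.0, per_chromosome_shuffle = FALSE),
    annotate = list(tss_cutoff_bp = 5000L, upstream_bp = 5000L,
                    downstream_bp = 1500L),
    patterns = list(fdr_threshold = 0.05, consensus_min = 2L),
    integrate = list(pseudocount = 0.1, fc_threshold = 2,
                     baseline = "0h",
                     time_map = c("1h" = "4h", "6h" = "12h")),
    enrich = list(gmt = NULL, p_cutoff = 0.05),
    inputs = list(genes = NULL, probe_dir = NULL, expression = NULL,
                  peaks_dir = NULL))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return configuration list merged over [default_config()].
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config must contain a 'seed' key")
  cfg <- default_config(user$seed)
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      for (key in names(user[[section]]))
        cfg[[section]][[key]] <- user[[section]][[key]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  tm <- cfg$integrate$time_map
  if (!is.null(tm)) cfg$integrate$time_map <- unlist(tm)
  cfg
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  config$integrate$time_map <- as.list(config$integrate$time_map)
  yaml::write_yaml(config, path)
  invisible(path)
}

peak_params_from_config <- function(pc) {
  peak_params(window_bp = pc$window_bp, min_probes = pc$min_probes,
              cutoff_fractions = seq(pc$cutoff_hi, pc$cutoff_lo,
                                     by = -pc$cutoff_step),
              n_permutations = pc$n_permutations,
              fdr_threshold = pc$fdr_threshold,
              sd_multiplier = pc$sd_multiplier,
              per_chromosome_shuffle = pc$per_chromosome_shuffle)
}

sim_config_from_pipeline <- function(config) {
  sc <- config$simulate
  sim_config(
    n_genes = sc$n_genes, n_chromosomes = sc$n_chromosomes,
    probe_spacing_bp = sc$probe_spacing_bp, tile_window = sc$tile_window,
    noise_sd = sc$noise_sd, enrichment_amplitude = sc$enrichment_amplitude,
    enrichment_width_bp = sc$enrichment_width_bp,
    enrichment_center_offset_bp = sc$enrichment_center_offset_bp,
    n_replicates = sc$n_replicates, time_labels = sc$time_labels,
    replicate_penetrance = sc$replicate_penetrance,
    p_de_given_bound = sc$p_de_given_bound,
    p_de_given_unbound = sc$p_de_given_unbound,
    expression_pseudocount = config$integrate$pseudocount,
    de_fc_threshold = config$integrate$fc_threshold,
    time_map = config$integrate$time_map,
    expression_time_labels = c(config$integrate$baseline,
                               unname(config$integrate$time_map)),
    seed = config$seed)
}

log_info <- function(...) message("[switchscan] ", ...)

#' Run the full pipeline: simulate, call peaks, annotate, patterns,
#' integrate, enrich
#'
#' Stages run in dependency order; any stage whose inputs are supplied
#' externally through `config$inputs` is skipped (real-data mode):
#' `genes` (gene table TSV), `probe_dir` (per-array probe TSVs named
#' `array_r<rep>_<time>.tsv`), `expression` (RPKM TSV), `peaks_dir`
#' (per-array BED files named `peaks_r<rep>_<time>.bed`, skips peak
#' calling). All outputs are written under `outdir` together with a
#' reproducibility manifest (config snapshot, seeds, per-file MD5 digests,
#' stage timings, versions). A stage failure halts the run with the failing
#' stage named; outputs of completed stages are retained.
#'
#' @param config configuration list ([default_config()]) or path to a YAML
#'   file ([read_pipeline_config()]).
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config, outdir = tempfile("switchscan_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("switchscan")),
                   r_version = R.version.string,
                   stages = list(), files = list())
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  out_path <- function(...) file.path(outdir, paste0(...))

  # --- stage: simulate (or load external inputs) -------------------------
  scfg <- sim_config_from_pipeline(config)
  time_labels <- scfg$time_labels
  reps <- seq_len(scfg$n_replicates)
  truth <- NULL
  sim <- t_stage("simulate", function() {
    if (!is.null(config$inputs$genes)) {
      genes <- read_gene_table(config$inputs$genes)
      expr <- read_expression_table(config$inputs$expression)
      arrays <- NULL
      if (is.null(config$inputs$peaks_dir)) {
        arrays <- list()
        for (r in reps) for (t in time_labels) {
          f <- file.path(config$inputs$probe_dir,
                         sprintf("array_r%d_%s.tsv", r, t))
          arrays[[paste0("r", r, "_", t)]] <- read_probe_array(f, r, t)
        }
      }
      list(genes = genes, expr = expr, arrays = arrays, truth = NULL)
    } else {
      genes <- generate_genome(scfg)
      tr <- assign_truth(scfg, genes)
      arrays <- generate_probe_arrays(scfg, genes, tr)
      expr <- generate_expression(scfg, genes, tr)
      write_gene_table(genes, out_path("genes.tsv"))
      write_genes_bed(genes, out_path("genes.bed"))
      write_expression_table(expr, out_path("expression.tsv"))
      utils::write.table(tr$truth, out_path("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      for (nm in names(arrays))
        write_probe_array(arrays[[nm]], out_path("array_", nm, ".tsv"))
      list(genes = genes, expr = expr, arrays = arrays, truth = tr)
    }
  })
  genes <- sim$genes
  truth <- sim$truth
  log_info("genes: ", nrow(genes), "; arrays: ",
           if (is.null(sim$arrays)) "external peaks" else length(sim$arrays))

  # --- stage: peak calling + empirical FDR -------------------------------
  params <- peak_params_from_config(config$peaks)
  peaks <- t_stage("peak_calling", function() {
    out <- list()
    i <- 0L
    for (r in reps) for (t in time_labels) {
      nm <- paste0("r", r, "_", t)
      i <- i + 1L
      if (!is.null(config$inputs$peaks_dir)) {
        f <- file.path(config$inputs$peaks_dir,
                       sprintf("peaks_r%d_%s.bed", r, t))
        out[[nm]] <- read_peaks_bed(f, r, t)
      } else {
        pr <- sim$arrays[[nm]]
        st <- compute_array_stats(pr, params)
        pk <- call_peaks(pr, st, params)
        pk <- permutation_fdr(pr, st, pk, params,
                              seed = config$seed + 1000L + i)
        attr(pk, "permutation_scores") <- NULL
        out[[nm]] <- pk
        write_peaks_bed(pk, out_path("peaks_", nm, ".bed"))
      }
      log_info("array ", nm, ": ", nrow(out[[nm]]), " peaks, ",
               sum(out[[nm]]$fdr <= params$fdr_threshold),
               " at FDR <= ", params$fdr_threshold)
    }
    out
  })

  # --- stage: annotation -------------------------------------------------
  ann <- t_stage("annotation", function() {
    all_peaks <- do.call(rbind, c(peaks, list(make.row.names = FALSE)))
    a <- annotate_peaks(all_peaks, genes,
                        tss_cutoff_bp = config$annotate$tss_cutoff_bp,
                        upstream_bp = config$annotate$upstream_bp,
                        downstream_bp = config$annotate$downstream_bp)
    write_annotated_peaks(a$annotated, genes,
                          out_path("annotated_peaks.tsv"))
    log_info("annotated ", nrow(a$annotated), " / ",
             nrow(all_peaks), " peaks (", nrow(a$unannotated),
             " unannotated)")
    a
  })

  # --- stage: patterns ---------------------------------------------------
  pat <- t_stage("patterns", function() {
    bm <- binarize(ann$annotated, genes, time_labels,
                   fdr_threshold = config$patterns$fdr_threshold,
                   consensus_min = config$patterns$consensus_min,
                   n_replicates = scfg$n_replicates)
    asg <- assign_patterns(bm)
    sw <- classify_switches(asg$assignments)
    write_pattern_table(sw, out_path("patterns.tsv"))
    log_info("bound genes (pattern > 0): ",
             sum(asg$assignments$pattern_code > 0))
    list(bm = bm, assignments = asg$assignments, counts = asg$counts,
         switches = sw)
  })

  # --- stage: expression integration -------------------------------------
  integ <- t_stage("integration", function() {
    fc <- compute_fold_changes(sim$expr,
                               baseline = config$integrate$baseline,
                               pseudocount = config$integrate$pseudocount,
                               fc_threshold = config$integrate$fc_threshold)
    res <- integrate_expression(pat$assignments, fc, genes,
                                time_map = config$integrate$time_map,
                                baseline = config$integrate$baseline)
    se <- switch_expression_summary(res$joined, pat$switches,
                                    follow_ups =
                                      unname(config$integrate$time_map))
    utils::write.table(res$joined, out_path("binding_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$summary, out_path("pattern_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cl in unique(pat$switches$switch_class)) {
      ids <- res$joined$refseq_id[res$joined$de & res$joined$gene_id %in%
        pat$switches$gene_id[pat$switches$switch_class == cl]]
      writeLines(ids, out_path("genes_", cl, "_de.txt"))
    }
    log_info("pattern summary (pattern: bound/DE): ",
             paste(sprintf("%d: %d/%d", res$summary$pattern_code,
                           res$summary$n_bound, res$summary$n_de),
                   collapse = ", "))
    c(res, list(expr_fc = fc, switch_summary = se))
  })

  # --- stage: enrichment (optional) --------------------------------------
  enr <- NULL
  if (!is.null(config$enrich$gmt)) {
    enr <- t_stage("enrichment", function() {
      sets <- read_gmt(config$enrich$gmt)
      out <- list()
      for (cl in unique(pat$switches$switch_class)) {
        q <- integ$joined$refseq_id[integ$joined$de &
          integ$joined$gene_id %in%
            pat$switches$gene_id[pat$switches$switch_class == cl]]
        if (length(q) == 0) next
        out[[cl]] <- hypergeom_enrich(q, sets,
                                      universe = genes$refseq_id,
                                      p_cutoff = config$enrich$p_cutoff)
        utils::write.table(out[[cl]],
                           out_path("enrichment_", cl, ".tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out
    })
  }

  # --- manifest ----------------------------------------------------------
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(config = config, genes = genes, truth = truth,
                 expr = sim$expr, peaks = peaks, annotated = ann$annotated,
                 unannotated = ann$unannotated, binding = pat$bm,
                 assignments = pat$assignments, counts = pat$counts,
                 switches = pat$switches, integration = integ,
                 enrichment = enr, manifest = manifest, outdir = outdir))
}
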