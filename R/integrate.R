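#' Fold changes over baseline and differential-expression flags
#'
#' For each follow-up time `t`,
#' `log2fc_t = log2(rpkm_t + pseudocount) - log2(rpkm_baseline + pseudocount)`
#' and the gene is flagged differentially expressed when the fold change is
#' at least `fc_threshold` above or below baseline, i.e.
#' `|log2fc_t| >= log2(fc_threshold)`. The pseudocount keeps zero RPKM
#' finite; base 2 makes the 2-fold threshold a unit log fold change.
#'
#' @param expr expression data.frame with `rpkm_<time>` columns.
#' @param baseline baseline time label.
#' @param pseudocount added to every RPKM before the log.
#' @param fc_threshold linear fold-change threshold (>= applies).
#' @return `expr` with `log2fc_<time>` and logical `de_<time>` columns for
#'   every non-baseline time.
#' @export
compute_fold_changes <- function(expr, baseline = "0h", pseudocount = 0.1,
                                 fc_threshold = 2) {
  base_col <- paste0("rpkm_", baseline)
  if (!base_col %in% names(expr))
    stop("missing baseline column ", base_col)
  stopifnot(pseudocount > 0, fc_threshold > 0)
  rpkm_cols <- setdiff(grep("^rpkm_", names(expr), value = TRUE), base_col)
  b <- log2(expr[[base_col]] + pseudocount)
  for (cl in rpkm_cols) {
    t <- sub("^rpkm_", "", cl)
    lfc <- log2(expr[[cl]] + pseudocount) - b
    expr[[paste0("log2fc_", t)]] <- lfc
    expr[[paste0("de_", t)]] <- abs(lfc) >= log2(fc_threshold)
  }
  expr
}

#' Join binding patterns to differential expression at offset time points
#'
#' Binding at a time point is matched to expression at the mapped follow-up
#' time (default 1 h binding to 4 h expression, 6 h binding to 12 h). A gene
#' counts as differentially expressed for its pattern if it is DE at the
#' expression time mapped from any binding time at which the pattern bit is
#' 1; patterns bound only at baseline are evaluated at both follow-ups and
#' flagged `baseline_only`. Genes are matched by RefSeq id; unmatched genes
#' are excluded from DE counts and reported. The summary reproduces the
#' standard per-pattern layout (always 7 rows, codes 1-7): for the
#' constitutive pattern the reported count is all bound-and-measured genes
#' rather than DE genes, per the usual convention for that row.
#'
#' @param assignments data.frame from [assign_patterns()].
#' @param expr_fc expression table with `log2fc_*`/`de_*` columns (see
#'   [compute_fold_changes()]).
#' @param genes gene table supplying the RefSeq id per gene.
#' @param time_map named character vector: binding time -> expression time.
#' @param baseline binding baseline time label.
#' @return list with `joined` (per-gene table for bound genes), `summary`
#'   (7-row per-pattern table with `n_bound`, `n_matched`, `n_unmatched`,
#'   `n_de`, `n_reported`) and `n_unmatched_total`.
#' @export
integrate_expression <- function(assignments, expr_fc, genes,
                                 time_map = c("1h" = "4h", "6h" = "12h"),
                                 baseline = "0h") {
  tt <- nchar(assignments$binary[1])
  bound <- assignments[assignments$pattern_code > 0, , drop = FALSE]
  bound$refseq_id <- genes$refseq_id[match(bound$gene_id, genes$gene_id)]
  if (anyDuplicated(expr_fc$refseq_id)) {
    warning("duplicate RefSeq ids in expression table; using first match")
    expr_fc <- expr_fc[!duplicated(expr_fc$refseq_id), , drop = FALSE]
  }
  m <- match(bound$refseq_id, expr_fc$refseq_id)
  bound$matched <- !is.na(m)
  if (nrow(bound) == 0) {
    codes <- 1:(2L^tt - 1L)
    summary <- data.frame(
      pattern_code = codes,
      binary = vapply(codes, function(cd)
        paste(pattern_bits(cd, tt), collapse = ""), ""),
      n_bound = 0L, n_matched = 0L, n_unmatched = 0L, n_de = 0L,
      n_reported = 0L, note = "", stringsAsFactors = FALSE)
    return(list(joined = bound, summary = summary, n_unmatched_total = 0L))
  }

  binding_times <- c(baseline, names(time_map))
  follow_ups <- unname(time_map)
  bits <- do.call(rbind, strsplit(bound$binary, "")) == "1"
  colnames(bits) <- binding_times[seq_len(tt)]

  de_mat <- sapply(follow_ups, function(et) {
    v <- expr_fc[[paste0("de_", et)]][m]
    ifelse(is.na(v), FALSE, v)
  })
  if (nrow(bound) == 1) de_mat <- matrix(de_mat, nrow = 1,
                                         dimnames = list(NULL, follow_ups))
  lfc_mat <- sapply(follow_ups, function(et)
    expr_fc[[paste0("log2fc_", et)]][m])
  if (nrow(bound) == 1) lfc_mat <- matrix(lfc_mat, nrow = 1,
                                          dimnames = list(NULL, follow_ups))

  non_base_bits <- bits[, names(time_map), drop = FALSE]
  bound$baseline_only <- rowSums(non_base_bits) == 0
  de_eval <- matrix(FALSE, nrow(bound), length(follow_ups))
  for (k in seq_along(time_map)) {
    use <- non_base_bits[, k] | bound$baseline_only
    de_eval[, k] <- use & de_mat[, k]
  }
  bound$de <- bound$matched & rowSums(de_eval) > 0
  for (k in seq_along(follow_ups)) {
    bound[[paste0("log2fc_", follow_ups[k])]] <- lfc_mat[, k]
    bound[[paste0("de_", follow_ups[k])]] <- de_mat[, k] & bound$matched
  }
  rownames(bound) <- NULL

  codes <- 1:(2L^tt - 1L)
  f <- factor(bound$pattern_code, levels = codes)
  n_bound <- as.integer(table(f))
  n_matched <- as.integer(table(f[bound$matched]))
  n_de <- as.integer(table(f[bound$de]))
  summary <- data.frame(
    pattern_code = codes,
    binary = vapply(codes, function(cd) paste(pattern_bits(cd, tt),
                                              collapse = ""), ""),
    n_bound = n_bound, n_matched = n_matched,
    n_unmatched = n_bound - n_matched, n_de = n_de,
    stringsAsFactors = FALSE)
  constitutive <- 2L^tt - 1L
  summary$n_reported <- ifelse(summary$pattern_code == constitutive,
                               summary$n_matched, summary$n_de)
  summary$note <- ifelse(
    summary$pattern_code == constitutive,
    "n_reported counts all bound-and-measured genes",
    ifelse(vapply(codes, function(cd)
      sum(pattern_bits(cd, tt)[-1]) == 0, TRUE),
      "bound at baseline only; DE evaluated at both follow-ups", ""))
  list(joined = bound, summary = summary,
       n_unmatched_total = sum(!bound$matched))
}

#' Per-switch expression summary and binding-vs-unbinding contrast
#'
#' For every (switch class, arm, follow-up time): the number of matched
#' genes and the mean and SD of their log2 fold change; plus a directional
#' contrast per class and time, mean log2fc of the binding arm minus the
#' unbinding arm. Empty arms are reported as absent rather than zero.
#'
#' @param joined per-gene table from [integrate_expression()].
#' @param switches data.frame from [classify_switches()].
#' @param follow_ups expression follow-up time labels.
#' @return list with `by_arm` and `contrast` data.frames.
#' @export
switch_expression_summary <- function(joined, switches,
                                      follow_ups = c("4h", "12h")) {
  df <- merge(joined[joined$matched, , drop = FALSE],
              switches[c("gene_id", "switch_class", "arm")], by = "gene_id")
  rows <- list(); contr <- list()
  for (cl in unique(switches$switch_class)) {
    for (t in follow_ups) {
      lfc_col <- paste0("log2fc_", t)
      means <- c(binding = NA_real_, unbinding = NA_real_)
      for (arm in c("binding", "unbinding", "constitutive")) {
        v <- df[[lfc_col]][df$switch_class == cl & df$arm == arm]
        if (length(v) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          switch_class = cl, arm = arm, time = t, n = length(v),
          mean_log2fc = mean(v), sd_log2fc = stats::sd(v),
          stringsAsFactors = FALSE)
        if (arm %in% names(means)) means[arm] <- mean(v)
      }
      contr[[length(contr) + 1L]] <- data.frame(
        switch_class = cl, time = t,
        contrast = means["binding"] - means["unbinding"],
        stringsAsFactors = FALSE)
    }
  }
  list(by_arm = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       contrast = do.call(rbind, c(contr, list(make.row.names = FALSE))))
}
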