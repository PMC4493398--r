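#' Discretize binding across time with replicate consensus
#'
#' A replicate supports (gene, time) when at least one peak annotated to the
#' gene on that (replicate, time) array passes `fdr <= fdr_threshold`; the
#' gene is called bound at a time point when at least `consensus_min`
#' replicates (default 2 of 3) support it. Genes never supported anywhere
#' keep all-false rows (pattern 0).
#'
#' @param annotated annotated peaks across all arrays (columns `gene_id`,
#'   `replicate`, `time_label`, `fdr`).
#' @param genes gene table defining the gene universe and row order.
#' @param time_labels ordered time labels (earliest first).
#' @param fdr_threshold per-peak empirical FDR cutoff.
#' @param consensus_min replicates required for a bound call.
#' @param n_replicates total replicates (inferred from the data when NULL).
#' @return object of class `binding_matrix`: list with `genes`, `times`,
#'   logical `calls` matrix, integer `support` matrix, `n_replicates`,
#'   `consensus_min`.
#' @export
binarize <- function(annotated, genes, time_labels,
                     fdr_threshold = 0.05, consensus_min = 2,
                     n_replicates = NULL) {
  reps <- sort(unique(annotated$replicate))
  if (is.null(n_replicates)) n_replicates <- max(length(reps), 1L)
  times_seen <- split(annotated$time_label, annotated$replicate)
  if (length(times_seen) > 1) {
    tsets <- lapply(times_seen, function(x) sort(unique(x)))
    if (length(unique(tsets)) > 1)
      stop("time points are inconsistent across replicates")
  }
  qual <- annotated[!is.na(annotated$fdr) &
                    annotated$fdr <= fdr_threshold, , drop = FALSE]
  support <- matrix(0L, nrow = nrow(genes), ncol = length(time_labels),
                    dimnames = list(genes$gene_id, time_labels))
  if (nrow(qual) > 0) {
    key <- unique(qual[c("gene_id", "time_label", "replicate")])
    tab <- table(factor(key$gene_id, levels = genes$gene_id),
                 factor(key$time_label, levels = time_labels))
    support <- matrix(as.integer(tab), nrow = nrow(genes),
                      dimnames = list(genes$gene_id, time_labels))
  }
  structure(list(genes = genes$gene_id, times = time_labels,
                 calls = support >= consensus_min, support = support,
                 n_replicates = as.integer(n_replicates),
                 consensus_min = as.integer(consensus_min)),
            class = "binding_matrix")
}

#' Binding matrix from logical calls
#'
#' Convenience constructor used when binary calls are already available
#' (e.g. ground truth); support is set to `n_replicates` where called.
#'
#' @param calls logical gene x time matrix with dimnames.
#' @param n_replicates,consensus_min consensus bookkeeping values.
#' @return a `binding_matrix`.
#' @export
binding_matrix_from_calls <- function(calls, n_replicates = 3L,
                                      consensus_min = 2L) {
  structure(list(genes = rownames(calls), times = colnames(calls),
                 calls = calls,
                 support = ifelse(calls, as.integer(n_replicates), 0L),
                 n_replicates = as.integer(n_replicates),
                 consensus_min = as.integer(consensus_min)),
            class = "binding_matrix")
}

#' Assign one binary temporal pattern per gene
#'
#' The gene's bound/unbound calls ordered earliest to latest form a binary
#' string read MSB-first as a pattern code: with 3 time points, "000" is
#' pattern 0 (never bound), "001" (bound only at the last time) is
#' pattern 1, "010" is pattern 2, ..., "111" is pattern 7 (constitutive).
#' Patterns are mutually exclusive: each gene has exactly one.
#'
#' @param bm a `binding_matrix`.
#' @return list with `assignments` (data.frame: `gene_id`, `binary`,
#'   `pattern_code`) and `counts` (data.frame: `pattern_code`, `binary`,
#'   `n_genes` over all codes `0..2^T - 1`).
#' @export
assign_patterns <- function(bm) {
  tt <- length(bm$times)
  bits <- bm$calls * 1L
  code <- as.integer(bits %*% 2L^((tt - 1):0))
  binary <- apply(bits, 1, paste, collapse = "")
  assignments <- data.frame(gene_id = bm$genes, binary = binary,
                            pattern_code = code, stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  all_codes <- 0:(2L^tt - 1L)
  counts <- data.frame(
    pattern_code = all_codes,
    binary = vapply(all_codes, function(cd)
      paste(pattern_bits(cd, tt), collapse = ""), ""),
    n_genes = as.integer(table(factor(code, levels = all_codes))),
    stringsAsFactors = FALSE)
  list(assignments = assignments, counts = counts)
}

#' Pair patterns into binding/unbinding switches
#'
#' For 3 time points, the non-null codes pair each code `x` with its bitwise
#' complement `7 - x` into a switch class: immediate (011 binding / 100
#' unbinding), transient (010 / 101), delayed (001 / 110); 111 is
#' constitutive. The "binding" arm is a code whose earliest bit is 0 with a
#' later bit 1 (binding is gained); the "unbinding" arm starts bound and
#' loses binding. Pattern 0 (never bound) is excluded.
#'
#' @param assignments data.frame from [assign_patterns()].
#' @return data.frame (`gene_id`, `binary`, `pattern_code`, `switch_class`,
#'   `arm`) covering genes with codes 1..7 only.
#' @export
classify_switches <- function(assignments) {
  tt <- nchar(assignments$binary[1])
  if (tt != 3)
    stop("switch classification is defined for 3 time points")
  cls <- c("delayed", "transient", "immediate", "immediate", "transient",
           "delayed", "constitutive")
  names(cls) <- as.character(1:7)
  out <- assignments[assignments$pattern_code > 0, , drop = FALSE]
  out$switch_class <- cls[as.character(out$pattern_code)]
  first <- substr(out$binary, 1, 1)
  rest <- substr(out$binary, 2, tt)
  out$arm <- ifelse(out$pattern_code == 7L, "constitutive",
             ifelse(first == "0" & grepl("1", rest), "binding",
             ifelse(first == "1" & grepl("0", rest), "unbinding",
                    NA_character_)))
  rownames(out) <- NULL
  out
}

#' Confusion matrix of inferred vs true pattern codes
#'
#' Parameter-recovery report for synthetic runs: 2^T x 2^T confusion matrix
#' of true versus inferred codes and the overall accuracy.
#'
#' @param assignments data.frame from [assign_patterns()].
#' @param truth ground-truth data.frame with `gene_id`, `true_pattern`.
#' @return list with `confusion` (true x inferred matrix) and `accuracy`.
#' @export
pattern_recovery_report <- function(assignments, truth) {
  if (!setequal(assignments$gene_id, truth$gene_id))
    stop("gene sets of assignments and truth differ")
  m <- match(assignments$gene_id, truth$gene_id)
  n_codes <- 2L^nchar(assignments$binary[1])
  lv <- 0:(n_codes - 1L)
  confusion <- table(true = factor(truth$true_pattern[m], levels = lv),
                     inferred = factor(assignments$pattern_code,
                                       levels = lv))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}

#' Write per-gene pattern assignments and switch classes as TSV
#' @param switches data.frame from [classify_switches()].
#' @param path output path.
#' @export
write_pattern_table <- function(switches, path) {
  utils::write.table(switches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
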