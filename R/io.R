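#' @import methods
#' @importFrom stats setNames
NULL

# Coordinate conventions
# ----------------------
# All internal peak/interval arithmetic is 0-based half-open.  Every on-disk
# 1-based format (probe tables, gene tables, GFF3) is converted exactly once,
# here at the I/O boundary.  BED is already 0-based half-open.

#' Read a probe-signal array table
#'
#' Tab-separated dialect with header `probe_id  chrom  position  log2_ratio`;
#' `position` is the probe's 1-based central coordinate. Rows are validated
#' (numeric, finite, no duplicate (chrom, position) within an array) and
#' returned sorted by (chrom, position).
#'
#' @param path file path.
#' @param replicate,time_label array identity attached to every record.
#' @return data.frame with columns `probe_id`, `chrom`, `position`,
#'   `log2_ratio`, `replicate`, `time_label`.
#' @export
read_probe_array <- function(path, replicate = NA_integer_,
                             time_label = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("probe_id", "chrom", "position", "log2_ratio")
  if (!all(need %in% names(raw)))
    stop("probe table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw$position))
  val <- suppressWarnings(as.numeric(raw$log2_ratio))
  bad <- which(is.na(pos) | !is.finite(val) | is.na(val) | pos < 1)
  if (length(bad) > 0)
    stop("malformed probe row at line ", bad[1] + 1L, " of ", path,
         " (non-numeric or non-finite position/log2_ratio, or position < 1)")
  df <- data.frame(probe_id = raw$probe_id, chrom = raw$chrom,
                   position = as.integer(pos), log2_ratio = val,
                   replicate = rep(replicate, nrow(raw)),
                   time_label = rep(time_label, nrow(raw)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("chrom", "position")]))
    stop("duplicate (chrom, position) in probe array ", path)
  df <- df[order(df$chrom, df$position), ]
  rownames(df) <- NULL
  df
}

#' Write a probe-signal array table
#' @param probes probe data.frame (see [read_probe_array()]).
#' @param path output path.
#' @export
write_probe_array <- function(probes, path) {
  utils::write.table(
    probes[c("probe_id", "chrom", "position", "log2_ratio")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene annotation tables
#'
#' Tab-separated with columns `gene_id`, `refseq_id`, `chrom`, `strand`,
#' `tss`, `transcript_end` (1-based). [write_genes_bed()] exports the
#' strand-aware gene region (5 kb upstream of the TSS to 1.5 kb past the
#' transcript end by default) as BED6 (0-based half-open, name = gene_id).
#'
#' @param path file path.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "refseq_id", "chrom", "strand", "tss",
            "transcript_end")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) stop("strand must be '+' or '-'")
  plus <- df$strand == "+"
  if (any(plus & df$tss > df$transcript_end) ||
      any(!plus & df$tss < df$transcript_end))
    stop("tss/transcript_end inconsistent with strand")
  df
}

#' @rdname read_gene_table
#' @param genes gene table.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# strand-aware gene region, 1-based inclusive
gene_region_bounds <- function(genes, upstream_bp = 5000,
                               downstream_bp = 1500) {
  plus <- genes$strand == "+"
  start1 <- ifelse(plus, genes$tss - upstream_bp,
                   genes$transcript_end - downstream_bp)
  end1 <- ifelse(plus, genes$transcript_end + downstream_bp,
                 genes$tss + upstream_bp)
  data.frame(start1 = pmax(1, start1), end1 = end1)
}

#' @rdname read_gene_table
#' @param upstream_bp,downstream_bp gene-region extent around the transcript.
#' @export
write_genes_bed <- function(genes, path, upstream_bp = 5000,
                            downstream_bp = 1500) {
  rg <- gene_region_bounds(genes, upstream_bp, downstream_bp)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = rg$start1, end = rg$end1),
    strand = genes$strand)
  gr$name <- genes$gene_id
  gr$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

empty_peaks <- function() {
  data.frame(peak_id = character(), chrom = character(),
             start = integer(), end = integer(), score = numeric(),
             n_probes = integer(), mean_log2 = numeric(), fdr = numeric(),
             replicate = integer(), time_label = character(),
             stringsAsFactors = FALSE)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Write peaks as BED6 / GFF3
#'
#' BED is 0-based half-open with the BED score column carrying the peak
#' score (highest detecting cutoff fraction) scaled to 0--1000 and the name
#' field carrying `"<peak_id>;fdr=<fdr>"`. GFF3 is 1-based inclusive with
#' the raw peak score in the score column and the FDR as an attribute.
#'
#' @param peaks peak data.frame from [call_peaks()] / [permutation_fdr()].
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines('track name="peaks" description="cutoff-scan peaks"', path)
    return(invisible(path))
  }
  gr <- peaks_to_granges(peaks)
  gr$name <- sprintf("%s;fdr=%s", peaks$peak_id,
                     formatC(peaks$fdr, format = "g", digits = 12))
  gr$score <- as.integer(round(peaks$score * 1000))
  rtracklayer::export.bed(
    gr, path,
    trackLine = new("BasicTrackLine", name = "peaks",
                    description = "cutoff-scan peaks"))
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
write_peaks_gff <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- peaks_to_granges(peaks)
  gr$source <- "switchscan"
  gr$type <- "binding_site"
  gr$score <- peaks$score
  gr$ID <- peaks$peak_id
  gr$fdr <- formatC(peaks$fdr, format = "g", digits = 12)
  gr$n_probes <- peaks$n_probes
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read peaks from BED / GFF3 written by this package
#'
#' Inverse of [write_peaks_bed()] / [write_peaks_gff()]; coordinates are
#' converted back to the internal 0-based half-open convention.
#'
#' @param path file path.
#' @param replicate,time_label array identity to attach.
#' @return peak data.frame.
#' @export
read_peaks_bed <- function(path, replicate = NA_integer_,
                           time_label = NA_character_) {
  gr <- rtracklayer::import.bed(path)
  if (length(gr) == 0) return(empty_peaks())
  nm <- strsplit(gr$name, ";fdr=", fixed = TRUE)
  data.frame(
    peak_id = vapply(nm, `[`, "", 1L),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = gr$score / 1000,
    n_probes = NA_integer_, mean_log2 = NA_real_,
    fdr = as.numeric(vapply(nm, `[`, "", 2L)),
    replicate = replicate, time_label = time_label,
    stringsAsFactors = FALSE)
}

#' @rdname read_peaks_bed
#' @export
read_peaks_gff <- function(path, replicate = NA_integer_,
                           time_label = NA_character_) {
  gr <- rtracklayer::import.gff3(path)
  if (length(gr) == 0) return(empty_peaks())
  np <- if (is.null(gr$n_probes)) rep(NA_integer_, length(gr)) else
    as.integer(gr$n_probes)
  data.frame(
    peak_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score),
    n_probes = np, mean_log2 = NA_real_,
    fdr = as.numeric(gr$fdr),
    replicate = replicate, time_label = time_label,
    stringsAsFactors = FALSE)
}

#' Read an expression table in RPKM
#'
#' Requires `gene_id` and `refseq_id` columns plus one `rpkm_<time>` column
#' per expression time label. Negative RPKM values are rejected.
#'
#' @param path file path.
#' @return data.frame of expression records.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "refseq_id") %in% names(df)))
    stop("expression table must have gene_id and refseq_id columns")
  rpkm_cols <- grep("^rpkm_", names(df), value = TRUE)
  if (length(rpkm_cols) == 0)
    stop("expression table must have at least one rpkm_<time> column")
  for (cl in rpkm_cols) {
    v <- df[[cl]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0))
      stop("column ", cl, " must be numeric and nonnegative (RPKM)")
  }
  df
}

#' Write an expression table
#' @param expr expression data.frame.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
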