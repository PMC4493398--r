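#' Annotate peaks to candidate target genes by TSS proximity
#'
#' Each peak is assigned to the gene with the smallest absolute signed
#' distance from the peak centre to the TSS, when that distance is within
#' `tss_cutoff_bp` (default 5000); failing that, a peak whose centre falls
#' inside a gene region (5 kb upstream of the TSS to 1.5 kb past the
#' transcript end, strand-aware) is assigned to the nearest such gene;
#' otherwise it is reported unannotated. Exactly one gene per annotated peak.
#'
#' The signed distance is strand-aware: negative means the peak centre lies
#' upstream of the TSS in the gene's transcription direction. The peak
#' centre of the 0-based half-open interval `[start, end)` is the 1-based
#' coordinate `floor((start + 1 + end) / 2)` (floor of the midpoint). Ties
#' in distance are broken deterministically toward the gene earliest in
#' (chrom, tss, gene_id) order.
#'
#' @param peaks peak data.frame.
#' @param genes gene table (see [read_gene_table()]).
#' @param tss_cutoff_bp maximum |distance| to the TSS for direct assignment.
#' @param upstream_bp,downstream_bp gene-region extent for the containment
#'   fallback.
#' @return list with `annotated` (peak columns plus `gene_id`, `refseq_id`,
#'   `signed_distance_bp`, `location_class`) and `unannotated` (peaks).
#' @export
annotate_peaks <- function(peaks, genes, tss_cutoff_bp = 5000,
                           upstream_bp = 5000, downstream_bp = 1500) {
  if (nrow(genes) == 0) stop("gene table is empty")
  genes <- genes[order(genes$chrom, genes$tss, genes$gene_id), ]
  rg <- gene_region_bounds(genes, upstream_bp, downstream_bp)

  if (nrow(peaks) == 0) {
    ann <- cbind(peaks, data.frame(gene_id = character(),
                                   refseq_id = character(),
                                   signed_distance_bp = integer(),
                                   location_class = character()))
    return(list(annotated = ann, unannotated = peaks))
  }

  centre <- floor((peaks$start + 1 + peaks$end) / 2)
  hit_gene <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (length(gi) == 0) next
    sgn <- ifelse(genes$strand[gi] == "+", 1L, -1L)
    for (p in pi) {
      d <- (centre[p] - genes$tss[gi]) * sgn
      best <- which(abs(d) == min(abs(d)))[1]  # gi sorted by (tss, gene_id)
      if (abs(d[best]) <= tss_cutoff_bp) {
        hit_gene[p] <- gi[best]
      } else {
        inside <- which(centre[p] >= rg$start1[gi] &
                        centre[p] <= rg$end1[gi])
        if (length(inside) > 0) {
          b2 <- inside[which.min(abs(d[inside]))]
          hit_gene[p] <- gi[b2]
        }
      }
    }
  }

  ok <- !is.na(hit_gene)
  ann <- peaks[ok, , drop = FALSE]
  g <- hit_gene[ok]
  sgn <- ifelse(genes$strand[g] == "+", 1L, -1L)
  dist <- (centre[ok] - genes$tss[g]) * sgn
  tx_lo <- pmin(genes$tss[g], genes$transcript_end[g])
  tx_hi <- pmax(genes$tss[g], genes$transcript_end[g])
  in_tx <- centre[ok] >= tx_lo & centre[ok] <= tx_hi
  ann$gene_id <- genes$gene_id[g]
  ann$refseq_id <- genes$refseq_id[g]
  ann$signed_distance_bp <- as.integer(dist)
  ann$location_class <- ifelse(dist < 0, "upstream",
                               ifelse(in_tx, "downstream-in-gene",
                                      "downstream-of-gene"))
  rownames(ann) <- NULL
  un <- peaks[!ok, , drop = FALSE]
  rownames(un) <- NULL
  list(annotated = ann, unannotated = un)
}

#' Signed distance-to-TSS histogram per time point
#'
#' Bins the signed peak-centre-to-TSS distances of annotated peaks into
#' `bin_bp` bins over `[-max_bp, +max_bp]`, per time point, and reports the
#' mode bin (midpoint of the first most-populated bin). Distances outside
#' the range (possible for peaks annotated through the gene-region fallback)
#' are dropped from the histogram.
#'
#' @param annotated annotated-peak data.frame (from [annotate_peaks()]),
#'   with a `time_label` column.
#' @param bin_bp bin width, bp.
#' @param max_bp histogram half-range, bp.
#' @return list with `histogram` (data.frame: `time_label`, `bin_start`,
#'   `bin_end`, `count`) and `modes` (data.frame: `time_label`,
#'   `mode_midpoint`, `mode_count`).
#' @export
tss_distance_profile <- function(annotated, bin_bp = 250, max_bp = 5000) {
  breaks <- seq(-max_bp, max_bp, by = bin_bp)
  times <- unique(annotated$time_label)
  hists <- list(); modes <- list()
  for (t in times) {
    d <- annotated$signed_distance_bp[annotated$time_label == t]
    d <- d[d >= -max_bp & d <= max_bp]
    if (length(d) == 0) {
      warning("no annotated peaks within range for time ", t)
      next
    }
    cnt <- hist(d, breaks = breaks, plot = FALSE,
                right = FALSE, include.lowest = TRUE)$counts
    hists[[t]] <- data.frame(time_label = t,
                             bin_start = breaks[-length(breaks)],
                             bin_end = breaks[-1], count = cnt,
                             stringsAsFactors = FALSE)
    k <- which.max(cnt)
    modes[[t]] <- data.frame(time_label = t,
                             mode_midpoint = (breaks[k] + breaks[k + 1]) / 2,
                             mode_count = cnt[k], stringsAsFactors = FALSE)
  }
  list(histogram = do.call(rbind, c(hists, list(make.row.names = FALSE))),
       modes = do.call(rbind, c(modes, list(make.row.names = FALSE))))
}

#' Overlap of peaks with a set of genomic intervals
#'
#' Half-open interval intersection between each peak and a reduced
#' (self-merged) copy of the supplied intervals; a peak overlaps when at
#' least 1 bp is shared. Adjacent half-open intervals do not overlap.
#' Chromosome names are compared as exact strings.
#'
#' @param peaks peak data.frame (0-based half-open `start`/`end`).
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from `rtracklayer::import.bed()` after conversion.
#' @return `peaks` with logical `overlaps` and integer `overlap_bp` columns.
#' @export
region_overlap <- function(peaks, intervals) {
  peaks$overlaps <- FALSE
  peaks$overlap_bp <- 0L
  if (nrow(peaks) == 0 || nrow(intervals) == 0) return(peaks)
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  ig <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end)))
  ov <- GenomicRanges::findOverlaps(pg, ig)
  if (length(ov) > 0) {
    w <- GenomicRanges::width(IRanges::pintersect(
      pg[S4Vectors::queryHits(ov)], ig[S4Vectors::subjectHits(ov)]))
    bp <- tapply(w, S4Vectors::queryHits(ov), sum)
    idx <- as.integer(names(bp))
    peaks$overlap_bp[idx] <- as.integer(bp)
    peaks$overlaps[idx] <- TRUE
  }
  peaks
}

#' Export annotated peaks as TSV
#'
#' Columns mirror the usual ChIP annotation fields (peak location, nearest
#' gene and transcript boundaries, distance from TSS, RefSeq id); Entrez and
#' conservation columns are emitted empty unless a mapping table with
#' columns `refseq_id`, `entrez_id` is supplied.
#'
#' @param annotated annotated peaks from [annotate_peaks()].
#' @param genes gene table.
#' @param path output path.
#' @param entrez_map optional data.frame mapping `refseq_id` to `entrez_id`.
#' @export
write_annotated_peaks <- function(annotated, genes, path,
                                  entrez_map = NULL) {
  g <- genes[match(annotated$gene_id, genes$gene_id), ]
  out <- data.frame(
    peak_id = annotated$peak_id, chrom = annotated$chrom,
    peak_start = annotated$start, peak_end = annotated$end,
    score = annotated$score, fdr = annotated$fdr,
    replicate = annotated$replicate, time_label = annotated$time_label,
    gene_id = annotated$gene_id, refseq_id = annotated$refseq_id,
    gene_tss = g$tss, gene_end = g$transcript_end, gene_strand = g$strand,
    distance_to_tss = annotated$signed_distance_bp,
    location_class = annotated$location_class,
    entrez_id = NA_character_, phastcons = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(entrez_map)) {
    m <- match(out$refseq_id, entrez_map$refseq_id)
    out$entrez_id <- entrez_map$entrez_id[m]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
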