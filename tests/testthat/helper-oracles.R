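# Independent oracles used by the test suite. These deliberately avoid the
# package's vectorized code paths: plain quadratic loops and exhaustive
# enumeration only.

# Brute-force cutoff-scan peak caller on one chromosome.
# probes: data.frame(position, log2_ratio), any order.
# Returns data.frame(start, end, score) in 0-based half-open coordinates.
oracle_call_peaks_chrom <- function(position, value, hmax, window_bp = 500,
                                    min_probes = 4,
                                    cutoffs = seq(0.90, 0.15, by = -0.05)) {
  o <- order(position)
  position <- position[o]; value <- value[o]
  peaks <- data.frame(start1 = numeric(0), end1 = numeric(0),
                      score = numeric(0))
  for (f in cutoffs) {
    cut <- f * hmax
    qual <- position[value > cut]
    # every window with its left edge at a qualifying probe
    seeds <- list()
    for (p in qual) {
      inside <- qual[qual >= p & qual <= p + window_bp]
      if (length(inside) >= min_probes)
        seeds[[length(seeds) + 1L]] <- c(min(inside), max(inside))
    }
    if (length(seeds) == 0) next
    # naive merge to a fixpoint
    regions <- do.call(rbind, seeds)
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i <= nrow(regions)) {
        j <- i + 1
        while (j <= nrow(regions)) {
          if (regions[i, 1] <= regions[j, 2] &&
              regions[j, 1] <= regions[i, 2]) {
            regions[i, ] <- c(min(regions[i, 1], regions[j, 1]),
                              max(regions[i, 2], regions[j, 2]))
            regions <- regions[-j, , drop = FALSE]
            merged_any <- TRUE
          } else j <- j + 1
        }
        i <- i + 1
      }
      if (!merged_any) break
    }
    # absorb into existing peaks (keep highest score, maximal extent)
    for (k in seq_len(nrow(regions))) {
      hit <- which(peaks$start1 <= regions[k, 2] &
                   peaks$end1 >= regions[k, 1])
      if (length(hit) == 0) {
        peaks <- rbind(peaks, data.frame(start1 = regions[k, 1],
                                         end1 = regions[k, 2], score = f))
      } else {
        peaks <- rbind(
          peaks[-hit, , drop = FALSE],
          data.frame(start1 = min(regions[k, 1], peaks$start1[hit]),
                     end1 = max(regions[k, 2], peaks$end1[hit]),
                     score = max(peaks$score[hit])))
      }
    }
  }
  peaks <- peaks[order(peaks$start1), , drop = FALSE]
  rownames(peaks) <- NULL
  data.frame(start = peaks$start1 - 1, end = peaks$end1,
             score = peaks$score)
}

# Exhaustive hypergeometric upper tail: probability that a uniformly random
# draw of n from N (of which the first K are "in the set") overlaps the set
# in at least k elements.
oracle_hypergeom_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the set
  sum(hits >= k) / ncol(draws)
}

# Quadratic all-pairs interval intersection (0-based half-open).
oracle_overlap_bp <- function(p_start, p_end, i_start, i_end) {
  total <- 0L
  for (j in seq_along(i_start)) {
    lo <- max(p_start, i_start[j])
    hi <- min(p_end, i_end[j])
    if (hi > lo) total <- total + (hi - lo)
  }
  total
}

# Small convenience: a probe data.frame on one chromosome.
make_probes <- function(position, log2_ratio, chrom = "chr1",
                        replicate = 1L, time_label = "0h") {
  data.frame(probe_id = sprintf("p%04d", seq_along(position)),
             chrom = chrom, position = as.integer(position),
             log2_ratio = log2_ratio, replicate = replicate,
             time_label = time_label, stringsAsFactors = FALSE)
}

# Peak row constructor for annotation tests (0-based half-open).
make_peaks <- function(start, end, chrom = "chr1", score = 0.5,
                       fdr = 0.01, replicate = 1L, time_label = "0h") {
  n <- length(start)
  data.frame(peak_id = sprintf("peak_%04d", seq_len(n)),
             chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             score = rep_len(score, n), n_probes = rep_len(4L, n),
             mean_log2 = rep_len(2, n), fdr = rep_len(fdr, n),
             replicate = rep_len(replicate, n),
             time_label = rep_len(time_label, n),
             stringsAsFactors = FALSE)
}

# One-gene table helper.
make_genes <- function(tss, strand = "+", chrom = "chr1",
                       transcript_len = 3000) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  tend <- ifelse(strand == "+", tss + transcript_len, tss - transcript_len)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             refseq_id = sprintf("NM_%06d", seq_len(n)),
             chrom = rep_len(chrom, n), strand = strand, tss = tss,
             transcript_end = tend, stringsAsFactors = FALSE)
}
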