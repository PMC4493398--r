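#' Peak-caller parameters
#'
#' Parameters of the cutoff-scan sliding-window peak caller. Defaults follow
#' the tiling-array convention this package implements: a peak requires at
#' least 4 probes above the cutoff inside a 500 bp window; cutoffs scan from
#' 90% down to 15% of the hypothetical maximum signal (array mean plus six
#' standard deviations) in steps of 0.05; the empirical FDR uses 20 signal
#' permutations and peaks are kept at FDR <= 0.05.
#'
#' @param window_bp sliding-window width, bp.
#' @param min_probes minimum qualifying probes within one window (>= 2).
#' @param cutoff_fractions strictly descending fractions in (0, 1] of the
#'   hypothetical maximum signal.
#' @param n_permutations number of signal permutations for the empirical FDR.
#' @param fdr_threshold FDR cutoff used downstream.
#' @param sd_multiplier multiplier on the array SD in the hypothetical
#'   maximum.
#' @param per_chromosome_shuffle if TRUE, permutations shuffle log2 ratios
#'   within each chromosome instead of across the whole array.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(window_bp = 500,
                        min_probes = 4,
                        cutoff_fractions = seq(0.90, 0.15, by = -0.05),
                        n_permutations = 20,
                        fdr_threshold = 0.05,
                        sd_multiplier = 6.0,
                        per_chromosome_shuffle = FALSE) {
  p <- list(window_bp = as.integer(window_bp),
            min_probes = as.integer(min_probes),
            cutoff_fractions = cutoff_fractions,
            n_permutations = as.integer(n_permutations),
            fdr_threshold = fdr_threshold,
            sd_multiplier = sd_multiplier,
            per_chromosome_shuffle = isTRUE(per_chromosome_shuffle))
  stopifnot(p$window_bp >= 1L, p$min_probes >= 2L, p$n_permutations >= 1L,
            p$fdr_threshold > 0, p$fdr_threshold <= 1)
  f <- p$cutoff_fractions
  if (length(f) < 1 || any(f <= 0) || any(f > 1) || any(diff(f) >= 0))
    stop("cutoff_fractions must be strictly descending within (0, 1]")
  class(p) <- "peak_params"
  p
}

#' Per-array signal statistics and hypothetical maximum
#'
#' The hypothetical maximum signal is the array mean log2 ratio plus
#' `sd_multiplier` (default six) standard deviations; peak-calling cutoffs
#' are fractions of it. The SD uses the population convention
#' (divisor n), fixed so exactness tests are well defined; with array-scale
#' probe counts the difference from the sample SD is negligible.
#'
#' @param probes probe data.frame (>= 2 rows).
#' @param params a [peak_params()] object.
#' @return list of class `array_stats`: `mean`, `sd`, `hypothetical_max`.
#' @export
compute_array_stats <- function(probes, params = peak_params()) {
  x <- probes$log2_ratio
  if (length(x) < 2) stop("need at least 2 probes to compute array stats")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0)
    warning("array SD is 0; hypothetical maximum degenerates to the mean")
  structure(list(mean = m, sd = s,
                 hypothetical_max = m + params$sd_multiplier * s),
            class = "array_stats")
}

# Seed regions at one absolute cutoff on one chromosome.
# pos: sorted 1-based probe positions; returns matrix [start1, end1]
# (1-based inclusive span of qualifying probes) of merged regions.
#
# A window of width window_bp is anchored at each qualifying probe p and
# covers qualifying probes q with pos_p <= pos_q <= pos_p + window_bp.
# Anchoring the left edge at probes is equivalent to a freely sliding
# window: any window can be shifted right until its left edge meets a probe
# without losing probes.
seed_regions <- function(pos, val, cutoff, window_bp, min_probes) {
  q <- pos[val > cutoff]
  if (length(q) < min_probes) return(NULL)
  jmax <- findInterval(q + window_bp, q)
  n_in <- jmax - seq_along(q) + 1L
  i_seed <- which(n_in >= min_probes)
  if (length(i_seed) == 0) return(NULL)
  starts <- q[i_seed]
  ends <- q[jmax[i_seed]]
  # merge overlapping/adjoining intervals; starts already sorted
  keep_start <- starts
  keep_end <- ends
  run_end <- cummax(keep_end)
  new_run <- c(TRUE, keep_start[-1] > run_end[-length(run_end)])
  grp <- cumsum(new_run)
  cbind(start1 = tapply(keep_start, grp, min),
        end1 = tapply(keep_end, grp, max))
}

call_peaks_chrom <- function(pos, val, hmax, params) {
  pk <- NULL  # matrix: start1, end1, score
  for (f in params$cutoff_fractions) {
    reg <- seed_regions(pos, val, f * hmax, params$window_bp,
                        params$min_probes)
    if (is.null(reg)) next
    if (is.null(pk)) {
      pk <- cbind(reg, score = f)
      next
    }
    for (k in seq_len(nrow(reg))) {
      ov <- which(pk[, "start1"] <= reg[k, "end1"] &
                  pk[, "end1"] >= reg[k, "start1"])
      if (length(ov) == 0) {
        pk <- rbind(pk, c(reg[k, ], score = f))
      } else {
        merged <- c(start1 = min(reg[k, "start1"], pk[ov, "start1"]),
                    end1 = max(reg[k, "end1"], pk[ov, "end1"]),
                    score = max(pk[ov, "score"]))
        pk <- rbind(pk[-ov, , drop = FALSE], merged)
      }
    }
  }
  pk
}

#' Call peaks on one array by cutoff scan
#'
#' For each cutoff fraction `f` (descending), the absolute cutoff is
#' `f * hypothetical_max`; a window of `window_bp` anchored at each
#' qualifying probe seeds a region whenever it holds `min_probes` or more
#' probes with log2 ratio strictly above the cutoff (ties at the cutoff do
#' not qualify). Overlapping or adjoining seed windows merge; a region first
#' detected at fraction `f` gets score `f`, and regions detected at lower
#' fractions that overlap a higher-score peak are absorbed into it, so each
#' peak keeps its maximal extent over all fractions at which it is detected.
#'
#' @param probes probe data.frame sorted by (chrom, position).
#' @param stats an [compute_array_stats()] result for the same array.
#' @param params a [peak_params()] object.
#' @return peak data.frame (0-based half-open `start`/`end`); `fdr` is `NA`
#'   until [permutation_fdr()] fills it. `score` is the highest detecting
#'   cutoff fraction, `n_probes` the number of probes above that cutoff
#'   within the peak, `mean_log2` their mean log2 ratio.
#' @export
call_peaks <- function(probes, stats, params = peak_params()) {
  if (is.unsorted(order(probes$chrom, probes$position)))
    probes <- probes[order(probes$chrom, probes$position), ]
  hmax <- stats$hypothetical_max
  res <- list()
  for (ch in unique(probes$chrom)) {
    sel <- probes$chrom == ch
    pk <- call_peaks_chrom(probes$position[sel], probes$log2_ratio[sel],
                           hmax, params)
    if (is.null(pk) || nrow(pk) == 0) next
    pk <- pk[order(pk[, "start1"]), , drop = FALSE]
    pos <- probes$position[sel]
    val <- probes$log2_ratio[sel]
    n_pb <- integer(nrow(pk)); mlog <- numeric(nrow(pk))
    for (k in seq_len(nrow(pk))) {
      contrib <- val[pos >= pk[k, "start1"] & pos <= pk[k, "end1"] &
                     val > pk[k, "score"] * hmax]
      n_pb[k] <- length(contrib)
      mlog[k] <- mean(contrib)
    }
    res[[ch]] <- data.frame(
      chrom = ch,
      start = as.integer(pk[, "start1"]) - 1L,
      end = as.integer(pk[, "end1"]),
      score = pk[, "score"], n_probes = n_pb, mean_log2 = mlog,
      fdr = NA_real_,
      replicate = probes$replicate[sel][1],
      time_label = probes$time_label[sel][1],
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty_peaks())
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out <- cbind(peak_id = sprintf("peak_%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}

#' Empirical FDR by signal permutation
#'
#' Log2 ratios are shuffled across the array's probe positions (positions
#' fixed, values permuted) `n_permutations` times and peaks are re-called on
#' each shuffle. For an observed peak score `s`,
#' `fdr(s) = min(1, mean_perm #\{permuted peaks with score >= s\} /
#' max(1, #\{observed peaks with score >= s\}))`, followed by a step-down
#' pass that enforces FDR monotone non-increasing in score. Deterministic
#' given `seed`.
#'
#' @param probes probe data.frame of the array.
#' @param stats its [compute_array_stats()] result (permutation preserves
#'   mean and SD, so the same stats apply to every shuffle).
#' @param observed_peaks result of [call_peaks()] on the same array.
#' @param params a [peak_params()] object.
#' @param seed integer seed for the permutation stream.
#' @return `observed_peaks` with `fdr` filled; attribute
#'   `"permutation_scores"` holds the list of permuted peak-score vectors
#'   for audit.
#' @export
permutation_fdr <- function(probes, stats, observed_peaks,
                            params = peak_params(), seed) {
  if (missing(seed)) stop("'seed' is required for permutation_fdr()")
  if (nrow(observed_peaks) == 0) return(observed_peaks)
  set.seed(as.integer(seed))
  perm_scores <- vector("list", params$n_permutations)
  pp <- probes
  for (i in seq_len(params$n_permutations)) {
    if (params$per_chromosome_shuffle) {
      v <- probes$log2_ratio
      for (ch in unique(probes$chrom)) {
        sel <- probes$chrom == ch
        v[sel] <- sample(v[sel])
      }
      pp$log2_ratio <- v
    } else {
      pp$log2_ratio <- sample(probes$log2_ratio)
    }
    perm_scores[[i]] <- call_peaks(pp, stats, params)$score
  }
  observed_peaks$fdr <- fdr_from_scores(observed_peaks$score, perm_scores)
  attr(observed_peaks, "permutation_scores") <- perm_scores
  observed_peaks
}

# Tail-count FDR with step-down monotonization; exported for audit so tests
# can recompute FDR values from logged permutation score lists.
#' @rdname permutation_fdr
#' @param observed_scores numeric vector of observed peak scores.
#' @param perm_scores list of numeric vectors of permuted peak scores.
#' @export
fdr_from_scores <- function(observed_scores, perm_scores) {
  s_levels <- sort(unique(observed_scores))  # ascending
  raw <- vapply(s_levels, function(s) {
    obs_ge <- sum(observed_scores >= s)
    perm_ge <- mean(vapply(perm_scores, function(v) sum(v >= s), numeric(1)))
    min(1, perm_ge / max(1, obs_ge))
  }, numeric(1))
  mono <- cummin(raw)  # non-increasing in score
  mono[match(observed_scores, s_levels)]
}

#' Scree-plot elbow for a peak-score cutoff
#'
#' Given peak scores sorted in descending order, picks the elbow of the
#' scree curve as the point of maximal perpendicular distance from
#' `(rank, score)` to the chord joining the first and last points; ties are
#' broken toward the smaller rank (the stricter cutoff).
#'
#' @param peak_scores numeric vector, descending, length >= 3.
#' @return list with `index` (rank of the elbow) and `threshold`
#'   (the score at that rank).
#' @export
scree_score_cutoff <- function(peak_scores) {
  n <- length(peak_scores)
  if (n < 3) stop("need at least 3 scores for a scree cutoff")
  if (is.unsorted(rev(peak_scores)))
    stop("peak_scores must be sorted in descending order")
  x <- seq_len(n)
  dy <- peak_scores[n] - peak_scores[1]
  dx <- n - 1
  num <- abs(dy * (x - 1) - dx * (peak_scores - peak_scores[1]))
  d <- num / sqrt(dy^2 + dx^2)
  idx <- which.max(d)  # which.max takes the first (smallest rank) on ties
  list(index = idx, threshold = peak_scores[idx])
}
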