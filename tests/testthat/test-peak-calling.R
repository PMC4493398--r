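test_that("array statistics follow the population-SD convention", {
  pp <- peak_params()
  expect_error(compute_array_stats(make_probes(1, 0), pp), "at least 2")

  expect_warning(
    compute_array_stats(make_probes(c(100, 200, 300, 400), rep(0, 4)), pp),
    "SD is 0")
  s0 <- suppressWarnings(
    compute_array_stats(make_probes(c(100, 200, 300, 400), rep(0, 4)), pp))
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)
  expect_equal(s0$hypothetical_max, 0)

  # population SD: {-1, 1} has sd 1 (not sqrt(2)); hmax = 0 + 6*1 = 6
  s1 <- compute_array_stats(make_probes(c(100, 200), c(-1, 1)), pp)
  expect_equal(s1$mean, 0)
  expect_equal(s1$sd, 1)
  expect_equal(s1$hypothetical_max, 6)

  # translation: shifting all ratios by +c shifts mean and hmax, sd fixed
  set.seed(1)
  x <- rnorm(50)
  sa <- compute_array_stats(make_probes(seq(100, 5000, 100), x), pp)
  sb <- compute_array_stats(make_probes(seq(100, 5000, 100), x + 2.5), pp)
  expect_equal(sb$mean, sa$mean + 2.5)
  expect_equal(sb$sd, sa$sd)
  expect_equal(sb$hypothetical_max, sa$hypothetical_max + 2.5)
})

test_that("the minimal qualifying configuration yields exactly one peak", {
  # 4 probes above the f=0.90 cutoff within 500 bp, background elsewhere
  pos <- c(100, 200, 300, 400, seq(2000, 6000, 100))
  val <- c(rep(10, 4), rep(0, 41))
  probes <- make_probes(pos, val)
  stats <- list(mean = 0, sd = 1, hypothetical_max = 10)
  pk <- call_peaks(probes, stats, peak_params())
  # strict ">" at the cutoff: value 10 is NOT above 0.90*10=9? it is (10>9),
  # and also not above 1.00*10; top fraction scanned is 0.90
  expect_equal(nrow(pk), 1)
  expect_equal(pk$score, 0.90)
  expect_gte(pk$n_probes, 4)
  expect_equal(pk$start, 100 - 1)  # 0-based half-open spanning 100..400
  expect_equal(pk$end, 400)

  # only 3 probes above every cutoff in any 500 bp window -> no peaks
  probes3 <- make_probes(c(100, 200, 300, seq(2000, 6000, 100)),
                         c(rep(10, 3), rep(0, 41)))
  expect_equal(nrow(call_peaks(probes3, stats, peak_params())), 0)

  # ties at the absolute cutoff do not qualify (strict "above")
  tie <- make_probes(c(100, 200, 300, 400), rep(9, 4))
  pk_tie <- call_peaks(tie, list(mean = 0, sd = 1, hypothetical_max = 10),
                       peak_params(cutoff_fractions = 0.90))
  expect_equal(nrow(pk_tie), 0)
})

test_that("call_peaks matches the brute-force window-enumeration oracle", {
  pp <- peak_params()
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(50:200, 1)
    pos <- sort(sample(1:20000, n))
    val <- rnorm(n, 0, 0.5)
    # spike some clustered enrichment half the time
    if (seed %% 2 == 0) {
      c0 <- sample(pos, 1)
      val[abs(pos - c0) <= 300] <- val[abs(pos - c0) <= 300] + 2
    }
    probes <- make_probes(pos, val)
    stats <- compute_array_stats(probes, pp)
    got <- call_peaks(probes, stats, pp)
    want <- oracle_call_peaks_chrom(pos, val, stats$hypothetical_max)
    expect_equal(nrow(got), nrow(want), label = paste("seed", seed))
    expect_equal(got$start, want$start, label = paste("seed", seed))
    expect_equal(got$end, want$end, label = paste("seed", seed))
    expect_equal(got$score, want$score, label = paste("seed", seed))
  }
})

test_that("relaxing min_probes or extending the cutoff scan never removes peaks", {
  pp_hi <- peak_params(cutoff_fractions = seq(0.90, 0.40, by = -0.05))
  pp_full <- peak_params()
  pp_loose <- peak_params(min_probes = 3)
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample(1:30000, 300))
    val <- rnorm(300, 0, 0.5)
    c0 <- sample(pos, 1)
    val[abs(pos - c0) <= 300] <- val[abs(pos - c0) <= 300] + 2
    probes <- make_probes(pos, val)
    stats <- compute_array_stats(probes, pp_full)
    covered_by <- function(pk_small, pk_big) {
      all(vapply(seq_len(nrow(pk_small)), function(i)
        any(pk_big$start < pk_small$end[i] &
            pk_big$end > pk_small$start[i] &
            pk_big$score >= pk_small$score[i]), logical(1)))
    }
    pk_hi <- call_peaks(probes, stats, pp_hi)
    pk_full <- call_peaks(probes, stats, pp_full)
    pk_loose <- call_peaks(probes, stats, pp_loose)
    expect_true(covered_by(pk_hi, pk_full))
    expect_true(covered_by(pk_full, pk_loose))
  }
})

test_that("permutation FDR separates spiked signal from null arrays", {
  pp <- peak_params()
  # noiseless spike-in: background exactly 0, one plateau at +2
  pos <- seq(100, 20000, 100)
  val <- rep(0, length(pos))
  val[90:96] <- 2
  probes <- make_probes(pos, val)
  stats <- compute_array_stats(probes, pp)
  pk <- call_peaks(probes, stats, pp)
  expect_equal(nrow(pk), 1)
  pk <- permutation_fdr(probes, stats, pk, pp, seed = 99)
  expect_lte(pk$fdr, 0.05)

  # i.i.d. noise only: called peaks carry FDR near 1 on average (the
  # observed and permuted peak counts are comparable at every score)
  set.seed(7)
  pos_big <- seq(100, 100 * 3000, 100)
  pn <- make_probes(pos_big, rnorm(length(pos_big), 0, 0.3))
  sn <- compute_array_stats(pn, pp)
  pkn <- call_peaks(pn, sn, pp)
  pkn <- permutation_fdr(pn, sn, pkn, pp, seed = 99)
  expect_gt(nrow(pkn), 0)
  expect_gt(mean(pkn$fdr), 0.5)

  # zero observed peaks -> empty output, no division
  flat <- make_probes(pos, rep(0, length(pos)))
  sflat <- suppressWarnings(compute_array_stats(flat, pp))
  expect_equal(nrow(permutation_fdr(flat, sflat,
                                    call_peaks(flat, sflat, pp),
                                    pp, seed = 1)), 0)
})

test_that("FDR values are seed-reproducible and recomputable from the
           logged permutation scores", {
  pp <- peak_params(n_permutations = 10)
  set.seed(3)
  pos <- seq(100, 30000, 100)
  val <- rnorm(length(pos), 0, 0.3)
  val[100:106] <- val[100:106] + 2
  val[200:206] <- val[200:206] + 1.2
  probes <- make_probes(pos, val)
  stats <- compute_array_stats(probes, pp)
  pk0 <- call_peaks(probes, stats, pp)
  pk1 <- permutation_fdr(probes, stats, pk0, pp, seed = 123)
  pk2 <- permutation_fdr(probes, stats, pk0, pp, seed = 123)
  expect_identical(pk1$fdr, pk2$fdr)

  # independent recomputation of the tail-count ratio from the audit log
  perm <- attr(pk1, "permutation_scores")
  expect_length(perm, 10)
  for (s in unique(pk1$score)) {
    obs_ge <- sum(pk1$score >= s)
    perm_ge <- mean(vapply(perm, function(v) sum(v >= s), numeric(1)))
    raw <- min(1, perm_ge / max(1, obs_ge))
    # step-down: reported fdr at s is the min of raw ratios over scores <= s
    raws <- vapply(sort(unique(pk1$score[pk1$score <= s])), function(s2) {
      min(1, mean(vapply(perm, function(v) sum(v >= s2), numeric(1))) /
            max(1, sum(pk1$score >= s2)))
    }, numeric(1))
    expect_equal(unique(pk1$fdr[pk1$score == s]), min(raws))
    expect_lte(unique(pk1$fdr[pk1$score == s]), raw + 1e-12)
  }
  # monotone non-increasing in score
  ord <- order(pk1$score)
  expect_true(all(diff(pk1$fdr[ord]) <= 1e-12))
})

test_that("scree elbow maximizes chord distance with smaller-rank ties", {
  expect_error(scree_score_cutoff(c(2, 1)), "at least 3")
  expect_error(scree_score_cutoff(c(1, 3, 2)), "descending")

  # scores linear in rank: all distances 0, tie broken to the first index
  lin <- scree_score_cutoff(seq(10, 1, length.out = 10))
  expect_equal(lin$index, 1)

  # frozen from the brute-force distance formula below
  sc <- c(10, 9, 8, 1, 0.9, 0.8)
  got <- scree_score_cutoff(sc)
  n <- length(sc)
  d <- vapply(seq_len(n), function(i)
    abs((sc[n] - sc[1]) * (i - 1) - (n - 1) * (sc[i] - sc[1])) /
      sqrt((sc[n] - sc[1])^2 + (n - 1)^2), numeric(1))
  expect_equal(got$index, which.max(d))
  expect_equal(got$index, 4)  # the first rank past the cliff at rank 3
  expect_equal(got$threshold, 1)

  # appending points collinear with the tail keeps the chosen threshold
  ext <- scree_score_cutoff(c(sc, 0.7, 0.6))
  expect_equal(ext$threshold, got$threshold)
})

test_that("truly enriched promoters are detected at FDR 0.05 per array", {
  # amplitude 2.0, noise SD 0.3, 100 bp spacing, 600 bp plateau: at least
  # 95% of truly bound promoters yield a qualifying peak on one array
  cfg <- sim_config(n_genes = 100, seed = 61)
  genes <- generate_genome(cfg)
  tr <- assign_truth(cfg, genes)
  a <- generate_probe_arrays(cfg, genes, tr)[["r2_6h"]]
  pp <- peak_params()
  st <- compute_array_stats(a, pp)
  pk <- permutation_fdr(a, st, call_peaks(a, st, pp), pp, seed = 62)
  hits <- annotate_peaks(pk[pk$fdr <= 0.05, ], genes)$annotated$gene_id
  bound <- tr$enrich$gene_id[tr$enrich$replicate == 2 &
                             tr$enrich$time_label == "6h" &
                             tr$enrich$enriched]
  expect_gte(mean(bound %in% hits), 0.95)
})
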