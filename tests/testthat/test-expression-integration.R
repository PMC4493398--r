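expr_tbl <- function(rpkm_0h, rpkm_4h, rpkm_12h = rpkm_0h,
                     ids = seq_along(rpkm_0h)) {
  data.frame(gene_id = sprintf("g%03d", ids),
             refseq_id = sprintf("NM_%06d", ids),
             rpkm_0h = rpkm_0h, rpkm_4h = rpkm_4h, rpkm_12h = rpkm_12h,
             stringsAsFactors = FALSE)
}

test_that("fold changes and DE flags follow the 2-fold >= rule", {
  expect_error(compute_fold_changes(expr_tbl(10, 10), baseline = "2h"),
               "baseline")

  fc <- compute_fold_changes(expr_tbl(10, 10))
  expect_equal(fc$log2fc_4h, 0)
  expect_false(fc$de_4h)

  # exact 4-fold with vanishing pseudocount: log2fc = 2, DE
  fc4 <- compute_fold_changes(expr_tbl(10, 40), pseudocount = 1e-12)
  expect_equal(fc4$log2fc_4h, 2, tolerance = 1e-9)
  expect_true(fc4$de_4h)

  # boundary: 19.9 vs 10 with pseudocount 0.1 is just under 2-fold
  fcb <- compute_fold_changes(expr_tbl(10, 19.9), pseudocount = 0.1)
  expect_lt(abs(fcb$log2fc_4h), 1)
  expect_false(fcb$de_4h)
  # exactly 2-fold on the post-pseudocount scale is DE (>= applies)
  fce <- compute_fold_changes(expr_tbl(10, 20.1), pseudocount = 0.1)
  expect_equal(fce$log2fc_4h, 1)
  expect_true(fce$de_4h)

  # DE flag symmetric under reciprocal fold change
  up <- compute_fold_changes(expr_tbl(10, 43))
  dn <- compute_fold_changes(expr_tbl(43, 10))
  expect_equal(dn$log2fc_4h, -up$log2fc_4h)
  expect_equal(dn$de_4h, up$de_4h)

  # zero RPKM stays finite through the pseudocount
  fz <- compute_fold_changes(expr_tbl(0, 5))
  expect_true(is.finite(fz$log2fc_4h))
})

test_that("binding patterns join expression at the mapped follow-up times", {
  genes <- make_genes(tss = seq(10000, 10000 + 5 * 60000, 60000))
  genes$refseq_id <- sprintf("NM_%06d", 1:6)
  asg <- data.frame(
    gene_id = genes$gene_id[1:5],
    binary = c("010", "001", "100", "111", "011"),
    pattern_code = c(2L, 1L, 4L, 7L, 3L), stringsAsFactors = FALSE)
  # g001 (010): DE at 4h only -> counted for pattern 2
  # g002 (001): DE at 4h only, but pattern 1 is evaluated at 12h -> not DE
  # g003 (100): baseline-only, DE at 12h -> DE via both-follow-up rule
  # g004 (111): not DE anywhere
  # g005 (011): bound but missing from the expression table -> unmatched
  expr <- expr_tbl(rpkm_0h = c(10, 10, 10, 10),
                   rpkm_4h = c(40, 40, 10, 10),
                   rpkm_12h = c(10, 10, 40, 10), ids = 1:4)
  fc <- compute_fold_changes(expr)
  res <- integrate_expression(asg, fc, genes)

  s <- res$summary
  expect_equal(nrow(s), 7)  # Table-1 layout always has 7 rows
  expect_equal(s$n_de[s$pattern_code == 2], 1L)
  expect_equal(s$n_de[s$pattern_code == 1], 0L)
  expect_equal(s$n_de[s$pattern_code == 4], 1L)
  expect_match(s$note[s$pattern_code == 4], "baseline only")
  expect_equal(s$n_de[s$pattern_code == 7], 0L)
  # constitutive row reports bound-and-measured, not DE
  expect_equal(s$n_reported[s$pattern_code == 7], 1L)
  # join accounting: matched + unmatched = bound, per pattern
  expect_equal(s$n_matched + s$n_unmatched, s$n_bound)
  expect_equal(res$n_unmatched_total, 1L)
  expect_equal(s$n_unmatched[s$pattern_code == 3], 1L)

  # duplicate RefSeq ids on the expression side: first match, with warning
  expr_dup <- rbind(fc, fc[1, ])
  expect_warning(integrate_expression(asg, expr_dup, genes), "duplicate")
})

test_that("deterministic truth coupling reproduces per-pattern DE counts", {
  cfg <- sim_config(n_genes = 400, p_de_given_bound = 1,
                    p_de_given_unbound = 0, seed = 37)
  genes <- generate_genome(cfg)
  tr <- assign_truth(cfg, genes)
  expr <- generate_expression(cfg, genes, tr)
  fc <- compute_fold_changes(expr)

  # assignments straight from the truth patterns
  tt <- tr$truth[match(genes$gene_id, tr$truth$gene_id), ]
  calls <- t(vapply(tt$true_pattern, function(cd)
    c(bitwAnd(bitwShiftR(cd, 2), 1), bitwAnd(bitwShiftR(cd, 1), 1),
      bitwAnd(cd, 1)) == 1, logical(3)))
  dimnames(calls) <- list(genes$gene_id, c("0h", "1h", "6h"))
  asg <- assign_patterns(binding_matrix_from_calls(calls))$assignments
  res <- integrate_expression(asg, fc, genes)

  # expected: every matched gene of a pattern with a non-baseline bound bit
  # is DE (p_de_given_bound = 1, generated log2fc >= 1); baseline-only
  # pattern 4 genes are never DE (p_de_given_unbound = 0)
  s <- res$summary
  expect_equal(s$n_unmatched, rep(0L, 7))
  for (cd in c(1L, 2L, 3L, 5L, 6L, 7L))
    expect_equal(s$n_de[s$pattern_code == cd],
                 s$n_bound[s$pattern_code == cd])
  expect_equal(s$n_de[s$pattern_code == 4], 0L)
})

test_that("switch summaries report per-arm trajectories and contrasts", {
  genes <- make_genes(tss = seq(10000, 10000 + 3 * 60000, 60000))
  genes$refseq_id <- sprintf("NM_%06d", 1:4)
  asg <- data.frame(gene_id = genes$gene_id,
                    binary = c("011", "100", "010", "101"),
                    pattern_code = c(3L, 4L, 2L, 5L),
                    stringsAsFactors = FALSE)
  sw <- classify_switches(asg)
  # all fold changes zero: all means zero, contrast zero
  expr0 <- expr_tbl(rep(10, 4), rep(10, 4), rep(10, 4))
  res0 <- integrate_expression(asg, compute_fold_changes(expr0), genes)
  ss0 <- switch_expression_summary(res0$joined, sw)
  expect_true(all(ss0$by_arm$mean_log2fc == 0))
  expect_true(all(ss0$contrast$contrast == 0))

  # up-regulation coupled to the binding arms gives positive contrasts
  expr1 <- expr_tbl(rpkm_0h = rep(10, 4), rpkm_4h = c(80, 5, 80, 5),
                    rpkm_12h = c(80, 5, 80, 5))
  res1 <- integrate_expression(asg, compute_fold_changes(expr1), genes)
  ss1 <- switch_expression_summary(res1$joined, sw)
  expect_true(all(ss1$contrast$contrast > 0))

  # an empty arm is absent from the by-arm table, not reported as zero
  asg_b <- asg[asg$binary %in% c("011", "010"), ]
  sw_b <- classify_switches(asg_b)
  res_b <- integrate_expression(asg_b, compute_fold_changes(expr1), genes)
  ss_b <- switch_expression_summary(res_b$joined, sw_b)
  expect_false("unbinding" %in% ss_b$by_arm$arm)
  expect_true(all(is.na(ss_b$contrast$contrast)))
})

test_that("permuting arm labels nulls the binding contrast", {
  cfg <- sim_config(n_genes = 300, p_de_given_bound = 1,
                    p_de_given_unbound = 0, seed = 41)
  genes <- generate_genome(cfg)
  tr <- assign_truth(cfg, genes)
  fc <- compute_fold_changes(generate_expression(cfg, genes, tr))
  tt <- tr$truth[match(genes$gene_id, tr$truth$gene_id), ]
  calls <- t(vapply(tt$true_pattern, function(cd)
    c(bitwAnd(bitwShiftR(cd, 2), 1), bitwAnd(bitwShiftR(cd, 1), 1),
      bitwAnd(cd, 1)) == 1, logical(3)))
  dimnames(calls) <- list(genes$gene_id, c("0h", "1h", "6h"))
  asg <- assign_patterns(binding_matrix_from_calls(calls))$assignments
  sw <- classify_switches(asg)
  res <- integrate_expression(asg, fc, genes)

  obs <- switch_expression_summary(res$joined, sw)$contrast
  set.seed(11)
  perm_contr <- replicate(100, {
    sw_p <- sw
    sw_p$arm <- sample(sw_p$arm)
    mean(switch_expression_summary(res$joined, sw_p)$contrast$contrast,
         na.rm = TRUE)
  })
  se <- sd(perm_contr) / sqrt(length(perm_contr))
  expect_lt(abs(mean(perm_contr)), 2 * se + 0.05)
})
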