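test_that("Fisher enrichment handles the balanced, enriched and degenerate tables", {
  r0 <- coactivity:::fisher_enrichment_table(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$p, 1)
  r1 <- coactivity:::fisher_enrichment_table(rbind(c(20, 5), c(5, 20)))
  expect_equal(r1$odds_ratio, 16)
  expect_equal(r1$p, fisher_p_oracle(rbind(c(20, 5), c(5, 20))),
               tolerance = 1e-10)
  # zero cell: sample OR is infinite with a finite p
  rz <- coactivity:::fisher_enrichment_table(rbind(c(5, 3), c(0, 7)))
  expect_identical(rz$odds_ratio, Inf)
  expect_true(is.finite(rz$p) && rz$p <= 1)
  rh <- coactivity:::fisher_enrichment_table(rbind(c(5, 3), c(0, 7)),
                                             haldane = TRUE)
  expect_true(is.finite(rh$odds_ratio))
  # flag interface builds the same table
  fg <- rep(c(TRUE, FALSE), c(25, 25))
  feat <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 20))
  expect_equal(fisher_enrichment(fg, feat)$odds_ratio, 16)
  expect_error(fisher_enrichment(logical(0), logical(0)), "empty")
})

test_that("odds ratios transform correctly under table swaps", {
  tab <- rbind(c(12, 7), c(4, 19))
  or <- coactivity:::fisher_enrichment_table(tab)$odds_ratio
  both <- coactivity:::fisher_enrichment_table(tab[2:1, 2:1])$odds_ratio
  rows <- coactivity:::fisher_enrichment_table(tab[2:1, ])$odds_ratio
  cols <- coactivity:::fisher_enrichment_table(tab[, 2:1])$odds_ratio
  expect_equal(both, or)
  expect_equal(rows, 1 / or)
  expect_equal(cols, 1 / or)
})

test_that("TAD-boundary profiles localize and translate correctly", {
  dom <- data.frame(chrom = "chr1", start = c(1e6, 5e6), end = c(2e6, 6e6))
  tads <- data.frame(chrom = "chr1",
                     start = c(1e6, 2e6, 5e6, 6e6),
                     end = c(1e6, 2e6, 5e6, 6e6) + 1)
  prof <- tad_boundary_proximity(tads, dom)
  expect_equal(sum(prof$profile$n_boundaries), 4L)
  expect_true(all(abs(prof$profile$dist_bp[prof$profile$n_boundaries > 0]) <=
                    10000))
  expect_gt(prof$near_mean, prof$far_mean)
  # translation equivariance: shifting TAD boundaries moves the mode
  tads2 <- tads
  tads2$start <- tads2$start + 20000
  tads2$end <- tads2$end + 20000
  prof2 <- tad_boundary_proximity(tads2, dom)
  mode1 <- prof$profile$dist_bp[which.max(prof$profile$n_boundaries)]
  mode2 <- prof2$profile$dist_bp[which.max(prof2$profile$n_boundaries)]
  expect_equal(mode2 - mode1, 20000)
  # uniform scattering: near and far means agree within MC error
  set.seed(1)
  tads3 <- data.frame(chrom = "chr1", start = runif(4000, 0, 1e7))
  tads3$end <- tads3$start + 1
  prof3 <- tad_boundary_proximity(tads3, dom)
  expect_lt(abs(prof3$near_mean / prof3$far_mean - 1), 0.35)
})

test_that("compartment coverage fractions are exact and validated", {
  dom <- data.frame(chrom = "chr1", start = 0, end = 100000,
                    label = "coactivity")
  comp_full <- data.frame(chrom = "chr1", start = 0, end = 200000,
                          class = "active")
  cc <- compartment_coverage(dom, comp_full)
  expect_equal(cc$active, 1)
  expect_equal(cc$uncovered, 0)
  comp_half <- data.frame(chrom = "chr1", start = c(0, 50000),
                          end = c(50000, 100000),
                          class = c("active", "facultative"))
  cc2 <- compartment_coverage(dom, comp_half)
  expect_equal(cc2$active, 0.5)
  expect_equal(cc2$facultative, 0.5)
  overlapping <- data.frame(chrom = "chr1", start = c(0, 40000),
                            end = c(50000, 90000), class = c("active", "active"))
  expect_error(compartment_coverage(dom, overlapping), "overlapping")
})

test_that("co-expression tiles mask sparse cells and flag duplicated profiles", {
  set.seed(2)
  n <- 20
  expr <- matrix(rexp(n * 4, 1 / 5), n, 4,
                 dimnames = list(NULL, paste0("g", 1:4)))
  expr[, 2] <- expr[, 1]          # duplicated pair: PCC exactly 1
  gm <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                   tss = c(1, 2, 3, 4) * 10000L)
  scores <- setNames(c(1.5, 1.5, -0.5, -0.5), paste0("g", 1:4))
  cs <- coexpression_stratified(expr, gm, scores, min_pairs = 1L)
  p12 <- cs$pairs[cs$pairs$gene_up == "g1", ]
  expect_equal(p12$pcc, 1, tolerance = 1e-12)
  # with the default 10-pair minimum every tile here is masked
  cs2 <- coexpression_stratified(expr, gm, scores)
  expect_true(all(is.na(cs2$tiles$mean_pcc)))
  expect_error(coexpression_stratified(expr[1:2, ], gm, scores), "3 individuals")
})

test_that("per-bin histone correlations agree with a two-pass reference", {
  set.seed(3)
  n <- 15; B <- 12
  bins <- data.frame(chrom = "chr1", start = (0:(B - 1)) * 10000L,
                     end = (1:B) * 10000L)
  scores <- matrix(rnorm(n * B), n, B)
  hist_sig <- 2 * scores + 1            # affine: correlation exactly 1
  dom <- data.frame(chrom = "chr1", start = 0, end = 60000,
                    label = "coactivity")
  hc <- histone_coactivity_correlation(scores, hist_sig, bins, dom)
  expect_equal(hc$per_bin$r, rep(1, B), tolerance = 1e-12)
  expect_equal(hc$per_domain$r, 1, tolerance = 1e-12)
  # independent noise: reference agreement to 1e-12
  hist2 <- matrix(rnorm(n * B), n, B)
  hc2 <- histone_coactivity_correlation(scores, hist2, bins, dom)
  ref <- vapply(seq_len(B), function(b) two_pass_cor(scores[, b], hist2[, b]),
                numeric(1))
  expect_equal(hc2$per_bin$r, ref, tolerance = 1e-12)
  # zero-variance signal: missing record, excluded from class summaries
  hist3 <- hist2; hist3[, 1] <- 3
  hc3 <- histone_coactivity_correlation(scores, hist3, bins, dom)
  expect_true(is.na(hc3$per_bin$r[1]))
  expect_false(any(is.na(hc3$by_class$mean_r)))
})

test_that("ABC summaries expose planted monotone structure", {
  n <- 25
  set.seed(4)
  gm <- data.frame(gene_id = paste0("g", 1:6), chrom = "chr1",
                   tss = (1:6) * 50000L, mean_tpm = 5)
  dom <- data.frame(chrom = "chr1", start = 0, end = 160000,
                    label = "variable")
  expr <- sapply(1:6, function(g) g * 10 + runif(n))
  colnames(expr) <- gm$gene_id
  abc <- round(expr * 2)
  colnames(abc) <- gm$gene_id
  s <- abc_summaries(abc, expr, gm, dom)
  expect_true(all(s$per_gene$paired_r > 0))
  expect_equal(unname(s$spearman["median_expr", "median_count"]), 1)
  # constant counts: zero CoV
  abc2 <- abc; abc2[, 1] <- 7
  s2 <- abc_summaries(abc2, expr, gm, dom)
  expect_equal(s2$per_gene$cov_count[1], 0)
  # a gene missing from expression is dropped with a message
  expect_message(abc_summaries(cbind(abc, gX = 1L), expr, gm, dom), "dropping")
})

test_that("promoter windows respect strand", {
  gm <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                   tss = c(10000L, 50000L), strand = c("+", "-"))
  pw <- promoter_windows(gm)
  expect_equal(pw$start[pw$name == "plus"], 8000L)
  expect_equal(pw$end[pw$name == "plus"], 10200L)
  # minus strand: 2 kb upstream extends to larger coordinates
  expect_equal(pw$start[pw$name == "minus"], 49800L)
  expect_equal(pw$end[pw$name == "minus"], 52000L)
})

test_that("TF variability relations detect planted OR-CoV coupling", {
  set.seed(5)
  n <- 60; p <- 20
  sds <- runif(p, 0.2, 1.2)
  tfx <- sapply(sds, function(s) rnorm(n, 0, s))
  colnames(tfx) <- sprintf("TF%02d", 1:p)
  or_tab <- data.frame(tf = colnames(tfx),
                       odds_ratio = exp(1.5 * sds + rnorm(p, 0, 0.2)))
  expr <- matrix(rexp(n * 4, 1 / 5), n, 4,
                 dimnames = list(NULL, paste0("g", 1:4)))
  targets <- setNames(rep(list(c("g1", "g2")), p), colnames(tfx))
  tv <- tf_variability_relations(or_tab, tfx, expr, targets)
  expect_gt(tv$or_cov_test$pcc, 0)
  expect_lt(tv$or_cov_test$p, 0.05)
  expect_false(any(is.na(tv$per_tf$mean_target_cov)))
  # degenerate: identical TFs give an undefined correlation
  tf_same <- matrix(rnorm(n), n, 3,
                    dimnames = list(NULL, c("A", "B", "C")))
  tf_same[, 2] <- tf_same[, 1]; tf_same[, 3] <- tf_same[, 1]
  or_same <- data.frame(tf = c("A", "B", "C"), odds_ratio = 2)
  tv0 <- tf_variability_relations(or_same, tf_same, expr,
                                  setNames(rep(list("g1"), 3), c("A", "B", "C")))
  expect_true(is.na(tv0$or_cov_test$pcc))
  # bound-versus-unbound contrast has the planted direction
  D <- 30
  binding <- matrix(runif(p * D) < 0.5, p, D,
                    dimnames = list(colnames(tfx), paste0("d", 1:D)))
  dscores <- matrix(rnorm(D * n, 0, 0.3), D, n)
  for (d in seq_len(D)) {
    bound <- which(binding[, d])
    if (length(bound))
      dscores[d, ] <- dscores[d, ] + 0.8 * rowMeans(tfx[, bound, drop = FALSE])
  }
  tv2 <- tf_variability_relations(or_tab, tfx, expr, targets,
                                  domain_scores = dscores,
                                  tf_domain_binding = binding)
  expect_gt(mean(tv2$bound_contrast$mean_pcc_bound -
                   tv2$bound_contrast$mean_pcc_unbound), 0)
})
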