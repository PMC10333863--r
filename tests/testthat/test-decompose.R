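make_counts <- function(m, bin_size = 10000L, chrom = "chr1", libs = NULL) {
  B <- ncol(m)
  bins <- data.frame(chrom = chrom, start = (seq_len(B) - 1L) * bin_size,
                     end = seq_len(B) * bin_size)
  rownames(m) <- sprintf("i%02d", seq_len(nrow(m)))
  binned_counts(m, bins, libs)
}

test_that("library QC excludes empty-bin outliers two-sided", {
  # identical libraries: zero SD, exclude none
  m <- matrix(5, 10, 50)
  qc <- qc_filter_libraries(make_counts(m))
  expect_equal(nrow(qc$excluded), 0L)
  expect_equal(nrow(qc$counts$counts), 10L)
  # nine libraries with 10 empty bins, one with 200: the outlier goes
  m <- matrix(5, 10, 400)
  for (j in 1:9) m[j, 1:10] <- 0
  m[10, 1:200] <- 0
  qc <- qc_filter_libraries(make_counts(m))
  expect_equal(qc$excluded$individual, "i10")
  expect_equal(qc$excluded$empty_bins, 200)
  # hand-worked case: tallies {0,0,0,0,0,50}; mean 8.333, sd 20.412,
  # mean + 2 sd = 49.16 < 50, so library 6 is excluded
  m <- matrix(3, 6, 60)
  m[6, 1:50] <- 0
  qc <- qc_filter_libraries(make_counts(m))
  expect_equal(qc$excluded$individual, "i06")
  expect_equal(qc$mean_empty, 50 / 6, tolerance = 1e-12)
  expect_equal(qc$sd_empty, sqrt(sum((c(0, 0, 0, 0, 0, 50) - 50 / 6)^2) / 5),
               tolerance = 1e-12)
  expect_error(qc_filter_libraries(make_counts(m[1:2, ])), "3 individuals")
})

test_that("VDJ bin masking respects half-open gene intervals", {
  bins <- data.frame(chrom = "chr1", start = (0:9) * 10000L, end = (1:10) * 10000L)
  gm <- data.frame(gene_id = c("gene1", "IGH_x"), chrom = "chr1",
                   start = c(5000L, 45000L), end = c(12000L, 71000L),
                   ig = c(FALSE, TRUE))
  expect_identical(mask_vdj_bins(bins, gm), c(5L, 6L, 7L, 8L))
  # no flagged genes: empty set
  expect_identical(mask_vdj_bins(bins, gm[1, , drop = FALSE]), integer(0))
  # gene ending exactly on a bin boundary: the boundary bin is excluded
  gm$end[2] <- 70000L
  expect_identical(mask_vdj_bins(bins, gm), c(5L, 6L, 7L))
  # naming convention fallback
  gm2 <- gm[, setdiff(names(gm), "ig")]
  expect_identical(mask_vdj_bins(bins, gm2), c(5L, 6L, 7L))
})

test_that("segment planning removes the two longest zero runs and splits greedily", {
  m <- matrix(2, 3, 200)
  m[, 51:80] <- 0    # 30-bin zero run
  m[, 121:140] <- 0  # 20-bin zero run
  m[, 181:183] <- 0  # 3-bin zero run (stays)
  plan <- plan_segments(make_counts(m))
  expect_equal(nrow(plan$removed_gaps), 2L)
  expect_equal(plan$removed_gaps$first_bin, c(51L, 121L))
  expect_equal(plan$removed_gaps$last_bin, c(80L, 140L))
  expect_equal(plan$segments$first_bin, c(1L, 81L, 141L))
  expect_equal(plan$segments$last_bin, c(50L, 120L, 200L))
  # hard splits at the maximum when no zero run is available
  m2 <- matrix(1, 2, 20)
  plan2 <- plan_segments(make_counts(m2), max_segment_bins = 8L)
  expect_true(all(plan2$segments$last_bin - plan2$segments$first_bin + 1L <= 8L))
  expect_equal(plan2$segments$first_bin, c(1L, 9L, 17L))
  # a surviving zero bin in the last 10% of a piece is preferred as the cut
  # point over the hard split (two longer zero runs are removed first)
  m3 <- matrix(1, 2, 40)
  m3[, c(3:5, 10:12, 31)] <- 0
  plan3 <- plan_segments(make_counts(m3), max_segment_bins = 20L)
  expect_equal(plan3$removed_gaps$first_bin, c(3L, 10L))
  expect_equal(plan3$segments$first_bin, c(1L, 6L, 13L, 32L))
  expect_equal(plan3$segments$last_bin, c(2L, 9L, 31L, 40L))
  # all-zero chromosome: zero segments with a warning
  expect_warning(p0 <- plan_segments(make_counts(matrix(0, 3, 30),
                                                 libs = rep(1, 3))),
                 "no informative bins")
  expect_equal(nrow(p0$segments), 0L)
})

test_that("constant counts collapse to the intercept with flat latents", {
  m <- matrix(50, 4, 30)
  bc <- make_counts(m, libs = rep(2, 4))
  fit <- fit_decomposition(bc, hyper = model_hyperparams(theta_init = 10))
  expect_lt(max(abs(fit$pd_mean)), 1e-6)
  expect_lt(max(abs(fit$pi_mean)), 1e-6)
  expect_equal(unname(fit$alpha[, 1]), rep(log(50 / 2), 4), tolerance = 1e-8)
  expect_true(all(fit$convergence$converged))
  expect_true(all(fit$pd_var >= 0) && all(fit$pi_var >= 0))
})

test_that("all-zero segments hit the intercept floor with flat latents", {
  m <- matrix(5, 3, 20)
  m[1, ] <- 0           # individual 1 is all-zero
  bc <- make_counts(m, libs = c(1, 1, 1))
  fit <- suppressWarnings(
    fit_decomposition(bc, hyper = model_hyperparams(theta_init = 10)))
  expect_equal(unname(fit$alpha[1, 1]), -30)
  expect_true(all(fit$pd_mean[1, ] == 0))
  expect_true(is.finite(fit$alpha[1, 1]))
})

test_that("doubling library sizes shifts alpha by -log 2 and leaves PD fixed", {
  set.seed(4)
  m <- matrix(rnbinom(3 * 60, mu = 40, size = 10), 3, 60)
  f1 <- fit_decomposition(make_counts(m, libs = rep(5, 3)),
                          hyper = model_hyperparams(theta_init = 10,
                                                    variances = "none"))
  f2 <- fit_decomposition(make_counts(m, libs = rep(10, 3)),
                          hyper = model_hyperparams(theta_init = 10,
                                                    variances = "none"))
  expect_equal(f2$alpha, f1$alpha - log(2), tolerance = 1e-6)
  expect_equal(f2$pd_mean, f1$pd_mean, tolerance = 1e-6)
})

test_that("MAP solution matches a generic constrained optimizer", {
  set.seed(7)
  hyper <- model_hyperparams(theta_init = 8, variances = "none")
  y <- rnbinom(30, mu = exp(1 + cumsum(rnorm(30, 0, 0.15))), size = 8)
  map <- coactivity:::fit_segment_map(y, s = 3, theta = 8, hyper)
  orc <- oracle_segment_map(y, s = 3, theta = 8, hyper$tau_pd, hyper$tau_pi,
                            start = c(map$pd[-30], map$pi, map$alpha) +
                              rnorm(60, 0, 0.05))
  expect_lt(max(abs(c(map$pd - orc$pd, map$pi - orc$pi, map$alpha - orc$alpha))),
            1e-6)
  # objective is non-decreasing over accepted Newton steps
  expect_true(all(diff(map$obj_trace) >= -1e-9))
  # sum-to-zero constraint
  expect_lt(abs(mean(map$pd)), 10 * hyper$tol)
})

test_that("posterior variances are non-negative and sampling agrees with analytic", {
  set.seed(8)
  y <- rnbinom(25, mu = 30, size = 10)
  h1 <- model_hyperparams(theta_init = 10)
  f1 <- coactivity:::fit_segment_map(y, s = 2, theta = 10, h1)
  expect_true(all(f1$pd_var >= 0) && all(f1$pi_var >= 0))
  h2 <- model_hyperparams(theta_init = 10, laplace_samples = 4000L)
  set.seed(9)
  f2 <- coactivity:::fit_segment_map(y, s = 2, theta = 10, h2)
  expect_equal(f2$pd_var, f1$pd_var, tolerance = 0.15)
})

test_that("the smooth component separates from the independent one on simulated data", {
  sim <- small_sim()
  fit <- small_fit()
  sc <- coactivity_matrix(fit)
  a_pd <- mean(apply(sc, 1, coactivity:::lag1_autocor), na.rm = TRUE)
  a_pi <- mean(apply(fit$pi_mean, 1, coactivity:::lag1_autocor), na.rm = TRUE)
  expect_gte(a_pd - a_pi, 0.3)
  # recovery of the true field
  truth <- sim$truth$pd_true[rownames(sc), , drop = FALSE]
  cors <- vapply(seq_len(nrow(sc)), function(j) {
    ok <- is.finite(sc[j, ])
    cor(sc[j, ok], truth[j, ok])
  }, numeric(1))
  expect_gte(median(cors), 0.9)
  # per-segment means satisfy the identifiability constraint
  segs <- fit$plan$segments
  for (g in seq_len(nrow(segs))) {
    idx <- segs$first_bin[g]:segs$last_bin[g]
    expect_lt(max(abs(rowMeans(fit$pd_mean[, idx]))), 1e-6)
  }
})

test_that("coactivity_matrix reports excluded bins as missing and is stable", {
  fit <- small_fit()
  fit2 <- fit
  fit2$excluded_bins <- c(3L, 7L)
  m <- coactivity_matrix(fit2)
  expect_true(all(is.na(m[, c(3L, 7L)])))
  expect_false(any(m[, c(3L, 7L)] %in% 0))
  expect_identical(coactivity_matrix(fit2), m)
})

test_that("theta profiling recovers the simulated overdispersion scale", {
  set.seed(10)
  mu_field <- exp(1.5 + cumsum(rnorm(300, 0, 0.05)))
  m <- t(sapply(1:4, function(j) rnbinom(300, mu = 3 * mu_field, size = 20)))
  bc <- make_counts(m, libs = rep(3, 4))
  fit <- fit_decomposition(bc, hyper = model_hyperparams(
    theta_init = 5, theta_mode = "estimated", variances = "none"))
  expect_true(all(fit$theta > 8) && all(fit$theta < 80))
})

test_that("model object methods are coherent", {
  fit <- small_fit()
  expect_output(print(fit), "decomposition fit")
  s <- summary(fit)
  expect_output(print(s), "pairwise PCC")
  expect_gt(s$mean_pairwise_pcc_pd, s$mean_pairwise_pcc_pi)
  expect_named(coef(fit), c("alpha", "theta"))
  r <- residuals(fit)
  expect_equal(dim(r), dim(fit$pd_mean))
  y_rep <- simulate(fit, nsim = 1, seed = 1)[[1]]
  expect_equal(dim(y_rep), dim(fit$counts))
  expect_true(cor(as.vector(y_rep), as.vector(fit$counts)) > 0.9)
})
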