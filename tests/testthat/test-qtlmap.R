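make_geno <- function(n, p, maf = 0.3, chrom = "chr1", pos = NULL, seed = 1) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p, 2L, maf), n, p,
                dimnames = list(sprintf("i%03d", 1:n), sprintf("s%03d", 1:p)))
  list(dosages = dos,
       snp_table = data.frame(id = colnames(dos), chrom = chrom,
                              pos = pos %||% (seq_len(p) * 1000L),
                              maf = maf))
}

test_that("the R2-from-t formula matches partial R2 from OLS refits", {
  set.seed(2)
  for (rep in 1:10) {
    n <- 40
    g <- make_geno(n, 1, seed = rep)
    covars <- matrix(rnorm(n * 3), n, 3)
    y <- matrix(0.3 * g$dosages[, 1] + covars %*% rnorm(3) + rnorm(n),
                ncol = 1, dimnames = list(rownames(g$dosages), "t1"))
    q <- map_qtl(g, y, data.frame(target_id = "t1", chrom = "chr1", pos = 1000L),
                 covariates = covars, maf_min = 0.01)
    # identity r2 = (t / sqrt(df + t^2))^2 holds exactly for the records
    expect_lt(max(abs(q$r2 - (q$t_stat / sqrt(q$df + q$t_stat^2))^2)), 1e-12)
    # oracle: partial R2 from explicit reduced/full OLS fits
    full <- lm(y ~ g$dosages[, 1] + covars)
    red <- lm(y ~ covars)
    pr2 <- (sum(residuals(red)^2) - sum(residuals(full)^2)) / sum(residuals(red)^2)
    expect_lt(abs(q$r2 - pr2), 1e-10)
    expect_equal(q$df, full$df.residual)
    # with no covariates the partial R2 equals the plain R2 change
    q0 <- map_qtl(g, y, data.frame(target_id = "t1", chrom = "chr1", pos = 1000L),
                  n_geno_pcs = 0L, n_pheno_pcs = 0L, maf_min = 0.01)
    f0 <- lm(y ~ g$dosages[, 1])
    expect_lt(abs(q0$r2 - summary(f0)$r.squared), 1e-10)
  }
})

test_that("perfect-fit pairs report r2 of 1 with a minimal positive p", {
  n <- 30
  g <- make_geno(n, 1)
  y <- matrix(0.5 * g$dosages[, 1], ncol = 1,
              dimnames = list(rownames(g$dosages), "t1"))
  q <- map_qtl(g, y, data.frame(target_id = "t1", chrom = "chr1", pos = 1000L),
               n_geno_pcs = 0L, n_pheno_pcs = 0L)
  expect_equal(q$r2, 1)
  expect_gt(q$p, 0)
  expect_lte(q$p, 1e-30)
})

test_that("MAF filtering, missing SNPs and constant dosages are handled", {
  n <- 50
  g <- make_geno(n, 4)
  g$dosages[, 2] <- 0                        # constant: skipped with a log
  g$dosages[1, 3] <- NA                      # missing: dropped by the filter
  g$dosages[, 4] <- rbinom(n, 2, 0.03)       # below the MAF cutoff
  y <- matrix(rnorm(n), ncol = 1, dimnames = list(rownames(g$dosages), "t1"))
  q <- map_qtl(g, y, data.frame(target_id = "t1", chrom = "chr1", pos = 1L),
               n_geno_pcs = 0L, n_pheno_pcs = 0L)
  expect_equal(q$snp_id, "s001")
  # rank-deficient covariates are rejected
  bad <- cbind(1, matrix(1, n, 1))
  expect_error(map_qtl(g, y, data.frame(target_id = "t1", chrom = "chr1",
                                        pos = 1L), covariates = bad),
               "rank-deficient")
})

test_that("BH q values are monotone in p and never smaller than p", {
  set.seed(3)
  n <- 60
  g <- make_geno(n, 12, pos = rep(1000L, 12))
  y <- matrix(rnorm(2 * n), n, 2,
              dimnames = list(rownames(g$dosages), c("t1", "t2")))
  q <- map_qtl(g, y, data.frame(target_id = c("t1", "t2"), chrom = "chr1",
                                pos = c(500L, 1500L)),
               n_geno_pcs = 0L, n_pheno_pcs = 0L)
  expect_true(all(q$q_bh >= q$p - 1e-15))
  o <- order(q$p)
  expect_true(all(diff(q$q_bh[o]) >= -1e-12))
})

test_that("LD pruning equals the brute-force reference on random LD blocks", {
  set.seed(4)
  n <- 80
  # three LD blocks via allele copying
  base <- matrix(rbinom(n * 4, 2L, 0.4), n, 4)
  dos <- matrix(0L, n, 20)
  for (s in 1:20) {
    b <- base[, (s - 1) %/% 5 %% 4 + 1]
    flip <- runif(n) < 0.15
    dos[, s] <- ifelse(flip, rbinom(n, 2L, 0.4), b)
  }
  dimnames(dos) <- list(sprintf("i%03d", 1:n), sprintf("s%03d", 1:20))
  g <- list(dosages = dos,
            snp_table = data.frame(id = colnames(dos), chrom = "chr1",
                                   pos = 1:20 * 100L))
  y <- matrix(0.4 * dos[, 3] + rnorm(n), ncol = 1,
              dimnames = list(rownames(dos), "t1"))
  q <- map_qtl(g, y, data.frame(target_id = "t1", chrom = "chr1", pos = 1000L),
               n_geno_pcs = 0L, n_pheno_pcs = 0L)
  pruned <- ld_prune(q, g)
  expect_identical(sort(pruned$snp_id), sort(brute_ld_prune(q, dos)))
  # retained set is pairwise below the threshold
  if (nrow(pruned) > 1L) {
    cc <- abs(cor(dos[, pruned$snp_id]))
    expect_true(all(cc[upper.tri(cc)] <= 0.8))
  }
  # two perfectly correlated SNPs: only the more significant survives
  g2 <- make_geno(50, 2, pos = c(100L, 200L))
  g2$dosages[, 2] <- g2$dosages[, 1]
  y2 <- matrix(g2$dosages[, 1] + rnorm(50, 0, 2), ncol = 1,
               dimnames = list(rownames(g2$dosages), "t1"))
  q2 <- map_qtl(g2, y2, data.frame(target_id = "t1", chrom = "chr1", pos = 1L),
                n_geno_pcs = 0L, n_pheno_pcs = 0L)
  expect_equal(nrow(ld_prune(q2, g2)), 1L)
  expect_equal(ld_prune(q2, g2)$snp_id, q2$snp_id[which.min(q2$p)])
  # pairwise-independent SNPs: all retained
  g3 <- make_geno(200, 5, pos = 1:5 * 100L, seed = 9)
  y3 <- matrix(rnorm(200), ncol = 1, dimnames = list(rownames(g3$dosages), "t1"))
  q3 <- map_qtl(g3, y3, data.frame(target_id = "t1", chrom = "chr1", pos = 1L),
                n_geno_pcs = 0L, n_pheno_pcs = 0L)
  expect_equal(nrow(ld_prune(q3, g3)), 5L)
})

test_that("QSS matches hand-worked examples and its limits", {
  g <- list(dosages = matrix(c(2L, 1L, 0L, 0L, 2L, 2L), 3, 2,
                             dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  q <- data.frame(snp_id = c("s1", "s2"), target_id = "d1",
                  beta = c(0.5, -0.25))
  qss <- compute_qss(q, g)
  # individual a: polarized genotypes {2, 2-0=2}, weights {0.5, 0.25}
  expect_equal(unname(qss$values["a"]), (0.5 * 2 + 0.25 * 2) / 0.75)
  expect_equal(unname(qss$values["a"]), 2)
  # single positive QTL with genotype 1
  q1 <- data.frame(snp_id = "s1", target_id = "d1", beta = 0.4)
  expect_equal(unname(compute_qss(q1, g)$values["b"]), 1)
  # all-risk-homozygous individuals score exactly 2; all-zero score 0
  gg <- list(dosages = matrix(c(2L, 0L, 0L, 2L), 2, 2,
                              dimnames = list(c("hi", "lo"), c("s1", "s2"))))
  qq <- data.frame(snp_id = c("s1", "s2"), target_id = "d",
                   beta = c(0.7, -0.3))
  v <- compute_qss(qq, gg)$values
  expect_identical(unname(v["hi"]), 2)
  expect_identical(unname(v["lo"]), 0)
  expect_error(compute_qss(data.frame(snp_id = "s1", beta = 0), g), "zero")
  expect_error(compute_qss(q[0, ], g), "at least one")
})

test_that("eGene sharing summaries and the exact test follow the pair structure", {
  gm <- data.frame(gene_id = paste0("g", 1:6), chrom = "chr1",
                   tss = c(10, 20, 30, 40, 50, 60) * 1000L, mean_tpm = 5)
  # genes 1-3 inside a domain share snpA; genes 4-6 outside have private QTLs
  qtls <- data.frame(
    snp_id = c("snpA", "snpA", "snpA", "snpB", "snpC", "snpD"),
    target_id = paste0("g", 1:6), target_kind = "gene",
    beta = 1, t_stat = 5, df = 10, p = 1e-4, q_bh = 1e-3, r2 = 0.5)
  class(qtls) <- c("qtl_table", "data.frame")
  dom <- data.frame(chrom = "chr1", start = 0, end = 35000,
                    label = "coactivity")
  sh <- eqtl_sharing(qtls, gm, list(coactivity = dom))
  expect_equal(nrow(sh$pairs), 5L)
  in_dom <- sh$by_label[sh$by_label$label == "coactivity", ]
  out <- sh$by_label[sh$by_label$label == "outside", ]
  expect_equal(in_dom$sharing_pct, 100)   # pairs (g1,g2), (g2,g3)
  expect_equal(out$sharing_pct, 0)
  expect_true(sh$fisher$odds_ratio > 1 || is.infinite(sh$fisher$odds_ratio))
  # distance bins partition all pairs
  expect_equal(sum(sh$distance_bins$n_pairs), nrow(sh$pairs))
  # fewer than two eGenes: empty outputs
  sh0 <- eqtl_sharing(qtls[1, ], gm, list(coactivity = dom))
  expect_equal(nrow(sh0$pairs), 0L)
})

test_that("Fisher sharing test agrees with hypergeometric enumeration", {
  tab <- rbind(c(30, 70), c(7, 93))
  res <- coactivity:::fisher_enrichment_table(tab)
  expect_equal(res$p, fisher_p_oracle(tab), tolerance = 1e-10)
  expect_equal(res$odds_ratio, (30 * 93) / (70 * 7))
})

test_that("per-domain explained-variance summaries detect planted differences", {
  mk_q <- function(ids, r2, beta) {
    q <- data.frame(snp_id = paste0("s", seq_along(r2)),
                    target_id = ids, target_kind = "domain",
                    beta = beta, t_stat = 3, df = 20, p = 0.001,
                    q_bh = 0.01, r2 = r2)
    class(q) <- c("qtl_table", "data.frame")
    q
  }
  set.seed(5)
  qa <- mk_q(rep(paste0("v", 1:10), each = 2), runif(20, 0.3, 0.6),
             rnorm(20, 0, 1))
  qb <- mk_q(rep(paste0("m", 1:10), each = 2), runif(20, 0.05, 0.15),
             rnorm(20, 0, 0.2))
  s <- variance_explained_summary(qa, qb)
  expect_true(all(s$per_domain$max_r2 >= 0 & s$per_domain$max_r2 <= 1))
  r2row <- s$tests[s$tests$quantity == "max_r2", ]
  expect_gt(r2row$median_a, r2row$median_b)
  expect_lt(r2row$p, 0.01)
})

test_that("null associations attain nominal type-I error", {
  set.seed(6)
  n <- 200; m <- 400
  dos <- matrix(rbinom(n * m, 2L, 0.3), n, m,
                dimnames = list(sprintf("i%03d", 1:n), sprintf("s%04d", 1:m)))
  g <- list(dosages = dos,
            snp_table = data.frame(id = colnames(dos), chrom = "chr1",
                                   pos = seq_len(m) * 1e7))
  y <- matrix(rnorm(n * m), n, m,
              dimnames = list(rownames(dos), paste0("t", 1:m)))
  tp <- data.frame(target_id = colnames(y), chrom = "chr1",
                   pos = seq_len(m) * 1e7)
  q <- map_qtl(g, y, tp, cis_window_bp = 1e6,
               n_geno_pcs = 0L, n_pheno_pcs = 0L)
  expect_equal(nrow(q), m)  # each target paired with exactly its own SNP
  rate <- mean(q$p < 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(rate - 0.05), ci + 0.01)
})
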