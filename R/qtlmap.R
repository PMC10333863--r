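#' Map cis QTLs by ordinary least squares with PC covariates
#'
#' For every SNP-target pair within `cis_window_bp` of the target anchor,
#' fits OLS of the target on the dosage plus covariates and records the
#' effect size, t statistic, degrees of freedom `n - (#covariates + 2)`,
#' two-sided p value, Benjamini-Hochberg q (within `target_kind`), and the
#' proportion of variance explained
#' \deqn{R^2 = (t / sqrt(df + t^2))^2.}
#' SNPs are filtered to non-missing dosages with minor allele frequency above
#' `maf_min`. When `covariates` is NULL, the configured numbers of genotype
#' and phenotype principal components are computed internally on the centered
#' matrices.
#'
#' @param genotypes list with `dosages` (individuals x SNPs) and `snp_table`
#'   (`id`, `chrom`, `pos`), as from [read_genotypes()].
#' @param targets numeric matrix, individuals x targets (genes or domains).
#' @param target_positions data.frame `target_id`, `chrom`, `pos` (anchor:
#'   TSS for genes, midpoint for domains).
#' @param target_kind `"gene"` or `"domain"`.
#' @param covariates optional numeric covariate matrix (individuals x p).
#' @param cis_window_bp half-width of the cis window around the anchor
#'   (default 1 Mb).
#' @param maf_min minor allele frequency filter (strict, default 0.1).
#' @param n_geno_pcs,n_pheno_pcs principal components used as covariates when
#'   `covariates` is NULL (defaults 3 and 15, capped at what the data allow).
#' @return a `qtl_table` data.frame: `snp_id`, `target_id`, `target_kind`,
#'   `beta`, `t_stat`, `df`, `p`, `q_bh`, `r2`. Pairs skipped for constant
#'   dosage are listed in the `"skipped"` attribute.
#' @export
map_qtl <- function(genotypes, targets, target_positions,
                    target_kind = c("gene", "domain"), covariates = NULL,
                    cis_window_bp = 1e6, maf_min = 0.1,
                    n_geno_pcs = 3L, n_pheno_pcs = 15L) {
  target_kind <- match.arg(target_kind)
  dos <- genotypes$dosages
  snps <- genotypes$snp_table
  n <- nrow(dos)
  if (nrow(targets) != n) stop_ca("genotypes and targets must share individuals")
  # MAF filter on non-missing SNPs
  ok_snp <- colSums(is.na(dos)) == 0
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af, na.rm = TRUE)
  ok_snp <- ok_snp & !is.na(maf) & maf > maf_min
  dos <- dos[, ok_snp, drop = FALSE]
  snps <- snps[ok_snp, , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- cbind(
      pcs_of(dos, min(n_geno_pcs, n - 2L, ncol(dos)), "geno_pc"),
      pcs_of(targets, min(n_pheno_pcs, n - 2L, ncol(targets)), "pheno_pc"))
  }
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X0)$rank < ncol(X0)) stop_ca("rank-deficient covariate matrix")
  q0 <- qr(X0)
  ry <- qr.resid(q0, targets)
  rg <- qr.resid(q0, dos)
  df <- n - (ncol(X0) - 1L + 2L)
  if (df <= 0) stop_ca("not enough individuals for the covariate set")
  rows <- list(); skipped <- list()
  ss_g_all <- colSums(rg^2)
  for (t_i in seq_len(ncol(targets))) {
    tp <- target_positions[target_positions$target_id == colnames(targets)[t_i], ]
    if (nrow(tp) == 0L) next
    cis <- which(snps$chrom == tp$chrom[1] & abs(snps$pos - tp$pos[1]) <= cis_window_bp)
    if (!length(cis)) next
    const <- ss_g_all[cis] < 1e-12
    if (any(const))
      skipped[[length(skipped) + 1L]] <- data.frame(
        snp_id = snps$id[cis[const]], target_id = colnames(targets)[t_i],
        reason = "constant dosage")
    cis <- cis[!const]
    if (!length(cis)) next
    y <- ry[, t_i]
    g <- rg[, cis, drop = FALSE]
    ss_g <- ss_g_all[cis]
    beta <- as.vector(crossprod(g, y)) / ss_g
    rss <- sum(y^2) - beta^2 * ss_g
    rss <- pmax(rss, 0)
    sigma2 <- rss / df
    se <- sqrt(sigma2 / ss_g)
    t_stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
    p <- pmax(p, .Machine$double.xmin)  # report minimum positive, never 0
    r2 <- ifelse(is.finite(t_stat), (t_stat / sqrt(df + t_stat^2))^2, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = snps$id[cis], target_id = colnames(targets)[t_i],
      target_kind = target_kind, beta = beta, t_stat = t_stat, df = df,
      p = p, r2 = r2, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), target_id = character(0),
               target_kind = character(0), beta = numeric(0),
               t_stat = numeric(0), df = integer(0), p = numeric(0),
               r2 = numeric(0))
  out$q_bh <- if (nrow(out)) p.adjust(out$p, "BH") else numeric(0)
  out <- out[, c("snp_id", "target_id", "target_kind", "beta", "t_stat",
                 "df", "p", "q_bh", "r2")]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

pcs_of <- function(m, k, prefix) {
  if (k <= 0L) return(NULL)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  out <- pc$x[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0(prefix, seq_len(k))
  out
}

#' Prune QTLs in linkage disequilibrium
#'
#' Greedy pruning by significance: the most significant QTL is kept and all
#' QTLs whose genotype (dosage) Pearson correlation with it exceeds
#' `r_threshold` in absolute value are removed; the procedure repeats with the
#' next remaining QTL until all retained QTLs are pairwise below the
#' threshold. Sorting is by ascending p, ties by descending |t|, then SNP id.
#'
#' @param qtls a `qtl_table` from [map_qtl()].
#' @param genotypes genotype list (for dosage correlations).
#' @param r_threshold correlation threshold (default 0.8; removal is strict
#'   `|r| > r_threshold`).
#' @param by_target prune within each target (default TRUE); set FALSE to
#'   prune the whole table jointly.
#' @return the pruned `qtl_table`.
#' @export
ld_prune <- function(qtls, genotypes, r_threshold = 0.8, by_target = TRUE) {
  if (nrow(qtls) == 0L) return(qtls)
  prune_one <- function(q) {
    q <- q[order(q$p, -abs(q$t_stat), q$snp_id), , drop = FALSE]
    g <- genotypes$dosages[, q$snp_id, drop = FALSE]
    keep <- logical(nrow(q))
    alive <- rep(TRUE, nrow(q))
    while (any(alive)) {
      i <- which(alive)[1]
      keep[i] <- TRUE
      alive[i] <- FALSE
      if (any(alive)) {
        r <- suppressWarnings(as.vector(cor(g[, i], g[, alive, drop = FALSE])))
        r[is.na(r)] <- 0
        drop <- which(alive)[abs(r) > r_threshold]
        alive[drop] <- FALSE
      }
    }
    q[keep, , drop = FALSE]
  }
  out <- if (by_target) {
    parts <- split(seq_len(nrow(qtls)), qtls$target_id)
    do.call(rbind, lapply(parts, function(ix) prune_one(qtls[ix, , drop = FALSE])))
  } else prune_one(qtls)
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' eQTL sharing between neighboring eGenes
#'
#' Considers genes with at least one significant QTL (eGenes, `q_bh <
#' sig_q`), forms consecutive eGene pairs in genomic order per chromosome,
#' and records whether each pair shares at least one eQTL and whether both
#' TSSs fall inside a single domain of each label. Reports per-label sharing
#' percentages, Fisher's exact test of sharing for in-domain versus outside
#' pairs, and an equal-count distance-bin summary.
#'
#' @param qtls gene-kind `qtl_table`.
#' @param gene_models gene table (`gene_id`, `chrom`, `tss`).
#' @param domain_sets named list of `domain_set` objects (e.g. coactivity,
#'   variable, matched).
#' @param sig_q eGene significance threshold on BH q (default 0.05).
#' @param n_distance_bins number of equal-count distance bins (default 5).
#' @return list with `pairs` (per-pair table), `by_label` (sharing summary),
#'   `fisher` (test of in-coactivity-domain vs outside sharing), and
#'   `distance_bins`.
#' @export
eqtl_sharing <- function(qtls, gene_models, domain_sets, sig_q = 0.05,
                         n_distance_bins = 5L) {
  sig <- qtls[qtls$q_bh < sig_q, , drop = FALSE]
  esets <- split(sig$snp_id, sig$target_id)
  egenes <- gene_models[gene_models$gene_id %in% names(esets), , drop = FALSE]
  if (nrow(egenes) < 2L)
    return(list(pairs = data.frame(), by_label = data.frame(),
                fisher = NULL, distance_bins = data.frame()))
  egenes <- egenes[order(egenes$chrom, egenes$tss), ]
  rows <- list()
  for (ch in unique(egenes$chrom)) {
    gg <- egenes[egenes$chrom == ch, , drop = FALSE]
    if (nrow(gg) < 2L) next
    for (i in seq_len(nrow(gg) - 1L)) {
      a <- gg$gene_id[i]; b <- gg$gene_id[i + 1L]
      shared <- length(intersect(esets[[a]], esets[[b]])) > 0L
      row <- data.frame(gene_a = a, gene_b = b, chrom = ch,
                        distance = gg$tss[i + 1L] - gg$tss[i],
                        shared = shared, stringsAsFactors = FALSE)
      for (lab in names(domain_sets)) {
        ds <- domain_sets[[lab]]
        inside <- any(ds$chrom == ch & ds$start <= gg$tss[i] &
                        gg$tss[i] < ds$end & ds$start <= gg$tss[i + 1L] &
                        gg$tss[i + 1L] < ds$end)
        row[[paste0("in_", lab)]] <- inside
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  pairs <- do.call(rbind, rows)
  lab_cols <- grep("^in_", names(pairs), value = TRUE)
  by_label <- do.call(rbind, lapply(lab_cols, function(cl) {
    sel <- pairs[[cl]]
    data.frame(label = sub("^in_", "", cl), n_pairs = sum(sel),
               sharing_pct = if (any(sel)) 100 * mean(pairs$shared[sel]) else NA_real_)
  }))
  outside <- if ("in_coactivity" %in% names(pairs)) !pairs$in_coactivity else
    !Reduce(`|`, pairs[lab_cols])
  by_label <- rbind(by_label, data.frame(
    label = "outside", n_pairs = sum(outside),
    sharing_pct = if (any(outside)) 100 * mean(pairs$shared[outside]) else NA_real_))
  fis <- NULL
  incl <- if ("in_coactivity" %in% names(pairs)) pairs$in_coactivity else !outside
  tab <- rbind(c(sum(pairs$shared & incl), sum(!pairs$shared & incl)),
               c(sum(pairs$shared & outside), sum(!pairs$shared & outside)))
  if (all(rowSums(tab) > 0))
    fis <- fisher_enrichment_table(tab)
  # equal-count distance bins (ties assigned to the lower bin)
  nb <- min(n_distance_bins, nrow(pairs))
  br <- unique(quantile(pairs$distance, probs = seq(0, 1, length.out = nb + 1L)))
  binf <- cut(pairs$distance, breaks = br, include.lowest = TRUE, right = TRUE)
  distance_bins <- do.call(rbind, lapply(levels(binf), function(lv) {
    sel <- binf == lv
    data.frame(bin = lv, n_pairs = sum(sel),
               sharing_fraction = mean(pairs$shared[sel]),
               mean_distance = mean(pairs$distance[sel]))
  }))
  list(pairs = pairs, by_label = by_label, fisher = fis,
       distance_bins = distance_bins)
}

#' QTL summary score
#'
#' Summarizes a domain's (pruned) QTLs into one per-individual score: QTLs
#' with negative effect size are polarized by inverting genotypes (`2 - g`)
#' and taking the absolute effect; the score is the effect-size-weighted mean
#' of polarized genotypes,
#' \deqn{QSS_j = sum_k w_k g'_{jk} / sum_k w_k, w_k = |beta_k|.}
#' The score lies in `[0, 2]`; an individual homozygous for the risk
#' (score-increasing) allele at every QTL scores exactly 2.
#'
#' @param qtls `qtl_table` restricted to one domain (pruned).
#' @param genotypes genotype list.
#' @return object of class `qss`: list with `values` (per individual),
#'   `qtl_ids`, `polarized_effects`.
#' @export
compute_qss <- function(qtls, genotypes) {
  if (nrow(qtls) == 0L) stop_ca("compute_qss needs at least one QTL")
  g <- genotypes$dosages[, qtls$snp_id, drop = FALSE]
  w <- abs(qtls$beta)
  if (sum(w) == 0) stop_ca("all effect sizes are zero; QSS undefined")
  neg <- qtls$beta < 0
  g[, neg] <- 2 - g[, neg]
  values <- as.vector(g %*% w) / sum(w)
  structure(list(values = setNames(values, rownames(g)),
                 qtl_ids = qtls$snp_id, polarized_effects = w),
            class = "qss")
}

#' @export
print.qss <- function(x, ...) {
  cat(sprintf("QTL summary score over %d QTL(s): range [%.3f, %.3f]\n",
              length(x$qtl_ids), min(x$values), max(x$values)))
  invisible(x)
}

#' Per-domain explained variance and effect-size comparison
#'
#' Summarizes pruned QTL tables for two domain classes: per domain the
#' maximum and total r2 and the largest absolute effect, plus Wilcoxon
#' rank-sum tests comparing the per-domain maxima between classes.
#'
#' @param qtls_a,qtls_b pruned `qtl_table`s for the two classes.
#' @param labels length-2 character labels.
#' @return list with `per_domain` and `tests`.
#' @export
variance_explained_summary <- function(qtls_a, qtls_b,
                                       labels = c("variable", "matched")) {
  summarize <- function(q, lab) {
    if (nrow(q) == 0L)
      return(data.frame(target_id = character(0), label = character(0),
                        max_r2 = numeric(0), sum_r2 = numeric(0),
                        max_abs_beta = numeric(0)))
    parts <- split(q, q$target_id)
    do.call(rbind, lapply(parts, function(p) data.frame(
      target_id = p$target_id[1], label = lab, max_r2 = max(p$r2),
      sum_r2 = sum(p$r2), max_abs_beta = max(abs(p$beta)))))
  }
  per <- rbind(summarize(qtls_a, labels[1]), summarize(qtls_b, labels[2]))
  rownames(per) <- NULL
  tests <- NULL
  a <- per[per$label == labels[1], ]; b <- per[per$label == labels[2], ]
  if (nrow(a) > 0 && nrow(b) > 0) {
    wt_r2 <- wilcox.test(a$max_r2, b$max_r2)
    wt_beta <- wilcox.test(a$max_abs_beta, b$max_abs_beta)
    tests <- data.frame(
      quantity = c("max_r2", "max_abs_beta"),
      median_a = c(median(a$max_r2), median(a$max_abs_beta)),
      median_b = c(median(b$max_r2), median(b$max_abs_beta)),
      p = c(wt_r2$p.value, wt_beta$p.value))
  }
  list(per_domain = per, tests = tests)
}
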