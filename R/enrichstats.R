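#' Fisher enrichment of a feature in a foreground set of units
#'
#' Builds the 2x2 contingency table (foreground/background x feature
#' present/absent) and tests association with Fisher's exact test. The
#' reported odds ratio is the sample odds ratio `(a d)/(b c)` (not the
#' conditional MLE), with `Inf` or `0` on zero off-/on-diagonal cells; an
#' optional Haldane correction of 0.5 per cell is available.
#'
#' @param in_foreground logical per unit (e.g. OCR lies in a variable
#'   domain).
#' @param has_feature logical per unit (e.g. OCR has a binding site).
#' @param haldane add 0.5 to every cell before computing the odds ratio.
#' @return object of class `contingency_result`: list with `table` (2x2),
#'   `odds_ratio`, `p`, `method`.
#' @export
fisher_enrichment <- function(in_foreground, has_feature, haldane = FALSE) {
  if (length(in_foreground) == 0L) stop_ca("empty unit set")
  if (length(in_foreground) != length(has_feature))
    stop_ca("unit flags must be aligned")
  tab <- rbind(c(sum(in_foreground & has_feature), sum(in_foreground & !has_feature)),
               c(sum(!in_foreground & has_feature), sum(!in_foreground & !has_feature)))
  fisher_enrichment_table(tab, haldane = haldane)
}

# Fisher's exact test on an explicit 2x2 table, sample odds ratio.
fisher_enrichment_table <- function(tab, haldane = FALSE) {
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  p <- fisher.test(tab)$p.value
  tt <- if (haldane) tab + 0.5 else tab
  num <- tt[1, 1] * tt[2, 2]
  den <- tt[1, 2] * tt[2, 1]
  or <- if (den == 0 && num == 0) NaN else if (den == 0) Inf else num / den
  structure(list(table = tab, odds_ratio = or, p = p, method = "fisher_exact"),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Fisher exact test: OR = %.4g, p = %.4g\n", x$odds_ratio, x$p))
  print(x$table)
  invisible(x)
}

#' TAD boundary positions relative to co-activity domain boundaries
#'
#' Histogram of boundary counts by signed distance from each TAD boundary to
#' the nearest domain boundary (domain starts and ends), in 10-kb distance
#' bins, plus mean counts per distance bin within and beyond `window_bp`.
#'
#' @param tad_boundaries interval data.frame of boundary elements (their
#'   midpoints are used as positions).
#' @param domain_boundaries `domain_set` or interval data.frame; both ends of
#'   each interval are boundaries.
#' @param window_bp near/far threshold (default 50,000).
#' @param max_dist_bp histogram half-range (default 500,000).
#' @param dist_bin_bp histogram bin width (default 10,000).
#' @return list with `profile` (data.frame `dist_bp`, `n_boundaries`),
#'   `near_mean`, `far_mean`.
#' @export
tad_boundary_proximity <- function(tad_boundaries, domain_boundaries,
                                   window_bp = 50000, max_dist_bp = 500000,
                                   dist_bin_bp = 10000) {
  tad_pos <- (tad_boundaries$start + tad_boundaries$end) / 2
  tad_chrom <- tad_boundaries$chrom
  dists <- rep(NA_real_, length(tad_pos))
  for (ch in unique(tad_chrom)) {
    db <- domain_boundaries[domain_boundaries$chrom == ch, , drop = FALSE]
    if (nrow(db) == 0L) next
    bpos <- sort(c(db$start, db$end))
    sel <- which(tad_chrom == ch)
    for (i in sel) {
      d <- tad_pos[i] - bpos
      dists[i] <- d[which.min(abs(d))]
    }
  }
  dists <- dists[!is.na(dists) & abs(dists) <= max_dist_bp]
  breaks <- seq(-max_dist_bp, max_dist_bp, by = dist_bin_bp)
  h <- table(cut(dists, breaks = breaks, include.lowest = TRUE))
  centers <- head(breaks, -1) + dist_bin_bp / 2
  profile <- data.frame(dist_bp = centers, n_boundaries = as.integer(h))
  near <- abs(profile$dist_bp) <= window_bp
  list(profile = profile,
       near_mean = mean(profile$n_boundaries[near]),
       far_mean = mean(profile$n_boundaries[!near]))
}

#' Compartment-class coverage of domain sets
#'
#' Per domain label, the fraction of total bp covered by each compartment
#' class (`active`, `facultative`, `constitutive`); the uncovered remainder
#' is reported as `uncovered`. Compartment annotations must be
#' non-overlapping.
#'
#' @param domains a `domain_set` (or rbind of several, column `label`).
#' @param compartments interval data.frame with a `class` column.
#' @return data.frame `label`, one column per class, `uncovered`.
#' @export
compartment_coverage <- function(domains, compartments) {
  gr <- intervals_to_gr(compartments)
  if (length(gr) > 1L) {
    red <- GenomicRanges::reduce(gr)
    if (sum(as.numeric(GenomicRanges::width(red))) <
        sum(as.numeric(GenomicRanges::width(gr))))
      stop_ca("overlapping compartment annotations must be pre-resolved")
  }
  classes <- sort(unique(compartments$class))
  rows <- lapply(split(domains, domains$label), function(d) {
    tot <- sum(d$end - d$start)
    fr <- vapply(classes, function(cl)
      overlap_bp(d, compartments[compartments$class == cl, , drop = FALSE]) / tot,
      numeric(1))
    out <- data.frame(label = d$label[1], t(fr))
    names(out)[-1] <- classes
    out$uncovered <- 1 - sum(fr)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-expression of neighboring gene pairs stratified by co-activity score
#'
#' For consecutive gene pairs (genomic TSS order per chromosome), computes
#' the Pearson correlation of expression across individuals, assigns each
#' pair to a 2-D tile by the co-activity scores at the upstream and
#' downstream TSS, and summarizes per tile the mean correlation, pair count
#' and the fraction of pairs significantly correlated (BH-adjusted p below
#' `sig_q`). Tiles with fewer than `min_pairs` pairs are masked.
#'
#' @param expression matrix, individuals x genes (TPM; log-transformed when
#'   `log_transform`).
#' @param gene_models gene table (`gene_id`, `chrom`, `tss`).
#' @param scores_at_tss named numeric vector: mean co-activity of the bin
#'   containing each gene's TSS.
#' @param breaks tile breaks applied to both axes (default integer breaks
#'   spanning the scores).
#' @param sig_q BH threshold for a "correlated" pair (default 0.1).
#' @param min_pairs minimum pairs per reported tile (default 10).
#' @param log_transform log-transform expression as `log(x + 1)`
#'   (default TRUE).
#' @return list with `pairs` (per-pair table) and `tiles` (per-tile summary).
#' @export
coexpression_stratified <- function(expression, gene_models, scores_at_tss,
                                    breaks = NULL, sig_q = 0.1,
                                    min_pairs = 10L, log_transform = TRUE) {
  if (nrow(expression) < 3L) stop_ca("need at least 3 individuals")
  ex <- if (log_transform) log(expression + 1) else expression
  gm <- gene_models[gene_models$gene_id %in% colnames(ex) &
                      gene_models$gene_id %in% names(scores_at_tss), ]
  gm <- gm[order(gm$chrom, gm$tss), ]
  rows <- list()
  for (ch in unique(gm$chrom)) {
    gg <- gm[gm$chrom == ch, , drop = FALSE]
    if (nrow(gg) < 2L) next
    for (i in seq_len(nrow(gg) - 1L)) {
      a <- gg$gene_id[i]; b <- gg$gene_id[i + 1L]
      if (sd(ex[, a]) == 0 || sd(ex[, b]) == 0) next
      ct <- cor.test(ex[, a], ex[, b])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_up = a, gene_down = b, chrom = ch,
        score_up = unname(scores_at_tss[a]), score_down = unname(scores_at_tss[b]),
        pcc = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(pairs = data.frame(), tiles = data.frame()))
  pairs <- do.call(rbind, rows)
  pairs$q_bh <- p.adjust(pairs$p, "BH")
  if (is.null(breaks)) {
    rng <- range(c(pairs$score_up, pairs$score_down), na.rm = TRUE)
    breaks <- seq(floor(rng[1]), ceiling(rng[2]), by = 1)
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)
  }
  tu <- cut(pairs$score_up, breaks, include.lowest = TRUE)
  td <- cut(pairs$score_down, breaks, include.lowest = TRUE)
  tiles <- do.call(rbind, lapply(split(seq_len(nrow(pairs)),
                                       list(tu, td), drop = TRUE),
                                 function(ix) data.frame(
    tile_up = as.character(tu[ix[1]]), tile_down = as.character(td[ix[1]]),
    n_pairs = length(ix), mean_pcc = mean(pairs$pcc[ix]),
    frac_significant = mean(pairs$q_bh[ix] < sig_q))))
  if (nrow(tiles)) {
    mask <- tiles$n_pairs < min_pairs
    tiles$mean_pcc[mask] <- NA_real_
    tiles$frac_significant[mask] <- NA_real_
    rownames(tiles) <- NULL
  }
  list(pairs = pairs, tiles = tiles)
}

#' Correlation between co-activity scores and histone signal
#'
#' Per bin, the Pearson correlation across individuals between the
#' co-activity score and the histone PTM signal (with BH-adjusted p values
#' and, per region class, the fraction of bins with q below `sig_q`); and per
#' domain, the correlation between the domain-mean score and the domain-mean
#' signal across individuals.
#'
#' @param scores matrix, individuals x bins.
#' @param histone_signal matrix, individuals x bins (RPM-like; optionally
#'   log-transformed by the caller).
#' @param bins bin coordinates.
#' @param domains a `domain_set` (bins outside any interval are classed
#'   `"background"`).
#' @param sig_q BH threshold (default 0.05).
#' @return list with `per_bin` (bin, class, r, p, q_bh, n), `by_class`
#'   (mean r and fraction significant per region class), and `per_domain`
#'   (domain-level correlations).
#' @export
histone_coactivity_correlation <- function(scores, histone_signal, bins,
                                           domains, sig_q = 0.05) {
  stopifnot(all(dim(scores) == dim(histone_signal)))
  check_scores_bins(scores, bins)
  B <- ncol(scores)
  cls <- rep("background", B)
  for (r in seq_len(nrow(domains))) {
    sel <- bins$chrom == domains$chrom[r] & bins$start >= domains$start[r] &
      bins$start < domains$end[r]
    cls[sel] <- domains$label[r]
  }
  r <- p <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    x <- scores[, b]; h <- histone_signal[, b]
    ok <- is.finite(x) & is.finite(h)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(h[ok]) == 0) next
    ct <- cor.test(x[ok], h[ok])
    r[b] <- unname(ct$estimate); p[b] <- ct$p.value
  }
  per_bin <- data.frame(bin = seq_len(B), chrom = bins$chrom,
                        start = bins$start, class = cls, r = r, p = p,
                        n = colSums(is.finite(scores) & is.finite(histone_signal)))
  per_bin$q_bh <- NA_real_
  ok <- !is.na(per_bin$p)
  per_bin$q_bh[ok] <- p.adjust(per_bin$p[ok], "BH")
  by_class <- do.call(rbind, lapply(split(per_bin[ok, ], per_bin$class[ok]),
                                    function(d) data.frame(
    class = d$class[1], n_bins = nrow(d), mean_r = mean(d$r),
    frac_significant = mean(d$q_bh < sig_q))))
  rownames(by_class) <- NULL
  per_domain <- do.call(rbind, lapply(seq_len(nrow(domains)), function(i) {
    sel <- bins$chrom == domains$chrom[i] & bins$start >= domains$start[i] &
      bins$start < domains$end[i]
    ms <- rowMeans(scores[, sel, drop = FALSE], na.rm = TRUE)
    mh <- rowMeans(histone_signal[, sel, drop = FALSE], na.rm = TRUE)
    rr <- if (sd(ms) == 0 || sd(mh) == 0) NA_real_ else cor(ms, mh)
    data.frame(chrom = domains$chrom[i], start = domains$start[i],
               end = domains$end[i], label = domains$label[i], r = rr)
  }))
  list(per_bin = per_bin, by_class = by_class, per_domain = per_domain)
}

coefficient_of_variation <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sd(x) / m
}

#' Summaries of enhancer (ABC) interaction counts per gene
#'
#' Per gene: median and coefficient of variation (CoV) of the interaction
#' count, median expression and expression CoV across individuals; Spearman
#' correlations among the four per-gene quantities; per-gene paired Pearson
#' correlation between expression and interaction count with BH q values;
#' and rank-sum comparisons of counts and count CoV between domain labels.
#'
#' @param abc_counts matrix, individuals x genes.
#' @param expression matrix, individuals x genes (TPM).
#' @param gene_models gene table (for domain assignment by TSS).
#' @param domains a `domain_set`; genes outside all intervals are classed
#'   `"background"`.
#' @param sig_q BH threshold for the paired correlations (default 0.1).
#' @return list with `per_gene`, `spearman` (correlation matrix), `paired`
#'   (summary of significant paired correlations), `label_tests`.
#' @export
abc_summaries <- function(abc_counts, expression, gene_models, domains,
                          sig_q = 0.1) {
  genes <- intersect(colnames(abc_counts), colnames(expression))
  dropped <- setdiff(colnames(abc_counts), genes)
  if (length(dropped))
    message(sprintf("dropping %d gene(s) absent from expression", length(dropped)))
  gm <- gene_models[match(genes, gene_models$gene_id), ]
  lab <- rep("background", length(genes))
  for (r in seq_len(nrow(domains))) {
    sel <- gm$chrom == domains$chrom[r] & gm$tss >= domains$start[r] &
      gm$tss < domains$end[r]
    lab[sel] <- domains$label[r]
  }
  per_gene <- data.frame(
    gene_id = genes, label = lab,
    median_count = apply(abc_counts[, genes, drop = FALSE], 2, median),
    cov_count = apply(abc_counts[, genes, drop = FALSE], 2, coefficient_of_variation),
    median_expr = apply(expression[, genes, drop = FALSE], 2, median),
    cov_expr = apply(expression[, genes, drop = FALSE], 2, coefficient_of_variation),
    row.names = NULL)
  pr <- pp <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    x <- expression[, genes[i]]; k <- abc_counts[, genes[i]]
    if (sd(x) == 0 || sd(k) == 0) next
    ct <- cor.test(x, k)
    pr[i] <- unname(ct$estimate); pp[i] <- ct$p.value
  }
  per_gene$paired_r <- pr
  per_gene$paired_p <- pp
  per_gene$paired_q <- NA_real_
  ok <- !is.na(pp)
  per_gene$paired_q[ok] <- p.adjust(pp[ok], "BH")
  qm <- per_gene[, c("median_count", "cov_count", "median_expr", "cov_expr")]
  cc <- complete.cases(qm)
  spearman <- cor(qm[cc, ], method = "spearman")
  sig <- per_gene$paired_q < sig_q & !is.na(per_gene$paired_q)
  paired <- data.frame(n_significant = sum(sig),
                       frac_positive = if (any(sig)) mean(per_gene$paired_r[sig] > 0)
                       else NA_real_)
  labs <- unique(lab)
  label_tests <- NULL
  if (length(labs) >= 2L) {
    main <- setdiff(labs, "background")[1] %||% labs[1]
    other <- setdiff(labs, main)[1]
    a <- per_gene[per_gene$label == main, ]; b <- per_gene[per_gene$label == other, ]
    label_tests <- data.frame(
      quantity = c("median_count", "cov_count"),
      label_a = main, label_b = other,
      p = c(wilcox.test(a$median_count, b$median_count)$p.value,
            wilcox.test(a$cov_count[!is.na(a$cov_count)],
                        b$cov_count[!is.na(b$cov_count)])$p.value))
  }
  list(per_gene = per_gene, spearman = spearman, paired = paired,
       label_tests = label_tests)
}

#' Strand-aware promoter windows
#'
#' Promoter of a gene: `upstream_bp` upstream to `downstream_bp` downstream
#' of the TSS, respecting strand (for a minus-strand gene the window extends
#' upstream in decreasing coordinates), clipped at zero.
#'
#' @param gene_models gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param upstream_bp,downstream_bp window extents (defaults 2000 and 200).
#' @return interval data.frame `chrom`, `start`, `end`, `name`.
#' @export
promoter_windows <- function(gene_models, upstream_bp = 2000L,
                             downstream_bp = 200L) {
  plus <- gene_models$strand == "+"
  start <- ifelse(plus, gene_models$tss - upstream_bp,
                  gene_models$tss - downstream_bp)
  end <- ifelse(plus, gene_models$tss + downstream_bp,
                gene_models$tss + upstream_bp)
  data.frame(chrom = gene_models$chrom, start = pmax(0L, as.integer(start)),
             end = as.integer(end), name = gene_models$gene_id,
             stringsAsFactors = FALSE)
}

#' TF binding-site enrichment versus TF expression variability
#'
#' Relates each TF's binding-site enrichment in variable domains (odds ratio)
#' to its expression variability (CoV on the linear scale) and to the mean
#' variability of its target genes (genes with a binding site in their
#' promoter window); tests the OR-CoV correlation; and, when domain scores
#' and per-TF domain binding are supplied, contrasts the correlation between
#' TF expression and domain co-activity for bound versus unbound domains
#' (Welch t test per TF, BH-corrected).
#'
#' @param tfbs_or data.frame `tf`, `odds_ratio` (per-TF enrichment, e.g. from
#'   [fisher_enrichment()] over OCRs).
#' @param tf_expression matrix, individuals x TFs, log scale (CoV is computed
#'   on `exp()` of it).
#' @param expression matrix, individuals x genes (TPM), for target CoV.
#' @param tf_targets named list: target gene ids per TF.
#' @param domain_scores optional matrix, domains x individuals.
#' @param tf_domain_binding optional logical matrix, TFs x domains.
#' @return list with `per_tf`, `or_cov_test` (PCC and p), and optionally
#'   `bound_contrast` (per-TF Welch test of bound vs unbound correlations).
#' @export
tf_variability_relations <- function(tfbs_or, tf_expression, expression,
                                     tf_targets, domain_scores = NULL,
                                     tf_domain_binding = NULL) {
  tfs <- tfbs_or$tf
  cov_tf <- vapply(tfs, function(t)
    coefficient_of_variation(exp(tf_expression[, t])), numeric(1))
  target_cov <- vapply(tfs, function(t) {
    tg <- intersect(tf_targets[[t]] %||% character(0), colnames(expression))
    if (!length(tg)) return(NA_real_)
    mean(apply(expression[, tg, drop = FALSE], 2, coefficient_of_variation),
         na.rm = TRUE)
  }, numeric(1))
  per_tf <- data.frame(tf = tfs, odds_ratio = tfbs_or$odds_ratio,
                       expression_cov = cov_tf, mean_target_cov = target_cov,
                       row.names = NULL)
  ok <- is.finite(per_tf$odds_ratio) & is.finite(per_tf$expression_cov)
  or_cov_test <- if (sum(ok) >= 3L && sd(per_tf$odds_ratio[ok]) > 0 &&
                     sd(per_tf$expression_cov[ok]) > 0) {
    ct <- cor.test(per_tf$odds_ratio[ok], per_tf$expression_cov[ok])
    data.frame(pcc = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  } else data.frame(pcc = NA_real_, p = NA_real_, n = sum(ok))
  bound_contrast <- NULL
  if (!is.null(domain_scores) && !is.null(tf_domain_binding)) {
    rows <- lapply(tfs, function(t) {
      if (!t %in% rownames(tf_domain_binding)) return(NULL)
      pcc <- apply(domain_scores, 1, function(y) {
        if (sd(y) == 0) return(NA_real_)
        cor(tf_expression[, t], y)
      })
      b <- tf_domain_binding[t, ]
      if (sum(b, na.rm = TRUE) < 2L || sum(!b, na.rm = TRUE) < 2L) return(NULL)
      tt <- t.test(pcc[b], pcc[!b])
      data.frame(tf = t, mean_pcc_bound = mean(pcc[b], na.rm = TRUE),
                 mean_pcc_unbound = mean(pcc[!b], na.rm = TRUE),
                 p = tt$p.value)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      bound_contrast <- do.call(rbind, rows)
      bound_contrast$q_bh <- p.adjust(bound_contrast$p, "BH")
    }
  }
  list(per_tf = per_tf, or_cov_test = or_cov_test,
       bound_contrast = bound_contrast)
}
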