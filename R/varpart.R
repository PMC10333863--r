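#' Select the transcription factors most predictive of domain co-activity
#'
#' For one domain (or each row of a domain x individual score matrix), fits
#' random-forest regressions of the per-individual mean co-activity score on
#' all TF expression levels under `n_folds`-fold cross-validation, averages
#' the impurity (variance-reduction) importance scores over folds, and takes
#' the `n_top` TFs with the highest average importance. The whole process is
#' repeated `n_repeats` times; the final selection is the `n_top` most
#' frequently occurring TFs (ties broken by mean importance). In `"top1"`
#' mode, each repeat's candidates are ranked by univariate OLS R-squared and
#' the most frequently top-ranked TF is selected.
#'
#' @param domain_scores numeric vector of per-individual mean co-activity for
#'   one domain, or a matrix (domains x individuals).
#' @param tf_expression matrix, individuals x TFs (log expression).
#' @param mode `"top10"` or `"top1"`.
#' @param n_top number of TFs selected in `"top10"` mode (default 10, capped
#'   at the panel size).
#' @param n_folds,n_repeats cross-validation folds (default 5) and repeats
#'   (default 3).
#' @param num_trees random-forest size (default 500).
#' @param seed integer seed; identical seeds give identical selections.
#' @return For a vector input, an object of class `tf_selection`: list with
#'   `selected_tfs`, `importance` (mean impurity importance), `frequency`
#'   (occurrences over repeats), `univariate_r2` and `mode`. For a matrix,
#'   a named list of such objects.
#' @export
select_top_tfs <- function(domain_scores, tf_expression,
                           mode = c("top10", "top1"), n_top = 10L,
                           n_folds = 5L, n_repeats = 3L, num_trees = 500L,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.matrix(domain_scores)) {
    out <- lapply(seq_len(nrow(domain_scores)), function(d)
      select_top_tfs(domain_scores[d, ], tf_expression, mode = mode,
                     n_top = n_top, n_folds = n_folds, n_repeats = n_repeats,
                     num_trees = num_trees, seed = derive_seed(seed, d)))
    names(out) <- rownames(domain_scores)
    return(out)
  }
  y <- as.numeric(domain_scores)
  n <- length(y)
  if (nrow(tf_expression) != n)
    stop_ca("domain_scores and tf_expression must share individuals")
  if (n < 2L * n_folds) stop_ca("need at least %d individuals", 2L * n_folds)
  if (sd(y) == 0) stop_ca("zero-variance response")
  tf_ids <- colnames(tf_expression)
  n_top <- min(n_top, ncol(tf_expression))
  uni_r2 <- function(tf) {
    x <- tf_expression[, tf]
    if (sd(x) == 0) return(0)
    cor(x, y)^2
  }
  set.seed(seed)
  imp_sum <- setNames(numeric(length(tf_ids)), tf_ids)
  freq <- setNames(integer(length(tf_ids)), tf_ids)
  top1_votes <- character(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- sample(rep(seq_len(n_folds), length.out = n))
    imp_rep <- setNames(numeric(length(tf_ids)), tf_ids)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      dd <- data.frame(y = y[tr], tf_expression[tr, , drop = FALSE],
                       check.names = FALSE)
      rf <- ranger::ranger(y ~ ., data = dd, num.trees = num_trees,
                           importance = "impurity", num.threads = 1L,
                           seed = derive_seed(seed, r * 100L + f))
      imp_rep <- imp_rep + rf$variable.importance[tf_ids] / n_folds
    }
    top <- names(sort(imp_rep, decreasing = TRUE))[seq_len(n_top)]
    freq[top] <- freq[top] + 1L
    imp_sum <- imp_sum + imp_rep / n_repeats
    if (mode == "top1") {
      r2s <- vapply(top, uni_r2, numeric(1))
      top1_votes[r] <- top[which.max(r2s)]
    }
  }
  ord <- order(-freq, -imp_sum)
  if (mode == "top10") {
    selected <- tf_ids[ord][seq_len(n_top)]
  } else {
    tab <- table(top1_votes)
    best <- names(tab)[tab == max(tab)]
    selected <- best[which.max(imp_sum[best])]
  }
  structure(list(selected_tfs = selected, importance = imp_sum,
                 frequency = freq,
                 univariate_r2 = vapply(selected, uni_r2, numeric(1)),
                 mode = mode, n_repeats = n_repeats, n_folds = n_folds),
            class = "tf_selection")
}

#' @export
print.tf_selection <- function(x, ...) {
  cat(sprintf("TF selection (%s, %d repeats x %d folds): %s\n", x$mode,
              x$n_repeats, x$n_folds, paste(x$selected_tfs, collapse = ", ")))
  invisible(x)
}

build_predictor_frame <- function(y, predictors) {
  dd <- data.frame(y = y)
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    if (is.factor(p) || is.character(p)) dd[[nm]] <- factor(p)
    else if (is.matrix(p)) dd[[nm]] <- I(p)
    else dd[[nm]] <- as.numeric(p)
  }
  dd
}

#' Partition co-activity variance among predictor groups
#'
#' Fits OLS of a domain's per-individual mean co-activity on all predictor
#' groups jointly and computes, for each group, the type-II sum of squares:
#' the increase in residual sum of squares when the whole group (all of its
#' columns) is dropped while every other group is retained. Fractions are
#' type-II SS divided by the total (corrected) sum of squares of the
#' response, so they read as proportions of co-activity variance; the
#' residual fraction is one minus the sum of the group fractions (for
#' orthogonal predictors this equals the residual SS over the total SS).
#' Held-one-out significance per group is the F test comparing the model
#' without the group against the full model.
#'
#' @param domain_scores numeric response (per-individual mean co-activity of
#'   one domain).
#' @param predictors named list of predictor groups: numeric vectors, numeric
#'   matrices (e.g. the selected TF expressions as one group), or factors
#'   (e.g. a laboratory batch).
#' @param sig_level significance flag threshold (default 0.05).
#' @return object of class `variance_partition`: data.frame `groups` with
#'   `group`, `df`, `ss`, `fraction`, `heldout_p`, `significant`; plus
#'   attributes-style fields `residual_fraction`, `total_explained`, `n`,
#'   `r_squared`.
#' @export
partition_variance <- function(domain_scores, predictors, sig_level = 0.05) {
  y <- as.numeric(domain_scores)
  dd <- build_predictor_frame(y, predictors)
  p_total <- sum(vapply(predictors, function(p) {
    if (is.matrix(p)) ncol(p) else if (is.factor(p) || is.character(p))
      length(unique(p)) - 1L else 1L
  }, numeric(1)))
  n <- length(y)
  if (n <= p_total + 1L) stop_ca("insufficient degrees of freedom (n = %d, predictors = %d)",
                                 n, p_total)
  full <- lm(y ~ ., data = dd)
  if (any(is.na(coef(full))))
    stop_ca("collinear predictors: %s aliased",
            paste(names(coef(full))[is.na(coef(full))], collapse = ", "))
  tss <- sum((y - mean(y))^2)
  rss_full <- sum(residuals(full)^2)
  rows <- list()
  for (nm in names(predictors)) {
    red <- lm(y ~ ., data = dd[, c("y", setdiff(names(predictors), nm)),
                               drop = FALSE])
    ss2 <- sum(residuals(red)^2) - rss_full
    cmp <- anova(red, full)
    rows[[nm]] <- data.frame(group = nm, df = cmp$Df[2], ss = ss2,
                             fraction = ss2 / tss,
                             heldout_p = cmp$`Pr(>F)`[2])
  }
  groups <- do.call(rbind, rows)
  groups$significant <- groups$heldout_p < sig_level
  rownames(groups) <- NULL
  structure(list(groups = groups,
                 residual_fraction = 1 - sum(groups$fraction),
                 total_explained = sum(groups$fraction),
                 r_squared = 1 - rss_full / tss,
                 n = n),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition (n = %d, model R^2 = %.3f)\n", x$n, x$r_squared))
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-16s %6.1f%%  (held-out p = %.3g%s)\n", g$group[i],
                100 * g$fraction[i], g$heldout_p[i],
                if (g$significant[i]) ", significant" else ""))
  cat(sprintf("  %-16s %6.1f%%\n", "residual", 100 * x$residual_fraction))
  invisible(x)
}

#' Held-one-out significance of predictor groups
#'
#' Per group, the F test comparing the OLS model without the group against
#' the full model with all groups.
#'
#' @inheritParams partition_variance
#' @return named numeric vector of p values.
#' @export
heldout_significance <- function(domain_scores, predictors) {
  vp <- partition_variance(domain_scores, predictors)
  setNames(vp$groups$heldout_p, vp$groups$group)
}

#' Compare TF-explained variance for co-activity versus expression
#'
#' Per domain, the R-squared of the TF-only OLS model for the co-activity
#' response and for the log-expression response, paired.
#'
#' @param tf_expression matrix, individuals x TFs (may be the selected TFs).
#' @param domain_scores matrix, domains x individuals (mean co-activity).
#' @param domain_log_expression matrix, domains x individuals (mean log
#'   expression of the domain's genes).
#' @return data.frame `domain`, `r2_coactivity`, `r2_expression`.
#' @export
compare_coactivity_vs_expression <- function(tf_expression, domain_scores,
                                             domain_log_expression) {
  stopifnot(nrow(domain_scores) == nrow(domain_log_expression))
  r2_of <- function(y) {
    f <- lm(y ~ ., data = data.frame(y = y, tf_expression, check.names = FALSE))
    summary(f)$r.squared
  }
  data.frame(
    domain = rownames(domain_scores) %||% seq_len(nrow(domain_scores)),
    r2_coactivity = apply(domain_scores, 1, r2_of),
    r2_expression = apply(domain_log_expression, 1, r2_of),
    row.names = NULL)
}
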