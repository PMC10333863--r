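#' Parameters of the co-activity domain caller
#'
#' @param frac_individuals minimum fraction of individuals with a positive
#'   co-activity score for a bin to be marked (default 0.15).
#' @param min_run_bins minimum number of consecutive marked bins (default 10).
#' @param merge_gap_bp maximum gap between runs to merge, in bp
#'   (default 100,000).
#' @param min_tpm minimum expression for a gene to count as expressed
#'   (default 0.1 TPM).
#' @param min_genes minimum number of expressed genes per retained region
#'   (default 2).
#' @param sd_threshold between-individual score SD above which a bin counts
#'   as variable (strict inequality; default 0.6).
#' @return object of class `domain_call_params`.
#' @export
domain_call_params <- function(frac_individuals = 0.15, min_run_bins = 10L,
                               merge_gap_bp = 100000L, min_tpm = 0.1,
                               min_genes = 2L, sd_threshold = 0.6) {
  check_fraction(frac_individuals, "frac_individuals", lo = 1e-12)
  if (min_tpm <= 0 || merge_gap_bp <= 0 || sd_threshold <= 0)
    stop_ca("all domain-calling parameters must be positive")
  structure(list(frac_individuals = frac_individuals,
                 min_run_bins = check_count(min_run_bins, "min_run_bins"),
                 merge_gap_bp = merge_gap_bp, min_tpm = min_tpm,
                 min_genes = check_count(min_genes, "min_genes"),
                 sd_threshold = sd_threshold),
            class = "domain_call_params")
}

check_scores_bins <- function(scores, bins) {
  if (ncol(scores) != nrow(bins))
    stop_ca("scores have %d columns but bins %d rows; first mismatch at %s:%d",
            ncol(scores), nrow(bins), bins$chrom[1], bins$start[1])
}

# Genes whose TSS lies inside [start, end) of an interval (half-open);
# returns counts of all and of expressed genes.
genes_in_interval <- function(iv, gene_models, min_tpm) {
  tss <- gene_models$tss %||% gene_models$start
  inside <- gene_models$chrom == iv$chrom & tss >= iv$start & tss < iv$end
  c(n_genes = sum(inside),
    n_expressed = sum(inside & gene_models$mean_tpm >= min_tpm))
}

# Turn per-chromosome marked-bin runs into merged, gene-filtered intervals.
runs_to_domains <- function(marked, scores, bins, gene_models, params, label) {
  rows <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    runs <- true_runs(marked[idx])
    runs <- runs[runs$end - runs$start + 1L >= params$min_run_bins, , drop = FALSE]
    if (nrow(runs) == 0L) next
    iv <- data.frame(chrom = ch,
                     start = bins$start[idx[runs$start]],
                     end = bins$end[idx[runs$end]])
    # merge runs separated by <= merge_gap_bp
    merged <- iv[1, , drop = FALSE]
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv$start[r] - merged$end[nrow(merged)] <= params$merge_gap_bp)
        merged$end[nrow(merged)] <- iv$end[r]
      else merged <- rbind(merged, iv[r, ])
    }
    rows[[length(rows) + 1L]] <- merged
  }
  if (!length(rows)) return(empty_domain_set())
  out <- do.call(rbind, rows)
  stats_ <- t(apply(out, 1, function(r) {
    iv <- list(chrom = r[["chrom"]], start = as.numeric(r[["start"]]),
               end = as.numeric(r[["end"]]))
    genes_in_interval(iv, gene_models, params$min_tpm)
  }))
  out$n_genes <- as.integer(stats_[, "n_genes"])
  out$n_expressed_genes <- as.integer(stats_[, "n_expressed"])
  out <- out[out$n_expressed_genes >= params$min_genes, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_domain_set())
  ms <- t(vapply(seq_len(nrow(out)), function(r) {
    idx <- which(bins$chrom == out$chrom[r] & bins$start >= out$start[r] &
                   bins$start < out$end[r])
    vals <- scores[, idx, drop = FALSE]
    per_ind <- rowMeans(vals, na.rm = TRUE)
    c(mean_score = mean(vals, na.rm = TRUE), score_sd = sd(per_ind))
  }, numeric(2)))
  out$mean_score <- ms[, "mean_score"]
  out$score_sd <- ms[, "score_sd"]
  out$label <- label
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "label", "mean_score", "score_sd",
               "n_genes", "n_expressed_genes")]
  rownames(out) <- NULL
  class(out) <- c("domain_set", "data.frame")
  out
}

empty_domain_set <- function() {
  out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    label = character(0), mean_score = numeric(0),
                    score_sd = numeric(0), n_genes = integer(0),
                    n_expressed_genes = integer(0))
  class(out) <- c("domain_set", "data.frame")
  out
}

#' Call co-activity domains
#'
#' Marks bins where the fraction of individuals with a strictly positive
#' co-activity score is at least `frac_individuals`, keeps maximal runs of at
#' least `min_run_bins` marked bins, merges runs separated by at most
#' `merge_gap_bp`, and retains merged regions containing at least `min_genes`
#' genes expressed at `min_tpm` or more (a gene is contained when its TSS
#' lies in the half-open interval).
#'
#' @param scores co-activity score matrix (individuals x bins), e.g. from
#'   [coactivity_matrix()].
#' @param bins bin coordinates aligned to the score columns.
#' @param gene_models gene table with `chrom`, `tss` and `mean_tpm`.
#' @param params a [domain_call_params()] object.
#' @return a `domain_set` data.frame (label `"coactivity"`) with per-domain
#'   mean score, between-individual SD of the domain mean, and gene counts.
#' @export
call_coactivity_domains <- function(scores, bins, gene_models,
                                    params = domain_call_params()) {
  check_scores_bins(scores, bins)
  frac_pos <- colMeans(scores > 0, na.rm = TRUE)
  frac_pos[colSums(!is.na(scores)) == 0] <- NA
  marked <- !is.na(frac_pos) & frac_pos >= params$frac_individuals
  runs_to_domains(marked, scores, bins, gene_models, params, "coactivity")
}

#' Call variable co-activity domains
#'
#' Within co-activity domains only, marks bins whose between-individual score
#' standard deviation is strictly above `sd_threshold`, then applies the same
#' run-length, merge, and expressed-gene rules as
#' [call_coactivity_domains()]. Runs are truncated at co-activity domain
#' boundaries before merging.
#'
#' @inheritParams call_coactivity_domains
#' @param coactivity the `domain_set` of called co-activity domains.
#' @return a `domain_set` with label `"variable"`.
#' @export
call_variable_domains <- function(scores, bins, gene_models, coactivity,
                                  params = domain_call_params()) {
  check_scores_bins(scores, bins)
  sds <- col_sds(scores)
  in_domain <- rep(FALSE, nrow(bins))
  for (r in seq_len(nrow(coactivity)))
    in_domain[bins$chrom == coactivity$chrom[r] &
                bins$start >= coactivity$start[r] &
                bins$start < coactivity$end[r]] <- TRUE
  marked <- in_domain & !is.na(sds) & sds > params$sd_threshold
  out <- runs_to_domains(marked, scores, bins, gene_models, params, "variable")
  out
}

#' Background regions of negative co-activity
#'
#' Maximal runs of bins outside co-activity domains whose median score across
#' individuals is negative.
#'
#' @inheritParams call_variable_domains
#' @return a `domain_set` with label `"background"`.
#' @export
background_regions <- function(scores, bins, coactivity) {
  check_scores_bins(scores, bins)
  med <- apply(scores, 2, median, na.rm = TRUE)
  outside <- rep(TRUE, nrow(bins))
  for (r in seq_len(nrow(coactivity)))
    outside[bins$chrom == coactivity$chrom[r] &
              bins$start >= coactivity$start[r] &
              bins$start < coactivity$end[r]] <- FALSE
  marked <- outside & !is.na(med) & med < 0
  rows <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    runs <- true_runs(marked[idx])
    if (nrow(runs) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start = bins$start[idx[runs$start]],
      end = bins$end[idx[runs$end]])
  }
  if (!length(rows)) return(empty_domain_set())
  out <- do.call(rbind, rows)
  out$label <- "background"
  out$mean_score <- vapply(seq_len(nrow(out)), function(r) {
    idx <- which(bins$chrom == out$chrom[r] & bins$start >= out$start[r] &
                   bins$start < out$end[r])
    mean(scores[, idx], na.rm = TRUE)
  }, numeric(1))
  out$score_sd <- NA_real_
  out$n_genes <- NA_integer_
  out$n_expressed_genes <- NA_integer_
  out <- out[order(out$chrom, out$start), names(empty_domain_set())]
  rownames(out) <- NULL
  class(out) <- c("domain_set", "data.frame")
  out
}

#' Sample a matched set of non-variable co-activity domains
#'
#' Candidates are co-activity domains with less than 10% of their length
#' overlapped by variable domains. For each variable domain the candidate
#' closest in Euclidean distance on z-standardized (mean score, log length,
#' number of expressed genes) is selected without replacement, so that the
#' matched set differs from the variable set mainly in between-individual
#' variability. Deterministic given the seed; ties are broken by genomic
#' order.
#'
#' @param coactivity `domain_set` of all co-activity domains.
#' @param variable `domain_set` of variable co-activity domains.
#' @param seed integer seed (matching itself is deterministic; the seed is
#'   part of the interface for reproducibility records).
#' @param max_overlap maximum tolerated fraction of a candidate overlapped by
#'   variable domains (default 0.10).
#' @return a `domain_set` with label `"matched"`.
#' @export
sample_matched_domains <- function(coactivity, variable, seed = 1L,
                                   max_overlap = 0.10) {
  if (nrow(variable) == 0L) return(empty_domain_set())
  ov <- overlap_bp_per_row(coactivity, variable)
  frac <- ov / (coactivity$end - coactivity$start)
  cand <- coactivity[frac < max_overlap, , drop = FALSE]
  if (nrow(cand) < nrow(variable))
    stop_ca("matched sampling: only %d candidates for %d variable domains",
            nrow(cand), nrow(variable))
  set.seed(seed)
  feat <- function(d) cbind(d$mean_score, log(d$end - d$start),
                            d$n_expressed_genes)
  all_f <- rbind(feat(cand), feat(variable))
  mu <- colMeans(all_f); sds <- apply(all_f, 2, sd)
  sds[sds == 0] <- 1
  zc <- sweep(sweep(feat(cand), 2, mu), 2, sds, `/`)
  zv <- sweep(sweep(feat(variable), 2, mu), 2, sds, `/`)
  taken <- rep(FALSE, nrow(cand))
  picks <- integer(nrow(variable))
  for (i in seq_len(nrow(variable))) {
    d2 <- colSums((t(zc) - zv[i, ])^2)
    d2[taken] <- Inf
    picks[i] <- which.min(d2)  # ties: which.min takes the first (genomic order)
    taken[picks[i]] <- TRUE
  }
  out <- cand[sort(picks), , drop = FALSE]
  out$label <- "matched"
  rownames(out) <- NULL
  class(out) <- c("domain_set", "data.frame")
  out
}

#' Domain coverage across positivity cutoffs
#'
#' Total genomic coverage (bp) of called co-activity domains as a function of
#' the fraction-of-individuals cutoff; coverage is non-increasing in the
#' cutoff.
#'
#' @inheritParams call_coactivity_domains
#' @param cutoffs fractions to evaluate (default 5-25%).
#' @return data.frame with `frac_individuals`, `n_domains`, `coverage_bp`.
#' @export
domain_coverage_profile <- function(scores, bins, gene_models,
                                    params = domain_call_params(),
                                    cutoffs = c(0.05, 0.10, 0.15, 0.20, 0.25)) {
  rows <- lapply(cutoffs, function(f) {
    p <- params; p$frac_individuals <- f
    d <- call_coactivity_domains(scores, bins, gene_models, p)
    data.frame(frac_individuals = f, n_domains = nrow(d),
               coverage_bp = sum(d$end - d$start))
  })
  do.call(rbind, rows)
}
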