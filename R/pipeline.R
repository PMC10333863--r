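#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full co-activity pipeline:
#' simulation (or input paths), decomposition hyperparameters, domain-calling
#' parameters, QTL settings, TF-selection/variance-partition settings, and
#' the global seed from which per-stage seeds are derived.
#'
#' @param sim a [sim_config()]; the pipeline's data source.
#' @param hyper a [model_hyperparams()]; when NULL, defaults to fixed
#'   precisions with `theta_init` set to the simulated overdispersion and no
#'   variance computation (posterior means only).
#' @param domain_params a [domain_call_params()].
#' @param maf_min,cis_window_bp,n_geno_pcs,n_pheno_pcs,ld_r_threshold,sig_q
#'   QTL-stage settings (defaults 0.1, 1 Mb, 3, 15, 0.8, 0.05).
#' @param tf_mode,n_top_tfs,rf_trees TF selection settings.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            hyper = NULL,
                            domain_params = domain_call_params(),
                            maf_min = 0.1, cis_window_bp = 1e6,
                            n_geno_pcs = 3L, n_pheno_pcs = 15L,
                            ld_r_threshold = 0.8, sig_q = 0.05,
                            tf_mode = "top10", n_top_tfs = 10L,
                            rf_trees = 500L, seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(hyper))
    hyper <- model_hyperparams(variances = "none", theta_init = sim$theta_sim)
  structure(list(sim = sim, hyper = hyper, domain_params = domain_params,
                 maf_min = maf_min, cis_window_bp = cis_window_bp,
                 n_geno_pcs = as.integer(n_geno_pcs),
                 n_pheno_pcs = as.integer(n_pheno_pcs),
                 ld_r_threshold = ld_r_threshold, sig_q = sig_q,
                 tf_mode = tf_mode, n_top_tfs = as.integer(n_top_tfs),
                 rf_trees = as.integer(rf_trees), seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' A compact default pipeline configuration
#'
#' A small simulated dataset (30 individuals, one chromosome of 500 bins,
#' 8 domains) with reduced phenotype PC counts, sized so the full pipeline
#' runs in well under a minute; intended for examples, the end-to-end test,
#' and the command-line `run` subcommand.
#'
#' @param seed global seed.
#' @return a [pipeline_config()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_individuals = 30L, n_chromosomes = 1L,
                     chrom_length_bins = 500L, n_domains = 8L,
                     n_tfs = 8L, seed = seed),
    n_pheno_pcs = 5L, seed = seed)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; any `*_path` entries must exist.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("sim", "hyper", "domain_params", "maf_min", "cis_window_bp",
             "n_geno_pcs", "n_pheno_pcs", "ld_r_threshold", "sig_q",
             "tf_mode", "n_top_tfs", "rf_trees", "seed", "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_ca("unknown configuration key(s): %s",
                           paste(bad, collapse = ", "))
  paths <- unlist(raw[grepl("_path$", names(raw))])
  for (p in paths) if (!file.exists(p)) stop_ca("input path does not exist: %s", p)
  args <- raw
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$hyper)) args$hyper <- do.call(model_hyperparams, raw$hyper)
  if (!is.null(raw$domain_params))
    args$domain_params <- do.call(domain_call_params, raw$domain_params)
  do.call(pipeline_config, args)
}

pipe_log <- function(config, stage, msg, ...) {
  if (config$log_level == "quiet") return(invisible())
  message(sprintf("[%s] %s: %s", "INFO", stage, sprintf(msg, ...)))
}

config_hash <- function(config) {
  tf <- tempfile()
  writeLines(paste(deparse(unclass(config)), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run the full co-activity pipeline
#'
#' Executes simulate, decompose, call-domains, map-qtl, qss, varpart and
#' enrich in order, writing every stage's tables under `out_dir` and a JSON
#' run report (`run_report.json`) with seeds, per-stage status and output
#' checksums. A stage failure halts the run with the stage name; completed
#' outputs are kept and the report is still written. Reruns with the same
#' configuration and seed produce byte-identical tables (the report's timing
#' fields differ).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the run report (list), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- sprintf("coactivity config=%s seed=%d", hash, config$seed)
  report <- list(config_hash = hash, seed = config$seed,
                 package_version = as.character(packageVersion("coactivity")),
                 stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      write_report(report, out_dir)
      stop_ca("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = round(proc.time()[3] - t0, 2))
    pipe_log(config, name, "done (%.1fs)", proc.time()[3] - t0)
    res
  }

  env <- new.env()
  stage("simulate", function() {
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(config$seed, 1L)
    sim <- simulate_dataset(sim_cfg)
    env$truth <- sim$truth; env$counts <- sim$counts
    write_matrix_tsv(sim$counts$counts, file.path(out_dir, "counts.tsv"),
                     "bin", header = hdr)
    write_bed(sim$counts$bins, file.path(out_dir, "bins.bed"))
    invisible(NULL)
  })

  stage("decompose", function() {
    qc <- qc_filter_libraries(env$counts)
    env$counts_qc <- qc$counts
    env$counts_qc$excluded_bins <- mask_vdj_bins(env$counts_qc$bins,
                                                 env$truth$gene_models)
    env$plan <- plan_segments(env$counts_qc)
    env$fit <- fit_decomposition(env$counts_qc, env$plan, config$hyper)
    env$scores <- coactivity_matrix(env$fit)
    write_matrix_tsv(env$scores, file.path(out_dir, "pd_mean.tsv"), "bin",
                     header = hdr)
    write_matrix_tsv(env$fit$pi_mean, file.path(out_dir, "pi_mean.tsv"), "bin",
                     header = hdr)
    invisible(NULL)
  })

  stage("call_domains", function() {
    bins <- env$counts_qc$bins
    gm <- env$truth$gene_models
    env$coact <- call_coactivity_domains(env$scores, bins, gm,
                                         config$domain_params)
    env$vari <- call_variable_domains(env$scores, bins, gm, env$coact,
                                      config$domain_params)
    env$bg <- background_regions(env$scores, bins, env$coact)
    env$matched <- tryCatch(
      sample_matched_domains(env$coact, env$vari,
                             seed = derive_seed(config$seed, 3L)),
      error = function(e) empty_domain_set())
    for (nm in c("coact", "vari", "bg", "matched")) {
      d <- env[[nm]]
      d$name <- sprintf("%s_%d", d$label, seq_len(nrow(d)))
      d$score <- d$mean_score
      write_bed(d, file.path(out_dir, paste0("domains_", nm, ".bed")),
                header = hdr)
    }
    all_d <- rbind(env$coact, env$vari, env$matched, env$bg)
    write.table(all_d, file.path(out_dir, "domains.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })

  stage("map_qtl", function() {
    inds <- rownames(env$scores)
    geno <- list(dosages = env$truth$genotypes[inds, , drop = FALSE],
                 snp_table = env$truth$snp_table)
    env$geno <- geno
    # eQTLs on gene expression
    expr <- log(env$truth$expression[inds, , drop = FALSE] + 1)
    gm <- env$truth$gene_models
    gene_pos <- data.frame(target_id = gm$gene_id, chrom = gm$chrom,
                           pos = gm$tss)
    env$eqtls <- map_qtl(geno, expr, gene_pos, "gene",
                         cis_window_bp = config$cis_window_bp,
                         maf_min = config$maf_min,
                         n_geno_pcs = config$n_geno_pcs,
                         n_pheno_pcs = config$n_pheno_pcs)
    # co-activity QTLs on variable + matched domain means
    dom <- rbind(env$vari, env$matched)
    if (nrow(dom) > 0L) {
      dm <- domain_mean_scores(env$scores, env$counts_qc$bins, dom)
      env$domain_means <- dm
      dom_pos <- data.frame(target_id = rownames(dm), chrom = dom$chrom,
                            pos = (dom$start + dom$end) / 2)
      # with few domain targets the score PCs would absorb the signal itself;
      # cap them well below the number of targets
      env$caqtls <- map_qtl(geno, t(dm), dom_pos, "domain",
                            cis_window_bp = config$cis_window_bp,
                            maf_min = config$maf_min,
                            n_geno_pcs = config$n_geno_pcs,
                            n_pheno_pcs = min(config$n_pheno_pcs, nrow(dm) %/% 4L))
      env$caqtls_sig <- env$caqtls[env$caqtls$q_bh < config$sig_q, , drop = FALSE]
      env$caqtls_pruned <- ld_prune(env$caqtls_sig, geno,
                                    r_threshold = config$ld_r_threshold)
    } else {
      env$caqtls <- env$caqtls_pruned <- NULL
    }
    write.table(env$eqtls, file.path(out_dir, "eqtls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(env$caqtls))
      write.table(env$caqtls_pruned, file.path(out_dir, "coactivity_qtls_pruned.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })

  stage("qss", function() {
    env$qss <- list()
    if (!is.null(env$caqtls_pruned) && nrow(env$caqtls_pruned) > 0L) {
      for (d in unique(env$caqtls_pruned$target_id)) {
        q <- env$caqtls_pruned[env$caqtls_pruned$target_id == d, , drop = FALSE]
        env$qss[[d]] <- compute_qss(q, env$geno)$values
      }
    }
    if (length(env$qss)) {
      qm <- do.call(cbind, env$qss)
      write_matrix_tsv(t(qm), file.path(out_dir, "qss.tsv"), "domain",
                       header = hdr)
    }
    invisible(NULL)
  })

  stage("varpart", function() {
    if (is.null(env$domain_means) || nrow(env$vari) == 0L) return(invisible(NULL))
    inds <- rownames(env$scores)
    tfx <- env$truth$tf_expression[inds, , drop = FALSE]
    gm <- env$truth$gene_models
    abc <- env$truth$abc_counts[inds, , drop = FALSE]
    rows <- list()
    var_ids <- rownames(env$domain_means)[seq_len(nrow(env$vari))]
    for (i in seq_along(var_ids)) {
      d <- var_ids[i]
      y <- env$domain_means[d, ]
      sel <- select_top_tfs(y, tfx, mode = config$tf_mode,
                            n_top = config$n_top_tfs,
                            num_trees = config$rf_trees,
                            seed = derive_seed(config$seed, 100L + i))
      genes_in <- gm$gene_id[gm$chrom == env$vari$chrom[i] &
                               gm$tss >= env$vari$start[i] &
                               gm$tss < env$vari$end[i]]
      preds <- list(tf = tfx[, sel$selected_tfs, drop = FALSE])
      if (!is.null(env$qss[[d]])) preds$qss <- env$qss[[d]][inds]
      if (length(genes_in))
        preds$abc <- rowSums(abc[, genes_in, drop = FALSE])
      vp <- tryCatch(partition_variance(y, preds), error = function(e) NULL)
      if (is.null(vp)) next
      row <- data.frame(domain = d, total_explained = vp$total_explained,
                        residual = vp$residual_fraction)
      for (g in seq_len(nrow(vp$groups))) {
        row[[paste0("frac_", vp$groups$group[g])]] <- vp$groups$fraction[g]
        row[[paste0("p_", vp$groups$group[g])]] <- vp$groups$heldout_p[g]
      }
      rows[[d]] <- row
    }
    if (length(rows)) {
      nm <- unique(unlist(lapply(rows, names)))
      rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
      vt <- do.call(rbind, rows)
      vt <- vt[order(-vt$total_explained), ]
      write.table(vt, file.path(out_dir, "variance_partition.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      env$varpart <- vt
    }
    invisible(NULL)
  })

  stage("enrich", function() {
    tr <- env$truth$annotation_tracks
    out <- list()
    if (nrow(env$coact) > 0L && nrow(tr$tad_boundaries) > 0L)
      out$tad_near_mean <- tad_boundary_proximity(tr$tad_boundaries, env$coact)$near_mean
    if (nrow(env$vari) > 0L) {
      ocr <- tr$ocr
      in_var <- overlap_bp_per_row(ocr, env$vari) > 0
      in_coact <- overlap_bp_per_row(ocr, env$coact) > 0
      use <- in_coact
      tf_rows <- lapply(unique(tr$tfbs$name), function(t) {
        tf_iv <- tr$tfbs[tr$tfbs$name == t, , drop = FALSE]
        has <- overlap_bp_per_row(ocr, tf_iv) > 0
        fr <- fisher_enrichment(in_var[use], has[use])
        data.frame(tf = t, odds_ratio = fr$odds_ratio, p = fr$p)
      })
      env$tfbs_or <- do.call(rbind, tf_rows)
      env$tfbs_or$q_bh <- p.adjust(env$tfbs_or$p, "BH")
      write.table(env$tfbs_or, file.path(out_dir, "tfbs_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(env$coact) > 0L) {
      cc <- compartment_coverage(rbind(env$coact, env$bg), tr$compartments)
      write.table(cc, file.path(out_dir, "compartment_coverage.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    inds <- rownames(env$scores)
    hc <- histone_coactivity_correlation(env$scores,
                                         env$truth$histone_signal[inds, , drop = FALSE],
                                         env$counts_qc$bins, env$coact)
    write.table(hc$by_class, file.path(out_dir, "histone_correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
  })

  report$total_seconds <- round(proc.time()[3] - t_all, 2)
  files <- list.files(out_dir, pattern = "\\.(tsv|bed)$", full.names = TRUE)
  report$outputs <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  write_report(report, out_dir)
  invisible(report)
}

write_report <- function(report, out_dir) {
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Per-domain mean co-activity per individual
#'
#' @param scores matrix, individuals x bins.
#' @param bins bin coordinates.
#' @param domains a `domain_set`.
#' @return matrix, domains x individuals, rownames `label_i`.
#' @export
domain_mean_scores <- function(scores, bins, domains) {
  out <- t(vapply(seq_len(nrow(domains)), function(r) {
    idx <- which(bins$chrom == domains$chrom[r] & bins$start >= domains$start[r] &
                   bins$start < domains$end[r])
    rowMeans(scores[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(scores))))
  rownames(out) <- sprintf("%s_%d", domains$label, seq_len(nrow(domains)))
  colnames(out) <- rownames(scores)
  out
}
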