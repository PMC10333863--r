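#' Configuration for the synthetic co-activity dataset generator
#'
#' Builds a validated configuration for [simulate_dataset()]. The generator
#' emulates the statistical structure assumed by the decomposition model and
#' the downstream analyses: a per-individual co-activity field built from
#' first-order random-walk increments, elevated inside planted domains and
#' shifted in trans by simulated transcription factor (TF) expression and in
#' cis by planted QTLs; an iid positionally independent field; negative
#' binomial counts with a library-size offset; genotypes under Hardy-Weinberg
#' with optional LD within domains; gene models, per-individual gene
#' expression, histone signal coupled to co-activity, enhancer-interaction
#' (ABC) counts, and annotation tracks consistent with the planted domains.
#'
#' @param n_individuals number of simulated individuals.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bins number of fixed-width bins per chromosome.
#' @param bin_size bin width in bp.
#' @param n_domains total number of planted co-activity domains.
#' @param domain_length_bins length-2 integer range of domain lengths (bins).
#' @param frac_variable_domains fraction of domains that receive individual-
#'   specific (TF and QTL driven) co-activity shifts.
#' @param n_tfs number of simulated TFs.
#' @param n_snps_per_domain number of cis SNPs planted per domain.
#' @param maf_range length-2 minor allele frequency range, within (0, 0.5].
#' @param tf_trans_effect_sd co-activity standard deviation contributed by
#'   each regulating TF to its variable domains (log scale); signs are
#'   random, and effect coefficients are scaled by the TF's own expression
#'   SD so the planted trans variance per domain is
#'   `tfs_per_domain * tf_trans_effect_sd^2`.
#' @param qtl_cis_effect_sd sd of planted domain cis-QTL effects on
#'   co-activity.
#' @param gene_eqtl_effect_sd sd of private eQTL effects planted on genes
#'   outside domains (log-expression scale).
#' @param tau_pd_sim precision of the simulated random-walk increments;
#'   `Inf` yields a flat field.
#' @param tau_pi_sim precision of the simulated iid field; `Inf` allowed.
#' @param theta_sim negative binomial overdispersion of the counts.
#' @param lib_size_range length-2 range of total library sizes (reads),
#'   drawn log-uniformly.
#' @param alpha_sim baseline log mean reads-per-million per bin.
#' @param domain_activity_shift constant added to the co-activity field
#'   inside every planted domain (log scale) before centering.
#' @param tfs_per_domain number of TFs with nonzero effect per variable
#'   domain.
#' @param genes_per_domain length-2 range of expressed genes per domain.
#' @param n_background_genes expressed genes planted outside domains, per
#'   chromosome.
#' @param ld_r allele-copying probability between consecutive SNPs within a
#'   domain, controlling pairwise genotype correlation (0 = independent).
#' @param gene_noise_sd sd of per-gene log-expression noise.
#' @param n_ig_genes number of flagged immunoglobulin-like gene segments to
#'   plant (outside domains); used to exercise VDJ-region masking.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 50L,
                       n_chromosomes = 2L,
                       chrom_length_bins = 1000L,
                       bin_size = 10000L,
                       n_domains = 16L,
                       domain_length_bins = c(15L, 40L),
                       frac_variable_domains = 0.5,
                       n_tfs = 12L,
                       n_snps_per_domain = 8L,
                       maf_range = c(0.1, 0.5),
                       tf_trans_effect_sd = 0.8,
                       qtl_cis_effect_sd = 0.25,
                       gene_eqtl_effect_sd = 0.6,
                       tau_pd_sim = 1e4,
                       tau_pi_sim = 16,
                       theta_sim = 50,
                       lib_size_range = c(5e6, 5e7),
                       alpha_sim = 1,
                       domain_activity_shift = 3,
                       tfs_per_domain = 3L,
                       genes_per_domain = c(2L, 5L),
                       n_background_genes = 8L,
                       ld_r = 0.6,
                       gene_noise_sd = 0.3,
                       n_ig_genes = 0L,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || anyNA(v))
      stop_ca("sim_config field '%s' must be numeric and non-missing", nm)
    if (any(!is.finite(v)) && !nm %in% c("tau_pd_sim", "tau_pi_sim"))
      stop_ca("sim_config field '%s' must be finite", nm)
  }
  for (nm in c("n_individuals", "n_chromosomes", "chrom_length_bins",
               "bin_size", "n_tfs"))
    cfg[[nm]] <- check_count(cfg[[nm]], nm)
  for (nm in c("n_domains", "n_snps_per_domain", "tfs_per_domain",
               "n_background_genes", "n_ig_genes", "seed"))
    cfg[[nm]] <- check_count(cfg[[nm]], nm, min = 0L)
  check_fraction(cfg$frac_variable_domains, "frac_variable_domains")
  check_fraction(cfg$ld_r, "ld_r")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0)
    stop_ca("'maf_range' must be an increasing pair within (0, 0.5]")
  if (length(cfg$domain_length_bins) != 2L || any(cfg$domain_length_bins < 2) ||
      diff(cfg$domain_length_bins) < 0)
    stop_ca("'domain_length_bins' must be an increasing pair of counts >= 2")
  if (length(cfg$genes_per_domain) != 2L || any(cfg$genes_per_domain < 1))
    stop_ca("'genes_per_domain' must be a pair of positive counts")
  if (length(cfg$lib_size_range) != 2L || any(cfg$lib_size_range <= 0))
    stop_ca("'lib_size_range' must be a pair of positive totals")
  if (cfg$theta_sim <= 0) stop_ca("'theta_sim' must be positive")
  if (cfg$tau_pd_sim <= 0 || cfg$tau_pi_sim <= 0)
    stop_ca("precisions 'tau_pd_sim'/'tau_pi_sim' must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic co-activity dataset configuration\n")
  cat(sprintf("  %d individuals, %d chromosome(s) x %d bins of %d bp\n",
              x$n_individuals, x$n_chromosomes, x$chrom_length_bins, x$bin_size))
  cat(sprintf("  %d domains (%.0f%% variable), %d TFs, %d SNPs/domain, seed %d\n",
              x$n_domains, 100 * x$frac_variable_domains, x$n_tfs,
              x$n_snps_per_domain, x$seed))
  invisible(x)
}

# Place k non-overlapping domains on a chromosome of nb bins, with a margin
# from the ends and a minimum inter-domain gap (both in bins).  The gap stays
# above the 10-bin merge distance so planted domains remain separable.
place_domains <- function(nb, lengths, margin = max(3L, min(15L, nb %/% 20L)),
                          min_gap = max(12L, min(25L, nb %/% 15L))) {
  k <- length(lengths)
  if (k == 0L) return(integer(0))
  slack <- nb - 2L * margin - sum(lengths) - (k - 1L) * min_gap
  if (slack < 0)
    stop_ca("domains do not fit on a chromosome of %d bins", nb)
  extra <- as.vector(rmultinom(1L, slack, rep(1, k + 1L)))
  starts <- integer(k)
  pos <- margin + extra[1L]
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + lengths[i] + min_gap + extra[i + 1L]
  }
  starts  # 0-based bin offsets
}

#' Simulate a co-activity dataset with known ground truth
#'
#' Generates latent co-activity (positionally dependent, PD) and positionally
#' independent (PI) fields, negative binomial counts, genotypes, gene models
#' and expression, TF expression, histone signal, ABC interaction counts and
#' annotation tracks, following the generative structure described in
#' [sim_config()].
#'
#' For individual j and bin i the PD field is built per chromosome as
#' cumulative Gaussian increments with precision `tau_pd_sim`, shifted inside
#' each planted domain by a constant activity offset plus
#' `sum_t effect[t,d] * tf_expression[j,t] + sum_s beta_s * genotype[j,s]`
#' (nonzero TF/QTL effects in variable domains only), and centered per
#' chromosome. PI is iid Gaussian with precision `tau_pi_sim`. Counts are
#' `NB(mean = s_j * exp(alpha + PD + PI), size = theta_sim)` with `s_j` the
#' library size in millions.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `truth` (class `sim_truth`) and `counts`
#'   (class `binned_counts`). `truth` holds `pd_true`, `pi_true`,
#'   `domain_intervals`, `tf_expression`, `tf_sd`, `tf_domain_effects`,
#'   `genotypes`, `snp_table`, `qtl_effects`, `gene_models`, `expression`
#'   (TPM, individuals x genes), `abc_counts`, `histone_signal`,
#'   `annotation_tracks` and the `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_individuals
  nb <- cfg$chrom_length_bins
  nchr <- cfg$n_chromosomes
  B <- nb * nchr
  inds <- sprintf("ind%03d", seq_len(n))
  chroms <- paste0("chr", seq_len(nchr))

  bins <- data.frame(
    chrom = rep(chroms, each = nb),
    start = rep((seq_len(nb) - 1L) * cfg$bin_size, nchr),
    end = rep(seq_len(nb) * cfg$bin_size, nchr),
    stringsAsFactors = FALSE
  )
  bin_ids <- paste0(bins$chrom, "_", bins$start)

  ## ---- planted domains -------------------------------------------------
  k_per_chr <- diff(round(seq(0, cfg$n_domains, length.out = nchr + 1L)))
  dom_list <- list()
  d_id <- 0L
  for (ci in seq_len(nchr)) {
    k <- k_per_chr[ci]
    if (k == 0L) next
    lens <- sample(seq(cfg$domain_length_bins[1], cfg$domain_length_bins[2]),
                   k, replace = TRUE)
    starts <- place_domains(nb, lens)
    for (i in seq_len(k)) {
      d_id <- d_id + 1L
      dom_list[[d_id]] <- data.frame(
        domain = sprintf("D%02d", d_id), chrom = chroms[ci],
        start_bin = starts[i], end_bin = starts[i] + lens[i],
        stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(dom_list)) do.call(rbind, dom_list) else
    data.frame(domain = character(0), chrom = character(0),
               start_bin = integer(0), end_bin = integer(0))
  D <- nrow(domains)
  n_var <- round(cfg$frac_variable_domains * D)
  var_idx <- if (D > 0L) sort(sample.int(D, n_var)) else integer(0)
  domains$label <- rep("non_variable", D)
  domains$label[var_idx] <- "variable"
  domains$start <- domains$start_bin * cfg$bin_size
  domains$end <- domains$end_bin * cfg$bin_size
  # global bin indices per domain
  chr_offset <- setNames((seq_len(nchr) - 1L) * nb, chroms)
  dom_bins <- lapply(seq_len(D), function(d)
    (chr_offset[domains$chrom[d]] + domains$start_bin[d] + 1L):
      (chr_offset[domains$chrom[d]] + domains$end_bin[d]))

  ## ---- TFs -------------------------------------------------------------
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  tf_sd <- runif(cfg$n_tfs, 0.3, 1.2)
  tf_expression <- sapply(tf_sd, function(s) rnorm(n, 0, s))
  dimnames(tf_expression) <- list(inds, tf_ids)
  tf_domain_effects <- matrix(0, cfg$n_tfs, D, dimnames = list(tf_ids, domains$domain))
  for (d in var_idx) {
    which_tf <- sample.int(cfg$n_tfs, min(cfg$tfs_per_domain, cfg$n_tfs))
    # each regulating TF contributes exactly tf_trans_effect_sd of co-activity
    # SD (random sign); scaling by the TF's own expression SD makes the
    # planted trans variance per domain deterministic
    tf_domain_effects[which_tf, d] <-
      sample(c(-1, 1), length(which_tf), replace = TRUE) *
      cfg$tf_trans_effect_sd / tf_sd[which_tf]
  }

  ## ---- genotypes: domain SNPs with optional LD -------------------------
  snp_rows <- list(); geno_cols <- list(); qtl_rows <- list()
  s_id <- 0L
  for (d in seq_len(D)) {
    maf <- runif(1, cfg$maf_range[1], cfg$maf_range[2])
    pos <- sort(sample(seq(domains$start[d], domains$end[d] - 1L),
                       cfg$n_snps_per_domain))
    h1 <- h2 <- matrix(0L, n, cfg$n_snps_per_domain)
    for (s in seq_len(cfg$n_snps_per_domain)) {
      if (s == 1L || cfg$ld_r == 0) {
        h1[, s] <- rbinom(n, 1L, maf); h2[, s] <- rbinom(n, 1L, maf)
      } else {
        copy1 <- rbinom(n, 1L, cfg$ld_r); copy2 <- rbinom(n, 1L, cfg$ld_r)
        h1[, s] <- ifelse(copy1 == 1L, h1[, s - 1L], rbinom(n, 1L, maf))
        h2[, s] <- ifelse(copy2 == 1L, h2[, s - 1L], rbinom(n, 1L, maf))
      }
    }
    g <- h1 + h2
    ids <- sprintf("snp%04d", s_id + seq_len(cfg$n_snps_per_domain))
    s_id <- s_id + cfg$n_snps_per_domain
    colnames(g) <- ids
    geno_cols[[d]] <- g
    snp_rows[[d]] <- data.frame(id = ids, chrom = domains$chrom[d], pos = pos,
                                maf = maf, domain = domains$domain[d],
                                stringsAsFactors = FALSE)
    beta <- if (domains$label[d] == "variable")
      rnorm(cfg$n_snps_per_domain, 0, cfg$qtl_cis_effect_sd) else
        rep(0, cfg$n_snps_per_domain)
    qtl_rows[[d]] <- data.frame(snp_id = ids, domain = domains$domain[d],
                                beta = beta, stringsAsFactors = FALSE)
  }

  ## ---- per-individual, per-domain co-activity shifts -------------------
  v <- matrix(0, n, max(D, 1L))
  if (D > 0L) {
    for (d in seq_len(D)) {
      v[, d] <- as.vector(tf_expression %*% tf_domain_effects[, d]) +
        as.vector(geno_cols[[d]] %*% qtl_rows[[d]]$beta)
    }
    colnames(v) <- domains$domain
  }

  ## ---- latent fields ---------------------------------------------------
  inc_sd <- if (is.finite(cfg$tau_pd_sim)) 1 / sqrt(cfg$tau_pd_sim) else 0
  pi_sd <- if (is.finite(cfg$tau_pi_sim)) 1 / sqrt(cfg$tau_pi_sim) else 0
  pd_true <- matrix(0, n, B, dimnames = list(inds, bin_ids))
  for (j in seq_len(n)) {
    row <- numeric(B)
    for (ci in seq_len(nchr)) {
      idx <- chr_offset[ci] + seq_len(nb)
      row[idx] <- if (inc_sd > 0) cumsum(rnorm(nb, 0, inc_sd)) else 0
    }
    for (d in seq_len(D))
      row[dom_bins[[d]]] <- row[dom_bins[[d]]] + cfg$domain_activity_shift + v[j, d]
    for (ci in seq_len(nchr)) {
      idx <- chr_offset[ci] + seq_len(nb)
      row[idx] <- row[idx] - mean(row[idx])
    }
    pd_true[j, ] <- row
  }
  pi_true <- matrix(rnorm(n * B, 0, pi_sd), n, B, dimnames = list(inds, bin_ids))

  ## ---- counts ----------------------------------------------------------
  lib_sizes <- exp(runif(n, log(cfg$lib_size_range[1]), log(cfg$lib_size_range[2])))
  s_mill <- lib_sizes / 1e6
  mu <- s_mill * exp(cfg$alpha_sim + pd_true + pi_true)
  counts <- matrix(rnbinom(n * B, mu = mu, size = cfg$theta_sim), n, B,
                   dimnames = list(inds, bin_ids))

  ## ---- gene models and expression --------------------------------------
  gene_rows <- list(); g_id <- 0L
  add_gene <- function(chrom, tss, strand, mean_tpm, domain, ig = FALSE) {
    g_id <<- g_id + 1L
    wid <- sample(2000:20000, 1L)
    start <- if (strand == "+") tss else max(0L, tss - wid)
    end <- if (strand == "+") tss + wid else tss
    nm <- if (ig) sprintf("IGH_sim%02d", g_id) else sprintf("gene%04d", g_id)
    gene_rows[[g_id]] <<- data.frame(
      gene_id = nm, chrom = chrom, tss = tss, strand = strand,
      start = start, end = end, mean_tpm = mean_tpm, domain = domain,
      ig = ig, stringsAsFactors = FALSE)
  }
  for (d in seq_len(D)) {
    m <- sample(seq(cfg$genes_per_domain[1], cfg$genes_per_domain[2]), 1L)
    m <- max(m, 2L)
    tss_bins <- sample(seq(domains$start_bin[d], domains$end_bin[d] - 1L),
                       m, replace = m > (domains$end_bin[d] - domains$start_bin[d]))
    for (b in tss_bins)
      add_gene(domains$chrom[d], b * cfg$bin_size + sample.int(cfg$bin_size, 1L) - 1L,
               sample(c("+", "-"), 1L), exp(runif(1, log(1), log(100))),
               domains$domain[d])
  }
  # expressed genes outside domains (they sit in negative co-activity regions)
  for (ci in seq_len(nchr)) {
    in_dom <- rep(FALSE, nb)
    for (d in which(domains$chrom == chroms[ci]))
      in_dom[(domains$start_bin[d] + 1L):domains$end_bin[d]] <- TRUE
    free_bins <- which(!in_dom) - 1L
    n_bg <- min(cfg$n_background_genes, length(free_bins))
    for (b in sample(free_bins, n_bg))
      add_gene(chroms[ci], b * cfg$bin_size + sample.int(cfg$bin_size, 1L) - 1L,
               sample(c("+", "-"), 1L), exp(runif(1, log(0.5), log(5))), NA_character_)
    if (cfg$n_ig_genes > 0L && ci == 1L) {
      for (b in sample(free_bins, min(cfg$n_ig_genes, length(free_bins))))
        add_gene(chroms[ci], b * cfg$bin_size + 100L, "+", 0.5, NA_character_,
                 ig = TRUE)
    }
  }
  gene_models <- do.call(rbind, gene_rows)
  G <- nrow(gene_models)

  # private eQTLs for background genes
  bg_idx <- which(is.na(gene_models$domain) & !gene_models$ig)
  bg_geno <- list(); bg_snp_rows <- list(); bg_beta <- list()
  for (gi in bg_idx) {
    maf <- runif(1, cfg$maf_range[1], cfg$maf_range[2])
    ids <- sprintf("snp%04d", s_id + 1:2); s_id <- s_id + 2L
    g <- matrix(rbinom(2L * n, 2L, maf), n, 2L, dimnames = list(inds, ids))
    bg_geno[[length(bg_geno) + 1L]] <- g
    bg_snp_rows[[length(bg_snp_rows) + 1L]] <- data.frame(
      id = ids, chrom = gene_models$chrom[gi],
      pos = pmax(0L, gene_models$tss[gi] + sample(-50000:50000, 2L)),
      maf = maf, domain = NA_character_, stringsAsFactors = FALSE)
    bg_beta[[length(bg_beta) + 1L]] <- data.frame(
      snp_id = ids, gene_id = gene_models$gene_id[gi],
      beta = rnorm(2L, 0, cfg$gene_eqtl_effect_sd), stringsAsFactors = FALSE)
  }
  geno_all <- c(geno_cols, bg_geno)
  if (!length(geno_all))
    stop_ca("no SNPs simulated: need domains or background genes")
  genotypes <- do.call(cbind, geno_all)
  rownames(genotypes) <- inds
  snp_table <- do.call(rbind, c(snp_rows, bg_snp_rows))
  qtl_effects <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
    data.frame(snp_id = character(0), domain = character(0), beta = numeric(0))
  gene_eqtl_effects <- if (length(bg_beta)) do.call(rbind, bg_beta) else
    data.frame(snp_id = character(0), gene_id = character(0), beta = numeric(0))

  # per-individual TPM: log expression tracks the centered co-activity at the
  # TSS bin (so domain genes inherit shared TF/QTL effects) plus private
  # eQTLs for background genes, plus gene-level noise
  tss_bin_global <- chr_offset[gene_models$chrom] +
    (gene_models$tss %/% cfg$bin_size) + 1L
  expression <- matrix(0, n, G, dimnames = list(inds, gene_models$gene_id))
  for (gi in seq_len(G)) {
    pd_at <- pd_true[, tss_bin_global[gi]]
    le <- log(gene_models$mean_tpm[gi]) + (pd_at - mean(pd_at)) +
      rnorm(n, 0, cfg$gene_noise_sd)
    expression[, gi] <- exp(le)
  }
  for (k in seq_along(bg_beta)) {
    eff <- bg_beta[[k]]
    gi <- match(eff$gene_id[1], gene_models$gene_id)
    shift <- as.vector(bg_geno[[k]] %*% eff$beta)
    expression[, gi] <- expression[, gi] * exp(shift - mean(shift))
  }

  ## ---- ABC counts, histone, annotation tracks --------------------------
  in_var_gene <- gene_models$domain %in% domains$domain[var_idx]
  abc_counts <- matrix(0L, n, G, dimnames = list(inds, gene_models$gene_id))
  for (gi in seq_len(G)) {
    lam <- rep(exp(0.3), n)
    if (in_var_gene[gi]) {
      vd <- v[, gene_models$domain[gi]]
      lam <- exp(0.3 + 0.5 + 0.3 * (vd - mean(vd)) / max(sd(vd), 1e-8))
    }
    abc_counts[, gi] <- rpois(n, lam)
  }

  in_dom_bin <- rep(FALSE, B)
  for (d in seq_len(D)) in_dom_bin[dom_bins[[d]]] <- TRUE
  histone_signal <- 1 + 0.8 * sweep(pd_true, 2, as.numeric(in_dom_bin), `*`) +
    matrix(rnorm(n * B, 0, 0.3), n, B)
  histone_signal[histone_signal < 0] <- 0
  dimnames(histone_signal) <- list(inds, bin_ids)

  tracks <- sim_annotation_tracks(cfg, bins, domains, var_idx, in_dom_bin,
                                  tf_ids, tf_sd, gene_models)

  truth <- structure(list(
    pd_true = pd_true, pi_true = pi_true,
    domain_intervals = domains[, c("domain", "chrom", "start", "end", "label")],
    tf_expression = tf_expression, tf_sd = setNames(tf_sd, tf_ids),
    tf_domain_effects = tf_domain_effects,
    domain_shifts = v,
    genotypes = genotypes, snp_table = snp_table,
    qtl_effects = qtl_effects, gene_eqtl_effects = gene_eqtl_effects,
    gene_models = gene_models, expression = expression,
    abc_counts = abc_counts, histone_signal = histone_signal,
    annotation_tracks = tracks, config = cfg
  ), class = "sim_truth")

  bc <- binned_counts(counts = counts, bins = bins,
                      lib_size_millions = setNames(s_mill, inds))
  list(truth = truth, counts = bc)
}

# Annotation tracks consistent with the planted domains: open chromatin
# regions denser inside domains, TF binding sites whose enrichment in
# variable domains grows with the TF's expression variability, TAD
# boundaries near domain edges, co-varying chromatin modules covering
# variable domains, and non-overlapping compartment classes.
sim_annotation_tracks <- function(cfg, bins, domains, var_idx, in_dom_bin,
                                  tf_ids, tf_sd, gene_models) {
  B <- nrow(bins)
  in_var_bin <- rep(FALSE, B)
  nchr <- cfg$n_chromosomes; nb <- cfg$chrom_length_bins
  chr_offset <- setNames((seq_len(nchr) - 1L) * nb, paste0("chr", seq_len(nchr)))
  for (d in var_idx) {
    idx <- chr_offset[domains$chrom[d]] +
      (domains$start_bin[d] + 1L):domains$end_bin[d]
    in_var_bin[idx] <- TRUE
  }
  # OCRs: Poisson counts per bin at the densities observed in LCL data
  n_ocr <- rpois(B, ifelse(in_dom_bin, 0.93, 0.27))
  ocr_bin <- rep(seq_len(B), n_ocr)
  ocr_off <- vapply(ocr_bin, function(i) sample.int(cfg$bin_size - 600L, 1L), 1L)
  ocr <- data.frame(chrom = bins$chrom[ocr_bin],
                    start = bins$start[ocr_bin] + ocr_off,
                    end = bins$start[ocr_bin] + ocr_off + 600L,
                    name = sprintf("ocr%05d", seq_along(ocr_bin)),
                    in_variable = in_var_bin[ocr_bin],
                    stringsAsFactors = FALSE)
  # TFBS: binding probability higher in variable-domain OCRs for
  # variably expressed TFs (plants a positive OR-vs-CoV coupling)
  tfbs_rows <- list()
  for (t in seq_along(tf_ids)) {
    p <- stats::plogis(stats::qlogis(0.12) + 1.0 * tf_sd[t] * ocr$in_variable)
    hit <- runif(nrow(ocr)) < p
    if (any(hit))
      tfbs_rows[[t]] <- data.frame(chrom = ocr$chrom[hit], start = ocr$start[hit],
                                   end = ocr$end[hit], name = tf_ids[t],
                                   stringsAsFactors = FALSE)
  }
  # promoter TFBSs so TFs have annotated target genes
  in_var_gene <- gene_models$domain %in% domains$domain[var_idx]
  for (t in seq_along(tf_ids)) {
    p <- stats::plogis(stats::qlogis(0.15) + 1.0 * tf_sd[t] * in_var_gene)
    hit <- runif(nrow(gene_models)) < p
    if (any(hit)) {
      tss <- gene_models$tss[hit]
      tfbs_rows[[length(tfbs_rows) + 1L]] <- data.frame(
        chrom = gene_models$chrom[hit], start = pmax(0L, tss - 100L),
        end = tss + 100L, name = tf_ids[t], stringsAsFactors = FALSE)
    }
  }
  tfbs <- do.call(rbind, tfbs_rows)
  tfbs <- tfbs[order(tfbs$chrom, tfbs$start), , drop = FALSE]
  rownames(tfbs) <- NULL
  # TAD boundaries: near domain edges plus uniform background
  edge_pos <- c(domains$start, domains$end)
  edge_chrom <- rep(domains$chrom, 2L)
  keep <- runif(length(edge_pos)) < 0.7
  tad_pos <- pmax(0, round(edge_pos[keep] + rnorm(sum(keep), 0, 20000)))
  tad_chrom <- edge_chrom[keep]
  n_rand <- max(2L, round(0.3 * length(tad_pos)))
  tad_pos <- c(tad_pos, sample.int(nb * cfg$bin_size, n_rand))
  tad_chrom <- c(tad_chrom, sample(paste0("chr", seq_len(nchr)), n_rand, TRUE))
  tad <- data.frame(chrom = tad_chrom, start = tad_pos, end = tad_pos + 1L,
                    stringsAsFactors = FALSE)
  tad <- tad[order(tad$chrom, tad$start), , drop = FALSE]
  rownames(tad) <- NULL
  # VCMs: cover most of each variable domain
  vcm_rows <- list()
  for (d in var_idx) {
    w <- domains$end[d] - domains$start[d]
    vcm_rows[[length(vcm_rows) + 1L]] <- data.frame(
      chrom = domains$chrom[d],
      start = domains$start[d] + round(0.05 * w),
      end = domains$start[d] + round(0.90 * w), stringsAsFactors = FALSE)
  }
  for (k in seq_len(3L)) {
    ci <- sample.int(nchr, 1L)
    st <- sample.int(nb * cfg$bin_size - 60000L, 1L)
    vcm_rows[[length(vcm_rows) + 1L]] <- data.frame(
      chrom = paste0("chr", ci), start = st, end = st + 50000L,
      stringsAsFactors = FALSE)
  }
  vcm <- do.call(rbind, vcm_rows)
  # compartments: domain union = active; the gaps alternate between
  # facultative and constitutive heterochromatin (non-overlapping)
  comp_rows <- list(); flip <- TRUE
  for (ci in seq_len(nchr)) {
    chrom <- paste0("chr", ci)
    dd <- domains[domains$chrom == chrom, , drop = FALSE]
    dd <- dd[order(dd$start), , drop = FALSE]
    pos <- 0L
    for (i in seq_len(nrow(dd))) {
      if (dd$start[i] > pos) {
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = dd$start[i],
          class = if (flip) "facultative" else "constitutive",
          stringsAsFactors = FALSE)
        flip <- !flip
      }
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        chrom = chrom, start = dd$start[i], end = dd$end[i], class = "active",
        stringsAsFactors = FALSE)
      pos <- dd$end[i]
    }
    if (pos < nb * cfg$bin_size) {
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = nb * cfg$bin_size,
        class = if (flip) "facultative" else "constitutive",
        stringsAsFactors = FALSE)
      flip <- !flip
    }
  }
  list(ocr = ocr[, c("chrom", "start", "end", "name")],
       tfbs = tfbs, tad_boundaries = tad, vcm = vcm,
       compartments = do.call(rbind, comp_rows))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic co-activity dataset (ground truth)\n")
  cat(sprintf("  %d individuals x %d bins; %d domains (%d variable)\n",
              nrow(x$pd_true), ncol(x$pd_true), nrow(x$domain_intervals),
              sum(x$domain_intervals$label == "variable")))
  cat(sprintf("  %d TFs, %d SNPs, %d genes\n", ncol(x$tf_expression),
              ncol(x$genotypes), nrow(x$gene_models)))
  invisible(x)
}
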