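# Shared small fixtures, built once per test file.

small_sim_cache <- new.env()

# A compact simulated dataset: 20 individuals, 1 chromosome x 400 bins,
# 5 domains. Cached so several tests can reuse it.
small_sim <- function() {
  if (is.null(small_sim_cache$sim))
    small_sim_cache$sim <- simulate_dataset(sim_config(
      n_individuals = 20L, n_chromosomes = 1L, chrom_length_bins = 400L,
      n_domains = 5L, n_tfs = 6L, n_background_genes = 4L, seed = 42L))
  small_sim_cache$sim
}

# Decomposition fit of the small dataset (posterior means only).
small_fit <- function() {
  if (is.null(small_sim_cache$fit)) {
    sim <- small_sim()
    qc <- qc_filter_libraries(sim$counts)
    plan <- plan_segments(qc$counts)
    small_sim_cache$qc <- qc
    small_sim_cache$plan <- plan
    small_sim_cache$fit <- fit_decomposition(
      qc$counts, plan,
      model_hyperparams(theta_init = sim$truth$config$theta_sim,
                        variances = "none"))
  }
  small_sim_cache$fit
}

# Two-sided Fisher p by hypergeometric enumeration (independent oracle).
fisher_p_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n2):min(k, m)
  d <- dhyper(supp, m, n2, k)
  sum(d[d <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
}

# Two-pass Pearson correlation (independent of stats::cor).
two_pass_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force reference LD pruning over an explicit removal list.
brute_ld_prune <- function(q, dosages, thr = 0.8) {
  q <- q[order(q$p, -abs(q$t_stat), q$snp_id), , drop = FALSE]
  keep <- character(0); removed <- character(0)
  for (i in seq_len(nrow(q))) {
    id <- q$snp_id[i]
    if (id %in% removed) next
    keep <- c(keep, id)
    rest <- setdiff(q$snp_id, c(keep, removed))
    if (length(rest)) {
      r <- abs(suppressWarnings(cor(dosages[, id], dosages[, rest, drop = FALSE])))
      r[is.na(r)] <- 0
      removed <- c(removed, rest[as.vector(r) > thr])
    }
  }
  keep
}

# Penalized objective and gradient in the reduced (constraint-eliminated)
# parameterization, for generic-optimizer oracles: u = (PD[1..N-1], PI, alpha),
# PD[N] = -sum(PD[1..N-1]).
reduced_objective <- function(u, y, s, theta, tau_pd, tau_pi) {
  N <- length(y)
  pd <- c(u[seq_len(N - 1L)], -sum(u[seq_len(N - 1L)]))
  pi_ <- u[N - 1L + seq_len(N)]
  alpha <- u[2L * N]
  eta <- log(s) + alpha + pd + pi_
  ll <- sum(dnbinom(y, mu = exp(eta), size = theta, log = TRUE))
  -(ll - (tau_pd / 2) * sum(diff(pd)^2) - (tau_pi / 2) * sum(pi_^2))
}

reduced_gradient <- function(u, y, s, theta, tau_pd, tau_pi) {
  N <- length(y)
  pd <- c(u[seq_len(N - 1L)], -sum(u[seq_len(N - 1L)]))
  pi_ <- u[N - 1L + seq_len(N)]
  alpha <- u[2L * N]
  m <- exp(log(s) + alpha + pd + pi_)
  g_ll <- y - (y + theta) * m / (theta + m)
  d2 <- diff(pd)
  g_pd_full <- g_ll - tau_pd * c(-d2[1], d2[-(N - 1L)] - d2[-1], d2[N - 1L])
  g_pd <- g_pd_full[seq_len(N - 1L)] - g_pd_full[N]
  g_pi <- g_ll - tau_pi * pi_
  -c(g_pd, g_pi, sum(g_ll))
}

# Oracle MAP for one segment via a generic quasi-Newton optimizer.
oracle_segment_map <- function(y, s, theta, tau_pd, tau_pi, start = NULL) {
  N <- length(y)
  u0 <- start %||% c(rep(0, N - 1L), rep(0, N), log(mean(y) / s + 1e-9))
  fit <- optim(u0, reduced_objective, reduced_gradient, y = y, s = s,
               theta = theta, tau_pd = tau_pd, tau_pi = tau_pi,
               method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  u <- fit$par
  list(pd = c(u[seq_len(N - 1L)], -sum(u[seq_len(N - 1L)])),
       pi = u[N - 1L + seq_len(N)], alpha = u[2L * N],
       value = -fit$value, convergence = fit$convergence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
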