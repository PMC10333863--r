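#' Hyperparameters of the transcriptional decomposition model
#'
#' The model for a chromosome segment of N bins in one individual is
#' \deqn{y_i ~ NB(mean = s e^{alpha + PD_i + PI_i}, size = theta)}
#' with `s` the library size in millions of reads, `PD` a first-order random
#' walk (co-activity) penalized by precision `tau_pd` on its increments,
#' `PI` iid Gaussian with precision `tau_pi`, and the identifiability
#' constraint `sum(PD) = 0`. Both precisions are fixed; the printed defaults
#' -5 and -1 are interpreted as log-precisions (`tau = exp(value)`), but a
#' raw-precision reading is supported through `tau_scale = "raw"`.
#'
#' @param log_tau_pd log-precision of the random-walk increments
#'   (default -5).
#' @param log_tau_pi log-precision of the iid component (default -1).
#' @param tau_scale `"log"` (tau = exp(value)) or `"raw"` (value used as the
#'   precision directly; must then be positive).
#' @param theta_init initial (or fixed) NB overdispersion, > 0.
#' @param theta_mode `"fixed"` or `"estimated"` (profile update of theta by
#'   maximum likelihood between Newton passes).
#' @param max_newton_iter maximum Newton iterations per fit.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param laplace_samples if > 0, posterior variances are estimated from this
#'   many Gaussian draws at the mode; 0 uses the analytic Laplace variances
#'   (diagonal of the constrained inverse Hessian).
#' @param variances one of `"analytic"`, `"none"`; `"none"` skips the
#'   (dense) variance computation, useful for long segments when only the
#'   posterior means are needed.
#' @param alpha_floor lower bound on the intercept, so all-zero segments
#'   return a finite level.
#' @return object of class `model_hyperparams`.
#' @export
model_hyperparams <- function(log_tau_pd = -5, log_tau_pi = -1,
                              tau_scale = c("log", "raw"),
                              theta_init = 10, theta_mode = c("fixed", "estimated"),
                              max_newton_iter = 100L, tol = 1e-8,
                              laplace_samples = 0L,
                              variances = c("analytic", "none"),
                              alpha_floor = -30) {
  tau_scale <- match.arg(tau_scale)
  theta_mode <- match.arg(theta_mode)
  variances <- match.arg(variances)
  check_scalar_number(log_tau_pd, "log_tau_pd")
  check_scalar_number(log_tau_pi, "log_tau_pi")
  tau_pd <- if (tau_scale == "log") exp(log_tau_pd) else log_tau_pd
  tau_pi <- if (tau_scale == "log") exp(log_tau_pi) else log_tau_pi
  if (!is.finite(tau_pd) || tau_pd <= 0 || !is.finite(tau_pi) || tau_pi <= 0)
    stop_ca("precisions must be finite and positive on the chosen scale")
  if (theta_init <= 0) stop_ca("'theta_init' must be positive")
  if (tol <= 0) stop_ca("'tol' must be positive")
  structure(list(log_tau_pd = log_tau_pd, log_tau_pi = log_tau_pi,
                 tau_pd = tau_pd, tau_pi = tau_pi, tau_scale = tau_scale,
                 theta_init = theta_init, theta_mode = theta_mode,
                 max_newton_iter = check_count(max_newton_iter, "max_newton_iter"),
                 tol = tol, laplace_samples = check_count(laplace_samples,
                                                          "laplace_samples", 0L),
                 variances = variances, alpha_floor = alpha_floor),
            class = "model_hyperparams")
}

#' Library quality control by empty-bin count
#'
#' Removes individuals whose number of empty (zero-count) bins lies more than
#' two standard deviations away from the mean across libraries (two-sided).
#'
#' @param counts a [binned_counts()] object with at least 3 individuals.
#' @param n_sd multiple of the standard deviation defining the exclusion band.
#' @return a list with `counts` (filtered [binned_counts()]) and `excluded`
#'   (data.frame of excluded individuals with their empty-bin tallies).
#' @export
qc_filter_libraries <- function(counts, n_sd = 2) {
  stopifnot(inherits(counts, "binned_counts"))
  if (nrow(counts$counts) < 3L) stop_ca("library QC needs at least 3 individuals")
  keep_bins <- setdiff(seq_len(ncol(counts$counts)), counts$excluded_bins)
  tally <- rowSums(counts$counts[, keep_bins, drop = FALSE] == 0)
  mu <- mean(tally); s <- sd(tally)
  bad <- if (s == 0) rep(FALSE, length(tally)) else
    tally > mu + n_sd * s | tally < mu - n_sd * s
  if (all(bad)) stop_ca("library QC excluded every individual")
  excluded <- data.frame(individual = rownames(counts$counts)[bad],
                         empty_bins = unname(tally[bad]))
  filtered <- binned_counts(counts$counts[!bad, , drop = FALSE], counts$bins,
                            counts$lib_size_millions[!bad], counts$excluded_bins)
  list(counts = filtered, excluded = excluded,
       mean_empty = mu, sd_empty = s)
}

#' Bins overlapping immunoglobulin (VDJ) gene segments
#'
#' Read mapping in VDJ-recombined regions (immunoglobulin heavy, kappa and
#' lambda loci) is biased, so bins overlapping flagged gene segments are
#' excluded from the analysis. A gene is flagged by a logical `ig` column or,
#' failing that, by an IGH/IGK/IGL gene-id prefix.
#'
#' @param bins bin coordinate data.frame (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param gene_models gene table with `chrom`, `start`, `end` and either an
#'   `ig` flag or `gene_id`.
#' @return sorted integer indices of bins to exclude (possibly empty).
#' @export
mask_vdj_bins <- function(bins, gene_models) {
  flagged <- if ("ig" %in% names(gene_models)) gene_models$ig else
    grepl("^IG[HKL]", gene_models$gene_id)
  gm <- gene_models[flagged, , drop = FALSE]
  if (nrow(gm) == 0L) return(integer(0))
  out <- integer(0)
  for (k in seq_len(nrow(gm))) {
    hit <- which(bins$chrom == gm$chrom[k] & bins$start < gm$end[k] &
                   gm$start[k] < bins$end)
    out <- c(out, hit)
  }
  sort(unique(out))
}

#' Plan chromosome segments for decomposition
#'
#' Per chromosome, the two longest runs of bins with no mapped reads in any
#' retained individual are removed (ties broken by leftmost start); the
#' remaining contiguous stretches are split greedily left-to-right into
#' pieces of at most `max_segment_bins`, preferring a split at an internal
#' zero-coverage bin when one exists within the last 10% of a piece, and
#' splitting hard at the maximum otherwise. Bins listed in
#' `counts$excluded_bins` are treated as gaps.
#'
#' @param counts a [binned_counts()] object.
#' @param max_segment_bins maximum bins per segment (default 7500).
#' @return object of class `segment_plan`: list with `segments`
#'   (data.frame `chrom`, `first_bin`, `last_bin` as global bin indices),
#'   `removed_gaps`, and `max_segment_bins`.
#' @export
plan_segments <- function(counts, max_segment_bins = 7500L) {
  stopifnot(inherits(counts, "binned_counts"))
  totals <- colSums(counts$counts)
  bins <- counts$bins
  avail <- !(seq_along(totals) %in% counts$excluded_bins)
  seg_rows <- list(); gap_rows <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    zero <- totals[idx] == 0 & avail[idx]
    runs <- true_runs(zero)
    removed <- rep(FALSE, length(idx))
    if (nrow(runs) > 0L) {
      lens <- runs$end - runs$start + 1L
      ord <- order(-lens, runs$start)
      take <- head(ord, 2L)
      for (r in take) removed[runs$start[r]:runs$end[r]] <- TRUE
      for (r in take)
        gap_rows[[length(gap_rows) + 1L]] <- data.frame(
          chrom = ch, first_bin = idx[runs$start[r]], last_bin = idx[runs$end[r]],
          reason = "zero_run")
    }
    if (all(removed | !avail[idx])) {
      warning(sprintf("chromosome %s has no informative bins; no segments planned", ch))
      next
    }
    usable <- avail[idx] & !removed
    stretches <- true_runs(usable)
    for (r in seq_len(nrow(stretches))) {
      lo <- stretches$start[r]; hi <- stretches$end[r]
      while (hi - lo + 1L > max_segment_bins) {
        win_lo <- lo + as.integer(floor(0.9 * max_segment_bins))
        win_hi <- lo + max_segment_bins - 1L
        zwin <- which(totals[idx[win_lo:win_hi]] == 0)
        cut <- if (length(zwin) > 0L) win_lo + max(zwin) - 1L else win_hi
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          chrom = ch, first_bin = idx[lo], last_bin = idx[cut])
        lo <- cut + 1L
      }
      if (hi - lo + 1L >= 2L)
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          chrom = ch, first_bin = idx[lo], last_bin = idx[hi])
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(chrom = character(0), first_bin = integer(0), last_bin = integer(0))
  removed_gaps <- if (length(gap_rows)) do.call(rbind, gap_rows) else
    data.frame(chrom = character(0), first_bin = integer(0), last_bin = integer(0),
               reason = character(0))
  structure(list(segments = segments, removed_gaps = removed_gaps,
                 max_segment_bins = as.integer(max_segment_bins)),
            class = "segment_plan")
}

#' @export
print.segment_plan <- function(x, ...) {
  cat(sprintf("Segment plan: %d segment(s), %d removed gap(s), max %d bins\n",
              nrow(x$segments), nrow(x$removed_gaps), x$max_segment_bins))
  invisible(x)
}

# Penalized NB log-likelihood of one segment at parameters (pd, pi, alpha).
segment_objective <- function(pd, pi_, alpha, y, log_s, theta, tau_pd, tau_pi) {
  eta <- pmin(log_s + alpha + pd + pi_, 30)
  ll <- sum(dnbinom(y, mu = exp(eta), size = theta, log = TRUE))
  ll - (tau_pd / 2) * sum(diff(pd)^2) - (tau_pi / 2) * sum(pi_^2)
}

# MAP fit of one segment for one individual by Newton iterations on the
# sparse KKT system (tridiagonal RW1 block + diagonal iid block + dense
# intercept row, plus the sum-to-zero constraint on PD).
fit_segment_map <- function(y, s, theta, hyper) {
  N <- length(y)
  if (N < 2L) stop_ca("segments must have at least 2 bins")
  tau_pd <- hyper$tau_pd; tau_pi <- hyper$tau_pi
  log_s <- log(s)
  if (all(y == 0)) {
    res <- list(pd = rep(0, N), pi = rep(0, N), alpha = hyper$alpha_floor,
                theta = theta, iterations = 0L, grad_norm = 0,
                converged = TRUE, degenerate = TRUE)
    if (hyper$variances == "analytic") { res$pd_var <- rep(0, N); res$pi_var <- rep(0, N) }
    return(res)
  }
  # RW1 structure matrix (tridiagonal)
  di <- c(1, rep(2, N - 2L), 1)
  K <- Matrix::sparseMatrix(i = c(seq_len(N), seq_len(N - 1L), 2:N),
                            j = c(seq_len(N), 2:N, seq_len(N - 1L)),
                            x = c(di, rep(-1, 2L * (N - 1L))), dims = c(N, N))
  pd <- rep(0, N); pi_ <- rep(0, N)
  alpha <- max(log(mean(y) / s), hyper$alpha_floor)
  obj <- segment_objective(pd, pi_, alpha, y, log_s, theta, tau_pd, tau_pi)
  obj_trace <- obj
  iter <- 0L; gmax <- Inf; converged <- FALSE
  a_con <- c(rep(1, N), rep(0, N), 0)  # constraint row: sum(PD) = 0
  ridge <- 1e-10
  repeat {
    iter <- iter + 1L
    eta <- pmin(log_s + alpha + pd + pi_, 30)
    m <- exp(eta)
    g_ll <- y - (y + theta) * m / (theta + m)
    w <- (y + theta) * theta * m / (theta + m)^2 + ridge
    grad <- c(g_ll - tau_pd * as.vector(K %*% pd),
              g_ll - tau_pi * pi_,
              sum(g_ll))
    gmax <- max(abs(c(grad[seq_len(N)] - mean(grad[seq_len(N)]),
                      grad[-seq_len(N)])))
    if (gmax < hyper$tol) { converged <- TRUE; break }
    if (iter > hyper$max_newton_iter) break
    W <- Matrix::Diagonal(x = w)
    H <- rbind(
      cbind(W + tau_pd * K, W, Matrix::Matrix(w, N, 1)),
      cbind(W, W + tau_pi * Matrix::Diagonal(N), Matrix::Matrix(w, N, 1)),
      cbind(Matrix::Matrix(w, 1, N), Matrix::Matrix(w, 1, N), sum(w))
    )
    M <- rbind(cbind(H, a_con), c(a_con, 0))
    rhs <- c(grad, -sum(pd))
    delta <- tryCatch(as.vector(Matrix::solve(M, rhs)),
                      error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1; accepted <- FALSE
    for (h in seq_len(30L)) {
      pd_n <- pd + step * delta[seq_len(N)]
      pi_n <- pi_ + step * delta[N + seq_len(N)]
      al_n <- max(alpha + step * delta[2L * N + 1L], hyper$alpha_floor)
      obj_n <- segment_objective(pd_n, pi_n, al_n, y, log_s, theta, tau_pd, tau_pi)
      if (is.finite(obj_n) && obj_n >= obj - 1e-12) {
        pd <- pd_n; pi_ <- pi_n; alpha <- al_n
        obj <- obj_n
        obj_trace <- c(obj_trace, obj)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  res <- list(pd = pd, pi = pi_, alpha = alpha, theta = theta,
              iterations = iter, grad_norm = gmax, converged = converged,
              degenerate = FALSE, objective = obj, obj_trace = obj_trace)
  if (hyper$variances == "analytic") {
    eta <- pmin(log_s + alpha + pd + pi_, 30)
    m <- exp(eta)
    w <- (y + theta) * theta * m / (theta + m)^2 + ridge
    W <- Matrix::Diagonal(x = w)
    H <- rbind(
      cbind(W + tau_pd * K, W, Matrix::Matrix(w, N, 1)),
      cbind(W, W + tau_pi * Matrix::Diagonal(N), Matrix::Matrix(w, N, 1)),
      cbind(Matrix::Matrix(w, 1, N), Matrix::Matrix(w, 1, N), sum(w))
    )
    M <- as.matrix(rbind(cbind(H, a_con), c(a_con, 0)))
    Sig <- tryCatch(solve(M), error = function(e) NULL)
    if (!is.null(Sig)) {
      dv <- diag(Sig)
      if (hyper$laplace_samples > 0L) {
        # variance from Gaussian draws at the mode (constrained covariance)
        S2 <- Sig[seq_len(2L * N), seq_len(2L * N)]
        ev <- eigen((S2 + t(S2)) / 2, symmetric = TRUE)
        L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
        Z <- L %*% matrix(rnorm(2L * N * hyper$laplace_samples),
                          2L * N, hyper$laplace_samples)
        vv <- apply(Z, 1, var)
        res$pd_var <- vv[seq_len(N)]; res$pi_var <- vv[N + seq_len(N)]
      } else {
        res$pd_var <- pmax(dv[seq_len(N)], 0)
        res$pi_var <- pmax(dv[N + seq_len(N)], 0)
      }
    } else {
      res$pd_var <- rep(NA_real_, N); res$pi_var <- rep(NA_real_, N)
    }
  }
  res
}

#' Fit the transcriptional decomposition model
#'
#' For every individual and chromosome segment, maximizes the penalized
#' negative binomial log-likelihood
#' \deqn{L = sum_i log NB(y_i | s e^{alpha + PD_i + PI_i}, theta)
#'       - (tau_PD/2) sum_{i>1} (PD_i - PD_{i-1})^2 - (tau_PI/2) sum_i PI_i^2}
#' subject to `sum(PD) = 0`, by Newton iterations on the sparse Hessian with
#' step halving. Posterior variances come from the diagonal of the
#' constrained inverse Hessian at the mode (Laplace approximation), or from
#' Gaussian draws when `laplace_samples > 0`. The exported co-activity score
#' is the posterior mean of the positionally dependent component `PD`.
#'
#' @param counts a [binned_counts()] object (after library QC).
#' @param plan a [plan_segments()] result; computed from `counts` if NULL.
#' @param hyper a [model_hyperparams()] object.
#' @return object of class `td_fit` with matrices `pd_mean`, `pd_var`,
#'   `pi_mean`, `pi_var` (individuals x bins; NA outside fitted segments),
#'   `alpha` (individuals x segments), `theta` (per individual),
#'   `convergence` (per fit), and the inputs needed by the methods.
#' @seealso [coactivity_matrix()], [summary.td_fit()]
#' @export
fit_decomposition <- function(counts, plan = NULL, hyper = model_hyperparams()) {
  stopifnot(inherits(counts, "binned_counts"))
  if (is.null(plan)) plan <- plan_segments(counts)
  stopifnot(inherits(plan, "segment_plan"))
  if (!inherits(hyper, "model_hyperparams")) hyper <- do.call(model_hyperparams, hyper)
  n <- nrow(counts$counts); B <- ncol(counts$counts)
  inds <- rownames(counts$counts) %||% sprintf("ind%03d", seq_len(n))
  segs <- plan$segments
  pd_mean <- pi_mean <- pd_var <- pi_var <- fitted_mu <-
    matrix(NA_real_, n, B, dimnames = list(inds, colnames(counts$counts)))
  alpha <- matrix(NA_real_, n, nrow(segs),
                  dimnames = list(inds, paste0("seg", seq_len(nrow(segs)))))
  theta <- setNames(rep(hyper$theta_init, n), inds)
  conv <- list()
  for (j in seq_len(n)) {
    s <- counts$lib_size_millions[j]
    th <- hyper$theta_init
    if (hyper$theta_mode == "estimated")
      th <- profile_theta(counts$counts[j, ], segs, th)
    for (g in seq_len(nrow(segs))) {
      idx <- segs$first_bin[g]:segs$last_bin[g]
      fit <- fit_segment_map(counts$counts[j, idx], s, th, hyper)
      pd_mean[j, idx] <- fit$pd
      pi_mean[j, idx] <- fit$pi
      if (!is.null(fit$pd_var)) {
        pd_var[j, idx] <- fit$pd_var
        pi_var[j, idx] <- fit$pi_var
      }
      fitted_mu[j, idx] <- s * exp(fit$alpha + fit$pd + fit$pi)
      alpha[j, g] <- fit$alpha
      conv[[length(conv) + 1L]] <- data.frame(
        individual = inds[j], segment = g, iterations = fit$iterations,
        grad_norm = fit$grad_norm, converged = fit$converged,
        degenerate = fit$degenerate)
      if (!fit$converged)
        warning(sprintf("fit for %s segment %d did not converge (grad %.2e)",
                        inds[j], g, fit$grad_norm))
    }
    theta[j] <- th
  }
  structure(list(pd_mean = pd_mean, pd_var = pd_var, pi_mean = pi_mean,
                 pi_var = pi_var, alpha = alpha, theta = theta,
                 fitted_mean = fitted_mu,
                 convergence = do.call(rbind, conv), plan = plan,
                 bins = counts$bins, counts = counts$counts,
                 lib_size_millions = counts$lib_size_millions,
                 excluded_bins = counts$excluded_bins, hyper = hyper),
            class = "td_fit")
}

# Profile the NB overdispersion for one individual. The latent fields can
# absorb bin-level noise under weak priors, which leaves theta unidentified
# against the fitted means; instead theta is estimated by ML against a
# fixed-bandwidth moving-average mean, which tracks the smooth field but
# averages out count noise. Pooled over all segments.
profile_theta <- function(y_row, segs, th0, window = 11L) {
  y_all <- mu_all <- numeric(0)
  for (g in seq_len(nrow(segs))) {
    y <- y_row[segs$first_bin[g]:segs$last_bin[g]]
    if (all(y == 0) || length(y) < window) next
    mu_loc <- stats::filter(y, rep(1 / window, window), sides = 2)
    ok <- !is.na(mu_loc) & mu_loc > 0
    y_all <- c(y_all, y[ok])
    mu_all <- c(mu_all, as.numeric(mu_loc[ok]))
  }
  if (length(y_all) < 3L * window) return(th0)
  est <- withCallingHandlers(
    tryCatch(as.numeric(MASS::theta.ml(y_all, mu_all, limit = 50)),
             error = function(e) th0),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.finite(est) && est > 0) est else th0
}

#' Extract the co-activity score matrix
#'
#' Returns the posterior mean of the positionally dependent component, with
#' excluded or unfitted bins as missing values (never zero). Columns follow
#' the bin order of the input counts.
#'
#' @param result a fitted [fit_decomposition()] object.
#' @return numeric matrix, individuals x bins.
#' @export
coactivity_matrix <- function(result) {
  stopifnot(inherits(result, "td_fit"))
  m <- result$pd_mean
  if (length(result$excluded_bins)) m[, result$excluded_bins] <- NA_real_
  m
}

#' @export
print.td_fit <- function(x, ...) {
  cat("Transcriptional decomposition fit\n")
  cat(sprintf("  %d individuals x %d bins in %d segment(s)\n",
              nrow(x$pd_mean), ncol(x$pd_mean), nrow(x$plan$segments)))
  cat(sprintf("  tau_PD = %.4g, tau_PI = %.4g, theta %s (median %.3g)\n",
              x$hyper$tau_pd, x$hyper$tau_pi,
              x$hyper$theta_mode, median(x$theta)))
  cat(sprintf("  %d/%d fits converged\n", sum(x$convergence$converged),
              nrow(x$convergence)))
  invisible(x)
}

#' Summarize a decomposition fit
#'
#' Reports cross-individual correlation of the component scores (a QC for
#' comparability of fits across individuals), overdispersion estimates and
#' convergence.
#'
#' @param object a `td_fit`.
#' @param ... unused.
#' @return object of class `summary.td_fit`.
#' @export
summary.td_fit <- function(object, ...) {
  pair_cor <- function(m) {
    ok <- colSums(is.na(m)) == 0
    if (sum(ok) < 2L || nrow(m) < 2L) return(NA_real_)
    cc <- cor(t(m[, ok, drop = FALSE]))
    mean(cc[upper.tri(cc)])
  }
  out <- list(
    n_individuals = nrow(object$pd_mean),
    n_bins_fitted = sum(colSums(!is.na(object$pd_mean)) > 0),
    mean_pairwise_pcc_pd = pair_cor(object$pd_mean),
    mean_pairwise_pcc_pi = pair_cor(object$pi_mean),
    theta = summary(object$theta),
    n_converged = sum(object$convergence$converged),
    n_fits = nrow(object$convergence),
    hyper = object$hyper)
  class(out) <- "summary.td_fit"
  out
}

#' @export
print.summary.td_fit <- function(x, ...) {
  cat("Transcriptional decomposition summary\n")
  cat(sprintf("  individuals: %d, fitted bins: %d\n", x$n_individuals,
              x$n_bins_fitted))
  cat(sprintf("  mean pairwise PCC: co-activity %.3f, independent %.3f\n",
              x$mean_pairwise_pcc_pd, x$mean_pairwise_pcc_pi))
  cat(sprintf("  converged fits: %d/%d\n", x$n_converged, x$n_fits))
  invisible(x)
}

#' @export
coef.td_fit <- function(object, ...) {
  list(alpha = object$alpha, theta = object$theta)
}

#' @export
fitted.td_fit <- function(object, ...) object$fitted_mean

#' @export
residuals.td_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted_mean
  r <- object$counts - mu
  if (type == "pearson") {
    th <- matrix(object$theta, nrow(mu), ncol(mu))
    r <- r / sqrt(mu + mu^2 / th)
  }
  r
}

#' @export
simulate.td_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted_mean
  th <- object$theta
  lapply(seq_len(nsim), function(k) {
    y <- mu
    for (j in seq_len(nrow(mu))) {
      ok <- is.finite(mu[j, ])
      y[j, ok] <- rnbinom(sum(ok), mu = mu[j, ok], size = th[j])
    }
    y
  })
}

#' Plot decomposition components along a chromosome
#' @param x a `td_fit`.
#' @param individual row index or name.
#' @param chrom chromosome to show (first by default).
#' @param ... passed to [plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plot.td_fit <- function(x, individual = 1L, chrom = NULL, ...) {
  chrom <- chrom %||% x$bins$chrom[1]
  idx <- which(x$bins$chrom == chrom)
  pos <- x$bins$start[idx] / 1e6
  pd <- x$pd_mean[individual, idx]
  pi_ <- x$pi_mean[individual, idx]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(pos, pd, type = "l", xlab = "", ylab = "co-activity (PD)",
       main = chrom, ...)
  graphics::abline(h = 0, lty = 3)
  plot(pos, pi_, type = "h", xlab = "position (Mb)", ylab = "independent (PI)",
       ...)
  invisible(data.frame(pos = pos, pd = pd, pi = pi_))
}
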