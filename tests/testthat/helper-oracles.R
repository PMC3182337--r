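# Independent oracles used across test files.  These deliberately avoid the
# package's own profiled/Woodbury code paths: the REML oracle builds the full
# marginal covariance matrix per subject and optimizes raw variance
# parameters with a generic derivative-free optimizer; the BH oracle is the
# literal sort / step-up / remap recipe.

# -2 x restricted log-likelihood at raw variance parameters, full matrices.
neg2reml_direct <- function(par, long, powers, random, offset) {
  # par: log(sigma_e^2) followed by the log-Cholesky of G
  X <- cbind(1, fpgcm::fp_transform(long$time_hours + offset, powers))
  P <- ncol(X)
  Q <- if (random == "slopes") P else 1L
  s2 <- exp(par[1L])
  L <- matrix(0, Q, Q)
  L[lower.tri(L, diag = TRUE)] <- par[-1L]
  diag(L) <- exp(diag(L))
  G <- tcrossprod(L)
  subj <- factor(long$subject_id)
  V <- matrix(0, nrow(long), nrow(long))
  for (s in levels(subj)) {
    ii <- which(subj == s)
    Z <- X[ii, seq_len(Q), drop = FALSE]
    V[ii, ii] <- Z %*% G %*% t(Z) + s2 * diag(length(ii))
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi <- chol2inv(ch)
  XtVX <- t(X) %*% Vi %*% X
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(1e10)
  beta <- solve(XtVX, t(X) %*% Vi %*% long$value)
  r <- long$value - X %*% beta
  as.numeric(
    2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
      t(r) %*% Vi %*% r + (nrow(long) - P) * log(2 * pi)
  )
}

# Brute-force maximization of the direct REML objective (multi-start
# Nelder-Mead over raw parameters); returns the maximized log-likelihood.
oracle_reml_loglik <- function(long, powers, random = "intercept", offset = 0) {
  P <- length(powers) + 1L
  Q <- if (random == "slopes") P else 1L
  n_theta <- Q * (Q + 1L) / 2L
  vals <- c()
  for (s0 in c(-2, 0)) {
    for (g0 in c(-3, -1)) {
      start <- c(s0, rep(0, n_theta))
      diag_idx <- cumsum(c(1L, if (Q > 1L) Q:2L))  # diagonal slots of lower.tri(diag = TRUE)
      start[1L + diag_idx] <- g0
      op <- optim(start, neg2reml_direct, long = long, powers = powers,
                  random = random, offset = offset, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))
      op <- optim(op$par, neg2reml_direct, long = long, powers = powers,
                  random = random, offset = offset, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))
      vals <- c(vals, op$value)
    }
  }
  -min(vals) / 2
}

# Literal Benjamini-Hochberg step-up: sort, cumulative min from the top, remap.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- running
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Small random unbalanced long-format dataset.
random_long <- function(n_subj, times, drop = 0, sigma_b = 0.4, sigma_e = 0.3,
                        beta = c(5, 0.2)) {
  long <- expand.grid(subject_id = sprintf("s%d", seq_len(n_subj)),
                      time_hours = times, stringsAsFactors = FALSE)
  if (drop > 0) {
    long <- long[-sample(nrow(long), drop), ]
    # keep at least one row per subject
    long <- long[order(long$subject_id, long$time_hours), ]
  }
  bi <- rnorm(n_subj, 0, sigma_b)
  names(bi) <- sprintf("s%d", seq_len(n_subj))
  long$value <- beta[1] + beta[2] * long$time_hours +
    bi[long$subject_id] + rnorm(nrow(long), 0, sigma_e)
  rownames(long) <- NULL
  long
}

fixture_path <- function(f) system.file("extdata", f, package = "fpgcm")
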