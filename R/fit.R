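# Core REML/ML machinery for the growth curve model
#
#   y_i = X_i beta + Z_i b_i + e_i,   b_i ~ N(0, G),  e_i ~ N(0, sigma_e^2 I)
#
# The marginal covariance is written V_i = sigma_e^2 * W_i with
# W_i = I + Z_i Lambda Lambda' Z_i' and G = sigma_e^2 Lambda Lambda'
# (relative covariance factor).  beta and sigma_e^2 are profiled out of the
# criterion; the optimization runs over Lambda only: a single ratio
# lambda = sigma_b^2 / sigma_e^2 for a random intercept, or the log-Cholesky
# parameterization of Lambda when every time term has a random slope.
# Woodbury identities keep all per-subject work at the dimension of Z.

VAR_FLOOR <- 1e-8

# ---- random-intercept path -------------------------------------------------

# Per-subject sufficient statistics; subject must be an integer index vector.
ri_stats <- function(X, y, subject) {
  P <- ncol(X)
  o <- order(subject)
  Xo <- X[o, , drop = FALSE]
  yo <- y[o]
  so <- subject[o]
  Sx <- rowsum(Xo, so, reorder = TRUE)          # S x P per-subject column sums
  Sy <- as.numeric(rowsum(yo, so, reorder = TRUE))
  list(XtX = crossprod(X), Sxy = as.numeric(crossprod(X, y)),
       yy = sum(y * y), Sx = Sx, Sy = Sy, n_i = as.numeric(rowsum(rep(1, length(yo)), so)),
       n = length(y), P = P)
}

# Cholesky of A after column equilibration, so near-collinearity is detected
# on the correlation scale regardless of how differently the FP columns are
# scaled (t^3 versus t^-2 spans many orders of magnitude).  Returns NULL for
# singular or indefinite A; otherwise the factor R, the scaling d, and
# log|A|.
chol_equilibrated <- function(A, tol = 1e-6) {
  dA <- diag(A)
  if (any(dA <= 0) || any(!is.finite(dA))) return(NULL)
  d <- 1 / sqrt(dA)
  As <- A * tcrossprod(d)
  R <- tryCatch(chol(As), error = function(e) NULL)
  if (is.null(R) || any(diag(R) < tol)) return(NULL)
  list(R = R, d = d, logdet = 2 * sum(log(diag(R))) + sum(log(dA)))
}

# Solve A x = b through the equilibrated factor.
chol_solve <- function(ce, b) {
  ce$d * backsolve(ce$R, backsolve(ce$R, ce$d * b, transpose = TRUE))
}

chol_inv <- function(ce) {
  chol2inv(ce$R) * tcrossprod(ce$d)
}

# -2 x profiled (restricted) log-likelihood at variance ratio lambda.
# Returns +Inf for singular generalized cross-products.
ri_crit <- function(lambda, st, reml = TRUE) {
  c_i <- lambda / (1 + lambda * st$n_i)
  A <- st$XtX - crossprod(st$Sx * sqrt(c_i))
  b <- st$Sxy - as.numeric(crossprod(st$Sx, c_i * st$Sy))
  q <- st$yy - sum(c_i * st$Sy^2)
  ce <- chol_equilibrated(A)
  if (is.null(ce)) return(Inf)
  beta <- chol_solve(ce, b)
  rss <- max(q - sum(b * beta), 0)
  df <- if (reml) st$n - st$P else st$n
  if (df <= 0) return(Inf)
  s2 <- max(rss / df, VAR_FLOOR)
  df * log(s2) + rss / s2 + sum(log1p(lambda * st$n_i)) +
    (if (reml) ce$logdet else 0) + df * log(2 * pi)
}

# Details (beta, se, variances, loglik) at a given lambda.
ri_solution <- function(lambda, st, reml = TRUE) {
  c_i <- lambda / (1 + lambda * st$n_i)
  A <- st$XtX - crossprod(st$Sx * sqrt(c_i))
  b <- st$Sxy - as.numeric(crossprod(st$Sx, c_i * st$Sy))
  q <- st$yy - sum(c_i * st$Sy^2)
  ce <- chol_equilibrated(A)
  if (is.null(ce)) stop("singular design")
  Ainv <- chol_inv(ce)
  beta <- as.numeric(Ainv %*% b)
  rss <- max(q - sum(b * beta), 0)
  df <- if (reml) st$n - st$P else st$n
  s2 <- rss / df
  s2f <- max(s2, VAR_FLOOR)
  crit <- df * log(s2f) + rss / s2f + sum(log1p(lambda * st$n_i)) +
    (if (reml) ce$logdet else 0) + df * log(2 * pi)
  vcov_beta <- s2 * Ainv
  list(beta = beta, vcov = vcov_beta, se = sqrt(pmax(diag(vcov_beta), 0)),
       sigma_e2 = s2, lambda = lambda, loglik = -crit / 2, rss = rss)
}

# Maximize the profiled criterion over lambda >= 0 (1-D search on log scale,
# boundary lambda = 0 checked explicitly).
ri_maximize <- function(st, reml = TRUE) {
  f <- function(u) ri_crit(exp(u), st, reml)
  # singular designs evaluate to +Inf; optimize warns but handles them
  opt <- suppressWarnings(stats::optimize(f, interval = c(-15, 8), tol = 1e-8))
  c0 <- ri_crit(0, st, reml)
  if (is.finite(c0) && c0 <= opt$objective + 1e-10) {
    list(lambda = 0, crit = c0)
  } else {
    list(lambda = exp(opt$minimum), crit = opt$objective)
  }
}

# ---- general path: log-Cholesky over Lambda (random slopes) ---------------

theta_to_L <- function(theta, Q) {
  L <- matrix(0, Q, Q)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

# Generalized cross-products under W^{-1} for a list of subject blocks.
lc_products <- function(L, blocks) {
  P <- ncol(blocks[[1L]]$X)
  A <- matrix(0, P, P); bv <- numeric(P); q <- 0; ld <- 0
  for (bl in blocks) {
    U <- bl$Z %*% L                       # n_i x Q
    M <- diag(ncol(U)) + crossprod(U)
    Rm <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(Rm)) return(NULL)
    ld <- ld + 2 * sum(log(diag(Rm)))
    XY <- cbind(bl$X, bl$y)
    UtXY <- crossprod(U, XY)
    K <- backsolve(Rm, backsolve(Rm, UtXY, transpose = TRUE))
    Gm <- crossprod(XY) - crossprod(UtXY, K)
    A <- A + Gm[1:P, 1:P, drop = FALSE]
    bv <- bv + Gm[1:P, P + 1L]
    q <- q + Gm[P + 1L, P + 1L]
  }
  list(A = A, b = bv, q = q, logdet = ld)
}

lc_crit <- function(theta, blocks, n, P, reml = TRUE) {
  Q <- ncol(blocks[[1L]]$Z)
  L <- theta_to_L(theta, Q)
  pr <- lc_products(L, blocks)
  if (is.null(pr)) return(1e10)
  ce <- chol_equilibrated(pr$A)
  if (is.null(ce)) return(1e10)
  beta <- chol_solve(ce, pr$b)
  rss <- max(pr$q - sum(pr$b * beta), 0)
  df <- if (reml) n - P else n
  if (df <= 0) return(1e10)
  s2 <- max(rss / df, VAR_FLOOR)
  df * log(s2) + rss / s2 + pr$logdet +
    (if (reml) ce$logdet else 0) + df * log(2 * pi)
}

lc_solution <- function(theta, blocks, n, P, reml = TRUE) {
  Q <- ncol(blocks[[1L]]$Z)
  L <- theta_to_L(theta, Q)
  pr <- lc_products(L, blocks)
  ce <- chol_equilibrated(pr$A)
  if (is.null(ce)) stop("singular design")
  Ainv <- chol_inv(ce)
  beta <- as.numeric(Ainv %*% pr$b)
  rss <- max(pr$q - sum(pr$b * beta), 0)
  df <- if (reml) n - P else n
  s2 <- rss / df
  s2f <- max(s2, VAR_FLOOR)
  crit <- df * log(s2f) + rss / s2f + pr$logdet +
    (if (reml) ce$logdet else 0) + df * log(2 * pi)
  vcov_beta <- s2 * Ainv
  list(beta = beta, vcov = vcov_beta, se = sqrt(pmax(diag(vcov_beta), 0)),
       sigma_e2 = s2, L = L, G = s2 * tcrossprod(L), loglik = -crit / 2,
       rss = rss)
}

# Starting values: within/between decomposition of OLS residuals.
start_lambda <- function(X, y, subject) {
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  r <- y - as.numeric(X %*% beta)
  mb <- tapply(r, subject, mean)
  vb <- if (length(mb) > 1) stats::var(as.numeric(mb)) else 0
  vw <- stats::var(r - as.numeric(mb[as.character(subject)]))
  if (!is.finite(vw) || vw <= 0) vw <- max(stats::var(r), VAR_FLOOR)
  max(vb / vw, 1e-3)
}

# ---- unified light-weight fit ---------------------------------------------

# long: data.frame(subject_id, time_hours, value); times are raw (pre-offset).
# Returns the internal fit list (no formula/plot baggage); never throws for
# numerical failure -- converged = FALSE with a reason instead.
fit_gcm_core <- function(long, powers, random = "intercept", time_offset = 0,
                         method = "REML", compute_both = TRUE) {
  reml <- identical(method, "REML")
  t_off <- long$time_hours + time_offset
  n <- nrow(long)
  P <- length(powers) + 1L
  Q <- if (identical(random, "slopes")) P else 1L
  n_var <- if (Q == 1L) 2L else Q * (Q + 1L) / 2L + 1L
  k <- P + n_var
  subj <- factor(long$subject_id)
  S <- nlevels(subj)
  fail <- function(reason) {
    list(beta = rep(NA_real_, P), se = rep(NA_real_, P), vcov = NULL,
         G = NULL, sigma_e2 = NA_real_, loglik = NA_real_,
         loglik_reml = NA_real_, loglik_ml = NA_real_, n_obs = n,
         n_subjects = S, k_params = k, powers = powers, random = random,
         time_offset = time_offset, method = method,
         converged = FALSE, reason = reason)
  }
  if (S < 2L) return(fail("fewer than 2 subjects"))
  if (n < k + 1L) return(fail(sprintf("only %d observations for %d parameters", n, k)))
  if (any(t_off <= 0)) return(fail("non-positive offset times"))
  X <- tryCatch(cbind(1, fp_transform(t_off, powers)),
                error = function(e) NULL)
  if (is.null(X)) return(fail("design construction failed"))
  colnames(X) <- c("(Intercept)", fp_term_names(powers))
  si <- as.integer(subj)

  if (Q == 1L) {
    st <- ri_stats(X, long$value, si)
    opt <- tryCatch(ri_maximize(st, reml), error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$crit)) return(fail("optimizer failure"))
    sol <- tryCatch(ri_solution(opt$lambda, st, reml), error = function(e) NULL)
    if (is.null(sol)) return(fail("singular design"))
    ll_other <- if (compute_both) {
      tryCatch({
        o2 <- ri_maximize(st, !reml)
        -o2$crit / 2
      }, error = function(e) NA_real_)
    } else NA_real_
    sb2 <- sol$lambda * sol$sigma_e2
    if (sol$lambda <= exp(-15) * 1.001) sb2 <- 0
    G <- matrix(sb2, 1, 1, dimnames = list("(Intercept)", "(Intercept)"))
    out <- sol
    out$G <- G
  } else {
    blocks <- lapply(split(seq_len(n), si), function(ii) {
      list(X = X[ii, , drop = FALSE], Z = X[ii, , drop = FALSE],
           y = long$value[ii])
    })
    lam0 <- start_lambda(X, long$value, si)
    L0 <- matrix(0, Q, Q)
    diag(L0) <- c(log(sqrt(lam0)), rep(log(0.1), Q - 1L))
    th0 <- L0[lower.tri(L0, diag = TRUE)]
    op <- tryCatch(
      stats::optim(th0, lc_crit, blocks = blocks, n = n, P = P, reml = reml,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000 * Q)),
      error = function(e) NULL
    )
    if (is.null(op) || op$value >= 1e10) return(fail("optimizer failure"))
    sol <- tryCatch(lc_solution(op$par, blocks, n, P, reml),
                    error = function(e) NULL)
    if (is.null(sol)) return(fail("singular design"))
    ll_other <- if (compute_both) {
      tryCatch({
        o2 <- stats::optim(op$par, lc_crit, blocks = blocks, n = n, P = P,
                           reml = !reml, method = "Nelder-Mead",
                           control = list(reltol = 1e-12, maxit = 2000 * Q))
        -o2$value / 2
      }, error = function(e) NA_real_)
    } else NA_real_
    dimnames(sol$G) <- list(colnames(X), colnames(X))
    out <- sol
  }
  names(out$beta) <- colnames(X)
  names(out$se) <- colnames(X)
  if (!is.null(out$vcov)) dimnames(out$vcov) <- list(colnames(X), colnames(X))
  out$loglik_reml <- if (reml) out$loglik else ll_other
  out$loglik_ml <- if (reml) ll_other else out$loglik
  out$n_obs <- n
  out$n_subjects <- S
  out$k_params <- k
  out$powers <- powers
  out$random <- random
  out$time_offset <- time_offset
  out$method <- method
  out$converged <- TRUE
  out$reason <- NA_character_
  out$X <- X
  out$subject <- subj
  out
}

model_aic <- function(fit, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  ll <- if (criterion == "REML") fit$loglik_reml else fit$loglik_ml
  if (!isTRUE(fit$converged) || !is.finite(ll)) {
    stop("AIC undefined: model did not converge")
  }
  -2 * ll + 2 * fit$k_params
}
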