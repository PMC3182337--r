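#' Fit a growth curve model with fractional polynomial time transformations
#'
#' Fits the linear mixed model
#' \deqn{y_{ij} = \beta_0 + \sum_b \beta_b f_b(t_{ij}) + b_{i0}
#'   + \sum_g b_{ig} f_g(t_{ij}) + e_{ij}}
#' for one response series with repeated measures per subject, where the
#' \eqn{f_b} are fractional polynomial transformations of (offset) time with
#' powers from the fixed set \code{fp_powers()}.  Subject random effects
#' \eqn{b_i \sim N(0, G)} capture between-subject heterogeneity; residuals
#' are i.i.d. \eqn{N(0, \sigma_e^2)}.  Estimation is by restricted maximum
#' likelihood (default) or maximum likelihood: the variance parameters are
#' optimized on a profiled criterion with \eqn{\beta} solved by generalized
#' least squares, so subjects with incomplete time grids contribute exactly
#' their observed rows (valid under missingness completely at random).
#'
#' Unidentifiable or singular inputs do not raise errors: the returned object
#' has \code{converged = FALSE} and a \code{reason}, so grid screening over
#' many models can simply drop failed candidates.
#'
#' @param formula A three-part formula \code{value ~ time | subject} naming
#'   the response, time and subject grouping columns of \code{data}.
#' @param data Data frame holding those columns, e.g. the output of
#'   [tc_long()].
#' @param powers Numeric vector of 1 or 2 fractional polynomial powers from
#'   [fp_powers()] (non-decreasing; a repeated power adds a
#'   \eqn{t^\phi \log t} term).  Default \code{1}: the linear growth model.
#' @param random \code{"intercept"} for a subject random intercept only, or
#'   \code{"slopes"} to give every fixed time term a random counterpart.
#' @param time_offset Added to all times before transformation; default +1
#'   when the earliest time is 0, else 0.
#' @param method \code{"REML"} (default) or \code{"ML"}.  Both maximized
#'   log-likelihoods are computed and stored; \code{method} decides which
#'   criterion the reported estimates maximize.
#' @return An object of class \code{"fpgcm"} with components including
#'   \code{coefficients}, \code{se}, \code{vcov}, \code{G}, \code{sigma_e2},
#'   \code{loglik_reml}, \code{loglik_ml}, \code{k_params}, \code{converged}.
#'   Supported methods: \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{logLik}, \code{AIC}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{simulate}, \code{plot}.
#' @export
#' @examples
#' d <- data.frame(subject = rep(1:4, each = 4),
#'                 time = rep(c(0, 2, 6, 10), 4))
#' set.seed(1)
#' d$y <- 8 + 0.2 * d$time + rnorm(4)[d$subject] * 0.4 + rnorm(16, 0, 0.3)
#' fit <- fpgcm(y ~ time | subject, d, powers = 1)
#' summary(fit)
fpgcm <- function(formula, data, powers = 1, random = c("intercept", "slopes"),
                  time_offset = NULL, method = c("REML", "ML")) {
  random <- match.arg(random)
  method <- match.arg(method)
  if (!inherits(formula, "formula") || length(formula) != 3L) {
    stop("'formula' must look like value ~ time | subject")
  }
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|")))) {
    stop("'formula' must have the form value ~ time | subject")
  }
  env <- environment(formula)
  value <- eval(formula[[2L]], data, env)
  tt <- eval(rhs[[2L]], data, env)
  subject <- eval(rhs[[3L]], data, env)
  keep <- !(is.na(value) | is.na(tt) | is.na(subject))
  long <- data.frame(subject_id = as.character(subject[keep]),
                     time_hours = as.numeric(tt[keep]),
                     value = as.numeric(value[keep]),
                     stringsAsFactors = FALSE)
  if (nrow(long) == 0L) stop("no complete observations")
  if (is.null(time_offset)) time_offset <- if (min(long$time_hours) == 0) 1 else 0
  fit <- fit_gcm_core(long, powers = as.numeric(powers), random = random,
                      time_offset = time_offset, method = method,
                      compute_both = TRUE)
  fit$coefficients <- fit$beta
  fit$long <- long
  fit$call <- match.call()
  class(fit) <- "fpgcm"
  fit
}

#' @export
print.fpgcm <- function(x, digits = 4, ...) {
  cat("Growth curve model with fractional polynomial time transformation\n")
  cat(sprintf("  powers: (%s)   random effects: %s   method: %s\n",
              paste(x$powers, collapse = ", "), x$random, x$method))
  cat(sprintf("  %d observations, %d subjects, time offset +%g\n",
              x$n_obs, x$n_subjects, x$time_offset))
  if (!x$converged) {
    cat(sprintf("  NOT CONVERGED: %s\n", x$reason))
    return(invisible(x))
  }
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Residual variance: %s   log-lik (%s): %s   AIC: %s\n",
              format(x$sigma_e2, digits = digits), x$method,
              format(x$loglik, digits = digits),
              format(model_aic(x, x$method), digits = digits)))
  invisible(x)
}

#' @export
summary.fpgcm <- function(object, ...) {
  if (!object$converged) {
    stop(sprintf("model did not converge: %s", object$reason))
  }
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, G = object$G, sigma_e2 = object$sigma_e2,
              loglik_reml = object$loglik_reml, loglik_ml = object$loglik_ml,
              aic = model_aic(object, object$method), method = object$method,
              powers = object$powers, random = object$random,
              n_obs = object$n_obs, n_subjects = object$n_subjects,
              call = object$call)
  class(out) <- "summary.fpgcm"
  out
}

#' @export
print.summary.fpgcm <- function(x, digits = 4, ...) {
  cat("Growth curve model (fractional polynomial powers:",
      paste(x$powers, collapse = ", "), ")\n")
  cat(sprintf("%s fit, %d observations from %d subjects\n",
              x$method, x$n_obs, x$n_subjects))
  cat("\nFixed effects (Wald z tests, normal reference):\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nRandom-effect covariance G:\n")
  print(round(x$G, digits))
  cat(sprintf("Residual variance sigma_e^2: %s\n", format(x$sigma_e2, digits = digits)))
  cat(sprintf("log-lik REML: %s   ML: %s   AIC: %s\n",
              format(x$loglik_reml, digits = digits),
              format(x$loglik_ml, digits = digits),
              format(x$aic, digits = digits)))
  invisible(x)
}

#' @export
coef.fpgcm <- function(object, ...) object$coefficients

#' @export
vcov.fpgcm <- function(object, ...) object$vcov

#' @export
logLik.fpgcm <- function(object, REML = NULL, ...) {
  use_reml <- if (is.null(REML)) identical(object$method, "REML") else isTRUE(REML)
  ll <- if (use_reml) object$loglik_reml else object$loglik_ml
  structure(ll, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' Wald test for a single fixed-effect coefficient
#'
#' Two-sided Wald z test with an asymptotic normal reference, the default
#' inference for screening because mixed-model denominator degrees of freedom
#' are contested and the screening procedure only needs a per-gene p-value.
#'
#' @param fit A converged \code{fpgcm} object.
#' @param coef_index Zero-based coefficient index (0 = intercept, 1 = first
#'   time term, ...).
#' @param ref \code{"z"} for the asymptotic normal reference (default) or
#'   \code{"t"} with residual degrees of freedom \eqn{n - p - 1}.
#' @return List with \code{estimate}, \code{se}, \code{z}, \code{p_value}.
#' @export
coef_test <- function(fit, coef_index, ref = c("z", "t")) {
  ref <- match.arg(ref)
  if (!isTRUE(fit$converged)) stop("model did not converge")
  P <- length(fit$coefficients)
  if (coef_index < 0 || coef_index > P - 1L) {
    stop(sprintf("coef_index must be between 0 and %d", P - 1L))
  }
  est <- unname(fit$coefficients[coef_index + 1L])
  se <- unname(fit$se[coef_index + 1L])
  z <- est / se
  p <- if (ref == "z") 2 * stats::pnorm(-abs(z)) else
    2 * stats::pt(-abs(z), df = fit$n_obs - P)
  list(estimate = est, se = se, z = z, p_value = p)
}

#' Population mean curve of a fitted growth curve model
#'
#' Evaluates \eqn{E[y](t) = \beta_0 + \sum_b \beta_b f_b(t + \mathrm{offset})}
#' at new times (the subject-level random effects average out).
#'
#' @param object A converged \code{fpgcm} fit.
#' @param newdata Optional data frame with a time column named as in the
#'   fitting formula (or \code{time_hours}); defaults to the observed times.
#' @param times Alternative shortcut: numeric vector of raw times.
#' @param ... Unused.
#' @return Numeric vector of population means.
#' @export
predict.fpgcm <- function(object, newdata = NULL, times = NULL, ...) {
  if (!isTRUE(object$converged)) stop("model did not converge")
  if (is.null(times)) {
    times <- if (is.null(newdata)) {
      object$long$time_hours
    } else if ("time_hours" %in% names(newdata)) {
      newdata$time_hours
    } else {
      tv <- as.list(object$call$formula[[3L]])[[2L]]
      eval(tv, newdata)
    }
  }
  X <- cbind(1, fp_transform(as.numeric(times) + object$time_offset, object$powers))
  as.numeric(X %*% object$coefficients)
}

#' @export
fitted.fpgcm <- function(object, ...) {
  as.numeric(object$X %*% object$coefficients)
}

#' Subject-level random effect predictions (BLUPs)
#'
#' @param object A converged \code{fpgcm} fit.
#' @return Matrix, one row per subject, one column per random effect.
#' @export
random_effects <- function(object) {
  stopifnot(inherits(object, "fpgcm"), isTRUE(object$converged))
  r <- object$long$value - fitted(object)
  Q <- nrow(object$G)
  lev <- levels(object$subject)
  out <- matrix(0, length(lev), Q, dimnames = list(lev, rownames(object$G)))
  s2 <- max(object$sigma_e2, VAR_FLOOR)
  Grel <- object$G / s2                   # Lambda Lambda'
  for (s in seq_along(lev)) {
    ii <- which(object$subject == lev[s])
    Z <- object$X[ii, seq_len(Q), drop = FALSE]
    Wi <- diag(length(ii)) + Z %*% Grel %*% t(Z)
    out[s, ] <- as.numeric(Grel %*% t(Z) %*% solve(Wi, r[ii]))
  }
  out
}

#' @export
residuals.fpgcm <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$long$value - fitted(object)
  if (type == "marginal") return(r)
  b <- random_effects(object)
  Q <- ncol(b)
  Zb <- rowSums(object$X[, seq_len(Q), drop = FALSE] *
                  b[as.character(object$subject), , drop = FALSE])
  r - Zb
}

#' Simulate response series from a fitted growth curve model
#'
#' Draws new subject random effects and residuals at the observed design.
#'
#' @param object A converged \code{fpgcm} fit.
#' @param nsim Number of simulated series.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with \code{nsim} columns, rows aligned with
#'   \code{object$long}.
#' @export
simulate.fpgcm <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(isTRUE(object$converged))
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  Q <- nrow(object$G)
  S <- nlevels(object$subject)
  ev <- eigen(object$G, symmetric = TRUE)
  Ghalf <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), Q) %*% t(ev$vectors)
  si <- as.integer(object$subject)
  out <- matrix(NA_real_, length(mu), nsim)
  for (k in seq_len(nsim)) {
    b <- matrix(stats::rnorm(S * Q), S, Q) %*% Ghalf
    Zb <- rowSums(object$X[, seq_len(Q), drop = FALSE] * b[si, , drop = FALSE])
    out[, k] <- mu + Zb + stats::rnorm(length(mu), 0, sqrt(object$sigma_e2))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.fpgcm <- function(x, n_grid = 100, ...) {
  stopifnot(isTRUE(x$converged))
  tr <- range(x$long$time_hours)
  tg <- seq(tr[1L], tr[2L], length.out = n_grid)
  mu <- predict(x, times = tg)
  graphics::plot(x$long$time_hours, x$long$value, col = "grey50",
                 xlab = "time (h)", ylab = "expression",
                 main = sprintf("FP powers (%s)", paste(x$powers, collapse = ", ")),
                 ...)
  for (s in levels(x$subject)) {
    ii <- x$subject == s
    o <- order(x$long$time_hours[ii])
    graphics::lines(x$long$time_hours[ii][o], x$long$value[ii][o],
                    col = "grey80")
  }
  graphics::lines(tg, mu, lwd = 2, col = "firebrick")
  invisible(x)
}
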