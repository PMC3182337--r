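test_that("a noise-free constant series collapses to its mean with zero variances", {
  d <- expand.grid(subject_id = c("s1", "s2", "s3"), time_hours = c(1, 2))
  d$value <- 5
  f <- fpgcm(value ~ time_hours | subject_id, d, powers = 1)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients[1]), 5, tolerance = 1e-6)
  expect_equal(unname(f$coefficients[2]), 0, tolerance = 1e-6)
  expect_lt(f$sigma_e2, 1e-6)
  expect_lt(f$G[1, 1], 1e-6)
  # the variance floor keeps the AIC finite even in this degenerate case
  expect_true(is.finite(fpgcm:::model_aic(f, "REML")))
})

test_that("balanced random-intercept REML equals the classical ANOVA estimators", {
  # 3 subjects x 3 replicate observations, intercept-only fixed design:
  # sigma_e^2 = MSW and sigma_b^2 = (MSB - MSW) / n in the balanced case
  y <- c(4.1, 5.0, 4.6,
         6.2, 5.8, 6.6,
         5.1, 4.8, 5.5)
  subj <- rep(1:3, each = 3)
  ybar_i <- tapply(y, subj, mean)
  msw <- sum((y - ybar_i[subj])^2) / (9 - 3)
  msb <- 3 * sum((ybar_i - mean(y))^2) / (3 - 1)
  exp_sb2 <- max((msb - msw) / 3, 0)

  X <- matrix(1, 9, 1)
  st <- fpgcm:::ri_stats(X, y, subj)
  opt <- fpgcm:::ri_maximize(st, reml = TRUE)
  sol <- fpgcm:::ri_solution(opt$lambda, st, reml = TRUE)
  expect_equal(sol$sigma_e2, msw, tolerance = 1e-6)
  expect_equal(sol$lambda * sol$sigma_e2, exp_sb2, tolerance = 1e-5)
  expect_equal(sol$beta[1], mean(y), tolerance = 1e-8)
})

test_that("profiled REML matches a brute-force full-matrix oracle", {
  set.seed(101)
  n_checked <- 0
  for (rep in 1:14) {
    n_subj <- sample(3:5, 1)
    tms <- sort(sample(c(0.5, 1, 2, 4, 8, 12), sample(3:5, 1)))
    long <- random_long(n_subj, tms, drop = sample(0:2, 1))
    pw <- sort(sample(fp_powers(), sample(1:2, 1), replace = TRUE))
    fit <- fpgcm:::fit_gcm_core(long, pw, "intercept", time_offset = 0,
                                method = "REML")
    if (!fit$converged) next
    oracle <- oracle_reml_loglik(long, pw, "intercept", offset = 0)
    expect_equal(fit$loglik_reml, oracle, tolerance = 1e-4)
    n_checked <- n_checked + 1
  }
  # random-slope structure on slightly larger balanced designs
  for (rep in 1:8) {
    long <- random_long(6, c(1, 2, 4, 8, 12), drop = sample(0:2, 1))
    pw <- sample(c(0, 0.5, 1), 1)
    fit <- fpgcm:::fit_gcm_core(long, pw, "slopes", time_offset = 0,
                                method = "REML")
    if (!fit$converged) next
    oracle <- oracle_reml_loglik(long, pw, "slopes", offset = 0)
    # both are maximizing the same objective; neither may beat the other
    # by more than the tolerance
    expect_equal(fit$loglik_reml, oracle, tolerance = 1e-4)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("fits agree with lme4 on REML and ML criteria", {
  set.seed(7)
  long <- random_long(6, c(0, 1, 2, 4, 8), drop = 3)
  f <- fpgcm(value ~ time_hours | subject_id, long, powers = 1,
             time_offset = 1)
  m <- lme4::lmer(value ~ I(time_hours + 1) + (1 | subject_id), long,
                  REML = TRUE)
  expect_equal(f$loglik_reml, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(f$coefficients), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 1e-5)
  m_ml <- lme4::refitML(m)
  expect_equal(f$loglik_ml, as.numeric(logLik(m_ml)), tolerance = 1e-6)
})

test_that("adding a constant shifts only the intercept", {
  set.seed(5)
  long <- random_long(5, c(0.5, 1, 2, 4), drop = 2)
  f1 <- fpgcm(value ~ time_hours | subject_id, long, powers = c(0, 1))
  long2 <- long
  long2$value <- long2$value + 7
  f2 <- fpgcm(value ~ time_hours | subject_id, long2, powers = c(0, 1))
  expect_equal(unname(f2$coefficients[1] - f1$coefficients[1]), 7,
               tolerance = 1e-6)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-6)
  expect_equal(f2$sigma_e2, f1$sigma_e2, tolerance = 1e-6)
  expect_equal(f2$loglik_reml, f1$loglik_reml, tolerance = 1e-6)
})

test_that("missingness is handled purely by row omission", {
  set.seed(9)
  fx <- make_fixture_dataset(n_null = 1, n_down = 1, n_up = 0, seed = 31)
  x <- fx$dataset
  # blank two chips for everyone, then compare against manual row deletion
  x_miss <- x
  x_miss$values[, c(2, 9)] <- NA_real_
  long_manual <- tc_long(x, x$genes[1])
  drop_keys <- paste(x$samples$subject_id[c(2, 9)], x$samples$time_hours[c(2, 9)])
  long_manual <- long_manual[!(paste(long_manual$subject_id, long_manual$time_hours)
                               %in% drop_keys), ]
  f1 <- fpgcm:::fit_gcm_core(tc_long(x_miss, x$genes[1]), 1, "intercept", 1, "REML")
  f2 <- fpgcm:::fit_gcm_core(long_manual, 1, "intercept", 1, "REML")
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loglik_reml, f2$loglik_reml)
})

test_that("degenerate designs fail softly with a reason", {
  # all observations at one time: slope inestimable
  d <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                  time_hours = 2, value = rnorm(6))
  f <- fpgcm(value ~ time_hours | subject_id, d, powers = 1)
  expect_false(f$converged)
  expect_true(is.character(f$reason))
  expect_error(summary(f), "did not converge")

  # single subject
  d2 <- data.frame(subject_id = "a", time_hours = c(1, 2, 3, 4),
                   value = rnorm(4))
  f2 <- fpgcm(value ~ time_hours | subject_id, d2, powers = 1)
  expect_false(f2$converged)
  expect_match(f2$reason, "subjects")
})

test_that("Wald coefficient tests use the stated references", {
  fake <- list(converged = TRUE, coefficients = c(1, 0), se = c(0.5, 2),
               n_obs = 30)
  expect_equal(coef_test(fake, 1)$p_value, 1)
  fake$coefficients <- c(1, 1.959964)
  fake$se <- c(0.5, 1)
  expect_equal(coef_test(fake, 1)$p_value, 0.05, tolerance = 1e-5)
  fake$coefficients <- c(1, 3)
  expect_equal(coef_test(fake, 1)$p_value, 2 * pnorm(-3), tolerance = 1e-12)
  # t reference is heavier-tailed
  expect_gt(coef_test(fake, 1, ref = "t")$p_value, coef_test(fake, 1)$p_value)
  expect_error(coef_test(fake, 5), "coef_index")
})

test_that("AIC counts fixed effects plus free variance parameters", {
  fake <- list(converged = TRUE, loglik_reml = -10, loglik_ml = -9, k_params = 3)
  expect_equal(fpgcm:::model_aic(fake, "REML"), 26)
  expect_equal(fpgcm:::model_aic(fake, "ML"), 24)
  better <- fake; better$loglik_reml <- -8
  expect_lt(fpgcm:::model_aic(better, "REML"), fpgcm:::model_aic(fake, "REML"))
  expect_error(fpgcm:::model_aic(list(converged = FALSE, loglik_reml = -1,
                                      k_params = 2), "REML"), "converge")
  # k: 2 fixed + sigma_b^2 + sigma_e^2 for the random-intercept linear model
  d <- random_long(4, c(1, 2, 4))
  f <- fpgcm(value ~ time_hours | subject_id, d, powers = 1)
  expect_equal(f$k_params, 4)
  expect_equal(AIC(f), -2 * f$loglik_reml + 2 * 4)
})

test_that("model methods are mutually consistent", {
  set.seed(13)
  long <- random_long(6, c(0.5, 1, 2, 4, 8))
  f <- fpgcm(value ~ time_hours | subject_id, long, powers = c(0, 1),
             random = "slopes")
  expect_true(f$converged)
  expect_equal(unname(predict(f)), unname(fitted(f)))
  expect_equal(residuals(f), long$value - fitted(f))
  # conditional residuals remove the subject BLUP contribution
  rc <- residuals(f, type = "conditional")
  expect_lt(sum(rc^2), sum(residuals(f)^2) + 1e-9)
  expect_equal(dim(random_effects(f)), c(6, 3))
  s <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(s), c(nrow(long), 3))
  expect_identical(s, simulate(f, nsim = 3, seed = 1))
  # population curve evaluated through the same basis as the design
  expect_equal(predict(f, times = long$time_hours[1]),
               unname(fitted(f)[1]), tolerance = 1e-10)
})
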