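test_that("BH adjustment matches the hand step-up on simple cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(2)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("an exact linear trend selects the linear transformation", {
  d <- expand.grid(subject_id = sprintf("s%d", 1:5),
                   time_hours = c(0, 2, 4, 6, 8, 10))
  v <- matrix(2 + 0.5 * d$time_hours, nrow = 1)
  rownames(v) <- "lin"
  s <- data.frame(sample_id = sprintf("c%d", seq_len(nrow(d))),
                  subject_id = d$subject_id, time_hours = d$time_hours)
  colnames(v) <- s$sample_id
  x <- time_course_data(v, s)
  sc <- fp_screen(x, order = 1, fdr = 0.05, quiet = TRUE)
  r <- sc$results
  expect_equal(r$phi1, 1)
  expect_equal(r$beta1, 0.5, tolerance = 1e-6)
  expect_lt(r$p1, 1e-10)
  expect_true(r$significant)
})

test_that("genes below the observation minimum are flagged unfit", {
  v <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  v[2, ] <- c(1, NA, NA)
  s <- data.frame(sample_id = c("a", "b", "c"),
                  subject_id = c("s1", "s1", "s2"), time_hours = c(1, 2, 1))
  x <- time_course_data(v, s)
  sc <- fp_screen(x, order = 2, min_obs = 5, fdr = 0.1, quiet = TRUE)
  expect_true(all(sc$results$unfit))
  expect_true(all(is.na(sc$results$p1)))
  expect_false(any(sc$results$significant))
})

test_that("null genes yield roughly uniform slope p-values", {
  # AIC pre-selection over the grid can inflate the small-p fraction; this
  # measures the realized calibration rather than assuming exact uniformity
  cfg <- sim_config(n_subjects = 9, time_points = c(0, 0.5, 4, 24),
                    fold_changes = numeric(0), genes_per_group = 0L,
                    n_null_genes = 400L, n_replicates = 1L, seed = 77)
  sim <- simulate_timecourse(cfg, seed = 77)
  sc <- fp_screen(sim$dataset, order = 1, fdr = 0.05, quiet = TRUE)
  frac <- mean(sc$results$p1 < 0.05)
  # binomial 3-sigma band around 0.05 is +-0.033; allow selection inflation
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.14)
})

test_that("screening is deterministic and order-invariant", {
  fx <- make_fixture_dataset(seed = 12)
  s1 <- fp_screen(fx$dataset, order = 1, fdr = 0.1, quiet = TRUE)
  s2 <- fp_screen(fx$dataset, order = 1, fdr = 0.1, quiet = TRUE)
  expect_identical(s1$results, s2$results)

  perm <- sample(length(fx$dataset$genes))
  xp <- fx$dataset
  xp$values <- xp$values[perm, , drop = FALSE]
  xp$genes <- xp$genes[perm]
  sp <- fp_screen(xp, order = 1, fdr = 0.1, quiet = TRUE)
  reordered <- sp$results[match(s1$results$gene_id, sp$results$gene_id), ]
  rownames(reordered) <- NULL
  expect_equal(reordered, s1$results)
})

test_that("lowering the FDR threshold never enlarges the significant set", {
  fx <- make_fixture_dataset(seed = 19)
  s10 <- fp_screen(fx$dataset, order = 1, fdr = 0.10, quiet = TRUE)
  s02 <- fp_screen(fx$dataset, order = 1, fdr = 0.02, quiet = TRUE)
  sig10 <- s10$results$gene_id[s10$results$significant]
  sig02 <- s02$results$gene_id[s02$results$significant]
  expect_true(all(sig02 %in% sig10))
})

test_that("strong trends are recovered from the incomplete design", {
  fx <- make_fixture_dataset(seed = 1)  # the shipped fixture generator
  sc <- fp_screen(fx$dataset, order = 1, fdr = 0.1, quiet = TRUE)
  r <- sc$results
  trend <- r$gene_id[r$significant & r$gene_id %in%
                       fx$truth$gene_id[fx$truth$kind != "null"]]
  expect_gte(length(trend), 8)  # 10 trend genes planted
  # up- and down-regulated genes land in different pattern families
  sig <- r[r$significant & !r$unfit, ]
  up <- grepl("\\+$", sig$pattern_key)
  expect_true(all(sig$beta1[up] > 0) && all(sig$beta1[!up] < 0))
})

test_that("the order-2 call requires both coefficients jointly significant", {
  set.seed(23)
  # strong quadratic-ish genes among nulls, full second-order grid
  d <- expand.grid(subject_id = sprintf("s%d", 1:8),
                   time_hours = c(0, 1, 2, 4, 8, 12, 24))
  G <- 30
  v <- matrix(rnorm(G * nrow(d), 8, 0.4), G)
  for (g in 1:5) {
    v[g, ] <- v[g, ] + 0.8 * log(d$time_hours + 1) -
      0.15 * (d$time_hours + 1)^0.5 * log(d$time_hours + 1)
  }
  rownames(v) <- sprintf("g%02d", 1:G)
  s <- data.frame(sample_id = sprintf("c%d", seq_len(nrow(d))),
                  subject_id = d$subject_id, time_hours = d$time_hours)
  colnames(v) <- s$sample_id
  x <- time_course_data(v, s)
  sc <- fp_screen(x, order = 2, fdr = 0.1, quiet = TRUE)
  r <- sc$results[!sc$results$unfit, ]
  pmaxv <- pmax(r$p1, r$p2)
  # intersection-union: the gene-level q values are BH of the max p-value
  expect_equal(r$q, oracle_bh(pmaxv), tolerance = 1e-12)
  if (any(r$significant)) {
    thr <- max(pmaxv[r$significant])
    expect_true(all(r$p1[r$significant] <= thr & r$p2[r$significant] <= thr))
    expect_true(all(pmaxv[!r$significant] > thr))
  }
  expect_equal(sort(unique(r$order)), 2)
})

test_that("screen output table is written with a provenance header", {
  fx <- make_fixture_dataset(n_null = 4, n_down = 1, n_up = 1, seed = 3)
  sc <- fp_screen(fx$dataset, order = 1, fdr = 0.1, quiet = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen(sc, f, seed = 42)
  lines <- readLines(f)
  expect_match(lines[1], "^# fpgcm")
  expect_match(lines[2], "seed: 42")
  tab <- read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 6)
  expect_true(all(c("gene_id", "phi1", "beta1", "p1", "q", "significant",
                    "pattern_key") %in% names(tab)))
})
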