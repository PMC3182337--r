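#' The incomplete observation pattern of the irritated-epidermis example
#'
#' Presence grid of the example experiment: 9 subjects biopsied before and at
#' 0.5, 4 and 24 hours after exposure to the irritant, with many chips
#' missing — 21 of the 36 subject-time combinations were observed.  The
#' original microarray values are not publicly deposited, so the package
#' ships synthetic data laid out on exactly this grid (see
#' [make_fixture_dataset()]).
#'
#' @return Logical 9 x 4 matrix, subjects in rows, times (hours) in columns.
#' @export
#' @examples
#' sum(epidermis_pattern())  # 21 observed chips
epidermis_pattern <- function() {
  tms <- c(0, 0.5, 4, 24)
  present <- matrix(FALSE, 9, 4, dimnames = list(
    subject = paste0("subj", 1:9), time = format(tms, trim = TRUE)
  ))
  present[1, c(1, 3, 4)] <- TRUE
  present[2, c(1, 2, 3)] <- TRUE
  present[3, c(1, 2)] <- TRUE
  present[4, c(1, 2)] <- TRUE
  present[5, c(1, 2)] <- TRUE
  present[6, c(1, 2, 4)] <- TRUE
  present[7, c(1, 2)] <- TRUE
  present[8, c(1, 3, 4)] <- TRUE
  present[9, 1] <- TRUE
  attr(present, "times") <- tms
  present
}

#' Synthetic dataset on the incomplete epidermis design
#'
#' Generates log2-scale expression for a handful of genes laid out on the
#' [epidermis_pattern()] grid: only the 21 observed chips appear as sample
#' columns.  Most genes are null (subject random intercept plus noise); a few
#' carry first-order fractional-polynomial trends of both signs so that
#' screening, clustering and pattern grouping have structure to find.  All
#' values are synthetic.
#'
#' @param n_null Number of null genes.
#' @param n_down,n_up Trend genes with negative / positive time coefficients.
#' @param sigma_e,sigma_b Residual and random-intercept SDs (log2 scale).
#' @param effect Absolute total log2 change of trend genes over the course.
#' @param seed Integer seed.
#' @return List with \code{dataset} (a \code{tc_data}) and \code{truth}
#'   (data frame \code{gene_id, kind, power, beta1}).
#' @export
make_fixture_dataset <- function(n_null = 30L, n_down = 7L, n_up = 3L,
                                 sigma_e = 0.25, sigma_b = 0.3, effect = 2,
                                 seed = 1L) {
  set.seed(seed)
  pat <- epidermis_pattern()
  tms <- attr(pat, "times")
  idx <- which(pat, arr.ind = TRUE)
  samples <- data.frame(
    sample_id = sprintf("subj%d_t%s", idx[, 1], format(tms[idx[, 2]], trim = TRUE)),
    subject_id = sprintf("subj%d", idx[, 1]),
    time_hours = tms[idx[, 2]],
    stringsAsFactors = FALSE
  )
  samples <- samples[order(samples$subject_id, samples$time_hours), ]
  n_chip <- nrow(samples)
  # trend shapes: first-order FP curves with assorted powers; scaled so the
  # population curve spans `effect` log2 units over the observed time range
  trend_powers <- rep_len(c(0, -0.5, 1, 0.5, -1), n_down + n_up)
  signs <- c(rep(-1, n_down), rep(1, n_up))
  G <- n_null + n_down + n_up
  gene_id <- c(sprintf("null_%03d", seq_len(n_null)),
               if (n_down) sprintf("down_%02d", seq_len(n_down)),
               if (n_up) sprintf("up_%02d", seq_len(n_up)))
  vals <- matrix(NA_real_, G, n_chip, dimnames = list(gene_id, samples$sample_id))
  toff <- samples$time_hours + 1  # offset grid for curve generation
  base <- stats::rnorm(G, 8, 0.8)
  truth <- data.frame(gene_id = gene_id, kind = "null", power = NA_real_,
                      beta1 = 0, stringsAsFactors = FALSE)
  subj <- factor(samples$subject_id)
  for (g in seq_len(G)) {
    mu <- rep(base[g], n_chip)
    if (g > n_null) {
      k <- g - n_null
      pw <- trend_powers[k]
      f <- fp_transform(toff, pw)[, 1L]
      # sign applies to the curve's total change: a decreasing basis (e.g.
      # t^-0.5) needs a negative coefficient to produce an "up" gene
      fr <- fp_transform(range(toff), pw)[, 1L]
      b1 <- signs[k] * effect / (fr[2L] - fr[1L])
      mu <- mu + b1 * f
      truth$kind[g] <- if (signs[k] > 0) "up" else "down"
      truth$power[g] <- pw
      truth$beta1[g] <- b1
    }
    bi <- stats::rnorm(nlevels(subj), 0, sigma_b)
    vals[g, ] <- mu + bi[as.integer(subj)] + stats::rnorm(n_chip, 0, sigma_e)
  }
  list(dataset = time_course_data(vals, samples), truth = truth)
}

#' Write the shipped demonstration fixtures
#'
#' Writes (a) the synthetic epidermis-style matrix/metadata pair on the
#' incomplete 9-subject design, (b) a small simulation configuration YAML,
#' and (c) a 4-gene clustering demo (one up-trending gene, three
#' down-trending).  Deterministic given the seed.
#'
#' @param dir Output directory, created if needed.
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_fixture_dataset(seed = seed)
  p1 <- file.path(dir, "synthetic_epidermis_matrix.tsv")
  p2 <- file.path(dir, "synthetic_epidermis_meta.tsv")
  write_expression_matrix(fx$dataset, p1, p2)

  cfg <- list(n_subjects = 20, time_points = c(0, 2, 4, 6, 8, 10),
              fold_changes = c(2, 2.5, 3, 3.5), genes_per_group = 10,
              n_null_genes = 960, sigma_e = 0.5, sigma_b = 0.3,
              missing_proportions = c(0, 0.25, 0.5, 0.7),
              n_replicates = 10, fdr_threshold = 0.1, seed = seed,
              note = "sigma_e/sigma_b are package defaults; the reference design does not state them")
  p3 <- file.path(dir, "sim_config.yaml")
  yaml::write_yaml(cfg, p3)

  demo <- make_fixture_dataset(n_null = 0L, n_down = 3L, n_up = 1L,
                               sigma_e = 0.1, seed = seed + 1L)
  p4 <- file.path(dir, "cluster_demo_matrix.tsv")
  p5 <- file.path(dir, "cluster_demo_meta.tsv")
  write_expression_matrix(demo$dataset, p4, p5)
  invisible(c(p1, p2, p3, p4, p5))
}
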