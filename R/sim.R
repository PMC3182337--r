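#' Configuration for the power-versus-missingness simulation study
#'
#' Defaults reproduce the reference study design: 20 subjects measured at 6
#' time points spanning 10 hours, four groups of 10 trend genes with fold
#' changes 2, 2.5, 3 and 3.5 over the time span, the remaining genes null,
#' chip-level missingness applied uniformly at random, screening with the
#' plain linear growth model and a BH call at FDR < 0.1.
#'
#' Fold change is mapped to an additive total change on the log2 expression
#' scale: a fold-f gene has slope \eqn{\beta_1 = \log_2(f) / \mathrm{span}}
#' per hour, so its expected expression rises by \eqn{\log_2 f} over the full
#' time course.  The noise levels \code{sigma_e} (residual SD) and
#' \code{sigma_b} (between-subject SD of the random intercept) are study
#' parameters on the log2 scale; the shipped defaults of 0.5 and 0.3 are
#' reconstructions fixed once for this package, since typical microarray
#' log-scale noise is of this magnitude.
#'
#' @param n_subjects Number of subjects (chips per time point).
#' @param time_points Measurement times in hours, strictly increasing.
#' @param fold_changes Fold changes of the trend-gene groups (may be empty
#'   for a null-only calibration study).
#' @param genes_per_group Trend genes per fold-change group.
#' @param n_null_genes Null genes (slope 0, same random-effect structure).
#' @param sigma_e,sigma_b Residual and random-intercept SDs (log2 scale).
#' @param baseline Intercept common to all genes (log2 scale).
#' @param missing_proportions Proportions of chips to blank, each in [0, 1).
#' @param n_replicates Simulation replicates per missing proportion.
#' @param fdr_threshold FDR level of the significance call.
#' @param seed Integer seed for the whole study.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 20L,
                       time_points = c(0, 2, 4, 6, 8, 10),
                       fold_changes = c(2, 2.5, 3, 3.5),
                       genes_per_group = 10L,
                       n_null_genes = 9960L,
                       sigma_e = 0.5,
                       sigma_b = 0.3,
                       baseline = 8,
                       missing_proportions = c(0, 0.05, 0.10, 0.25, 0.50, 0.70),
                       n_replicates = 100L,
                       fdr_threshold = 0.1,
                       seed = 1L) {
  stopifnot(
    n_subjects >= 2, length(time_points) >= 2, !is.unsorted(time_points, strictly = TRUE),
    min(time_points) >= 0, all(fold_changes > 1 | length(fold_changes) == 0),
    genes_per_group >= 0, n_null_genes >= 0, sigma_e >= 0, sigma_b >= 0,
    all(missing_proportions >= 0 & missing_proportions < 1),
    n_replicates >= 1, fdr_threshold > 0, fdr_threshold < 1
  )
  structure(
    list(n_subjects = as.integer(n_subjects), time_points = as.numeric(time_points),
         fold_changes = as.numeric(fold_changes),
         genes_per_group = as.integer(genes_per_group),
         n_null_genes = as.integer(n_null_genes), sigma_e = sigma_e,
         sigma_b = sigma_b, baseline = baseline,
         missing_proportions = as.numeric(missing_proportions),
         n_replicates = as.integer(n_replicates),
         fdr_threshold = fdr_threshold, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate one synthetic time-course expression dataset
#'
#' Generates \eqn{y_{gij} = \beta_0 + \beta_{1g} t_j + b_{gi} + e_{gij}} with
#' \eqn{b_{gi} \sim N(0, \sigma_b^2)} and \eqn{e_{gij} \sim N(0, \sigma_e^2)},
#' independently per gene.  Trend genes in fold-change group f have
#' \eqn{\beta_{1g} = \log_2(f)/\mathrm{span}}; null genes have slope 0 but
#' the same random-intercept structure.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this replicate.
#' @return List with \code{dataset} (a [time_course_data()] object, complete)
#'   and \code{truth} (data frame \code{gene_id, group, beta1}; \code{group}
#'   is the fold change or \code{"null"}).
#' @export
simulate_timecourse <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tp <- config$time_points
  span <- diff(range(tp))
  S <- config$n_subjects
  Tn <- length(tp)
  n_trend <- length(config$fold_changes) * config$genes_per_group
  G <- n_trend + config$n_null_genes
  if (G == 0L) stop("configuration generates zero genes")
  beta1 <- c(rep(log2(config$fold_changes) / span, each = config$genes_per_group),
             rep(0, config$n_null_genes))
  group <- c(rep(as.character(config$fold_changes), each = config$genes_per_group),
             rep("null", config$n_null_genes))
  gene_id <- c(
    if (n_trend) sprintf("trend_f%s_%02d",
                         rep(config$fold_changes, each = config$genes_per_group),
                         rep(seq_len(config$genes_per_group), length(config$fold_changes))),
    if (config$n_null_genes) sprintf("null_%05d", seq_len(config$n_null_genes))
  )
  t_all <- rep(tp, times = S)
  subj <- rep(seq_len(S), each = Tn)
  b <- matrix(stats::rnorm(G * S, 0, config$sigma_b), G, S)
  E <- matrix(stats::rnorm(G * S * Tn, 0, config$sigma_e), G, S * Tn)
  values <- config$baseline + outer(beta1, t_all) + b[, subj, drop = FALSE] + E
  samples <- data.frame(
    sample_id = sprintf("S%02d_T%g", subj, t_all),
    subject_id = sprintf("S%02d", subj),
    time_hours = t_all,
    stringsAsFactors = FALSE
  )
  rownames(values) <- gene_id
  colnames(values) <- samples$sample_id
  ds <- time_course_data(values, samples)
  list(dataset = ds,
       truth = data.frame(gene_id = gene_id, group = group, beta1 = beta1,
                          stringsAsFactors = FALSE))
}

#' Blank chips (or cells) of a dataset completely at random
#'
#' Chip-level missingness removes whole (subject, time) arrays: the same
#' columns are blanked for every gene, the way arrays go missing in practice.
#' Exactly \code{round(proportion * n_subjects * n_times)} chips are blanked,
#' redrawing (with a log message) if a draw would leave some subject with no
#' observation at all.  Cell-level missingness instead blanks each cell of
#' the value matrix independently.
#'
#' @param x A \code{tc_data} object.
#' @param proportion Proportion to blank, in [0, 1).
#' @param seed Integer seed for the mask.
#' @param level \code{"chip"} (default) or \code{"cell"}.
#' @param quiet Suppress the redraw message.
#' @return The dataset with values blanked (\code{NA}).
#' @export
apply_missingness <- function(x, proportion, seed, level = c("chip", "cell"),
                              quiet = FALSE) {
  stopifnot(inherits(x, "tc_data"), proportion >= 0, proportion < 1)
  level <- match.arg(level)
  if (proportion == 0) return(x)
  set.seed(seed)
  if (level == "cell") {
    mask <- matrix(stats::runif(length(x$values)) < proportion, nrow(x$values))
    x$values[mask] <- NA_real_
    return(x)
  }
  n_chip <- ncol(x$values)
  k <- round(proportion * n_chip)
  if (k == 0L) return(x)
  subj <- x$samples$subject_id
  for (try in seq_len(1000L)) {
    drop <- sample.int(n_chip, k)
    left <- table(subj[-drop])
    if (length(left) == length(unique(subj))) break
    if (try == 1000L) stop("could not draw a mask leaving every subject observed")
    if (!quiet && try == 1L) message("redrawing missingness mask to keep every subject observed")
  }
  keep_subj_times <- tapply(seq_along(subj)[-drop], subj[-drop], length)
  if (sum(keep_subj_times >= 2) < 2) {
    stop("missingness leaves fewer than 2 subjects with 2+ time points; model unidentifiable")
  }
  x$values[, drop] <- NA_real_
  x
}

#' Run the power-versus-missingness study
#'
#' For every replicate and missing proportion: simulate a complete dataset,
#' blank chips at random, screen all genes with the plain linear growth model
#' (random intercept, Wald test on the slope), call significance by BH at the
#' configured FDR, and score the fraction of trend genes recovered.  Power is
#' pooled over replicates and genes per (fold change, missing proportion)
#' cell, with a binomial Monte-Carlo standard error.
#'
#' @param config A [sim_config()].
#' @param missing_proportions Conditions to run; defaults to the config's.
#' @param collect_estimates Also return the per-gene slope estimates of the
#'   trend genes (for bias assessment).
#' @param quiet Suppress per-condition progress messages.
#' @return Object of class \code{"power_table"}: data frame with columns
#'   \code{fold_change, missing, power, mc_se, n_trials}, plus attributes
#'   \code{config} and (optionally) \code{estimates}.
#' @export
power_study <- function(config, missing_proportions = config$missing_proportions,
                        collect_estimates = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_draws <- config$n_replicates * length(missing_proportions) * 2L
  child <- sample.int(.Machine$integer.max - 1L, n_draws)
  ci <- 0L
  cells <- list()
  est <- list()
  fdp <- matrix(NA_real_, length(missing_proportions), config$n_replicates)
  for (mi in seq_along(missing_proportions)) {
    pm <- missing_proportions[mi]
    hits <- stats::setNames(numeric(length(config$fold_changes)),
                            as.character(config$fold_changes))
    for (r in seq_len(config$n_replicates)) {
      sim <- simulate_timecourse(config, seed = child[ci <- ci + 1L])
      ds <- apply_missingness(sim$dataset, pm, seed = child[ci <- ci + 1L],
                              quiet = TRUE)
      sc <- fp_screen(ds, grid = list(1), random = "intercept",
                      fdr = config$fdr_threshold, quiet = TRUE)
      res <- sc$results
      is_null <- sim$truth$group == "null"
      n_rej <- sum(res$significant)
      fdp[mi, r] <- if (n_rej > 0) sum(res$significant & is_null) / n_rej else 0
      for (f in as.character(config$fold_changes)) {
        idx <- sim$truth$group == f
        hits[f] <- hits[f] + sum(res$significant[idx])
      }
      if (collect_estimates) {
        idx <- !is_null
        est[[length(est) + 1L]] <- data.frame(
          missing = pm, replicate = r,
          group = sim$truth$group[idx],
          beta1_true = sim$truth$beta1[idx],
          beta1_hat = res$beta1[idx],
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(config$fold_changes)) {
      n_trials <- config$n_replicates * config$genes_per_group
      p_hat <- hits / n_trials
      cells[[mi]] <- data.frame(
        fold_change = config$fold_changes, missing = pm, power = as.numeric(p_hat),
        mc_se = sqrt(p_hat * (1 - p_hat) / n_trials), n_trials = n_trials
      )
    }
    if (!quiet) {
      message(sprintf("missing %.0f%%: done (%d replicates)", 100 * pm,
                      config$n_replicates))
    }
  }
  out <- if (length(cells)) do.call(rbind, cells) else
    data.frame(fold_change = numeric(0), missing = numeric(0),
               power = numeric(0), mc_se = numeric(0), n_trials = integer(0))
  rownames(out) <- NULL
  structure(out,
            config = config,
            fdp = data.frame(missing = missing_proportions,
                             mean_fdp = rowMeans(fdp),
                             mc_se = apply(fdp, 1, stats::sd) / sqrt(config$n_replicates)),
            estimates = if (collect_estimates) do.call(rbind, est) else NULL,
            class = c("power_table", "data.frame"))
}

#' @export
print.power_table <- function(x, digits = 2, ...) {
  if (nrow(x)) {
    m <- tapply(x$power, list(fold = x$fold_change, missing = x$missing), mean)
    cat("Estimated power by fold change (rows) and missing proportion (columns):\n")
    print(round(m, digits))
  }
  fdp <- attr(x, "fdp")
  if (!is.null(fdp)) {
    cat("\nRealized false discovery proportion by missing proportion:\n")
    print(data.frame(missing = fdp$missing, mean_fdp = round(fdp$mean_fdp, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a power table as TSV shaped fold-change x missing-proportion
#'
#' @param x A \code{power_table}.
#' @param path Output path.
#' @param seed Optional integer recorded in the header.
#' @export
write_power_table <- function(x, path, seed = NA) {
  stopifnot(inherits(x, "power_table"))
  cfg <- attr(x, "config")
  wide <- stats::reshape(as.data.frame(x)[c("fold_change", "missing", "power")],
                         idvar = "fold_change", timevar = "missing",
                         direction = "wide")
  names(wide) <- sub("^power\\.", "missing_", names(wide))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(cfg, seed), con)
  utils::write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
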