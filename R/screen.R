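#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: the adjusted value of the i-th
#' smallest p-value is \eqn{\min_{j \ge i} m p_{(j)} / j}, capped at 1 and
#' mapped back to the input order (so thresholding the output at level q is
#' the BH step-up rule at FDR q).  Thin validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]} (no \code{NA}).
#' @return Vector of adjusted values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen every gene of a dataset through the fractional-polynomial grid
#'
#' For each gene: fit every candidate model of the grid, pick the lowest-AIC
#' converged candidate (ties broken by the canonical grid order), and record
#' Wald p-values for its time coefficients.  Across genes, a single
#' Benjamini-Hochberg pass controls the FDR: the per-gene test statistic is
#' the \eqn{\beta_1} p-value for first-order grids, or
#' \eqn{\max(p_{\beta_1}, p_{\beta_2})} for second-order grids, an
#' intersection-union combination of the rule that a gene is called only when
#' every time coefficient of its best model is significant.
#'
#' Genes with too few observations, fewer than two subjects, or no converged
#' candidate are carried through flagged \code{unfit}; they contribute no
#' test and are excluded from the BH denominator.
#'
#' When missingness is chip-level (every sample column entirely observed or
#' entirely blank) and the random structure is intercept-only, all genes
#' share the same per-subject designs and the screen uses a fast path that
#' precomputes them once; results are numerically identical to the general
#' per-gene path.
#'
#' @param x A [time_course_data()] object.
#' @param order Grid order, 1 (8 candidate transformations) or 2 (36).
#' @param random Random-effect structure, \code{"intercept"} or
#'   \code{"slopes"}; the epidermis-style default is a random intercept with
#'   fixed time effects.
#' @param fdr FDR threshold for the significance call.
#' @param selection Likelihood used for estimation and AIC ranking,
#'   \code{"REML"} (default) or \code{"ML"}.  REML criteria across different
#'   fixed-effect designs are only approximately comparable; a note is
#'   emitted once per screen when this applies.
#' @param min_obs Minimum observations per gene to attempt a fit; default 4
#'   for order 1 and 6 for order 2 (second-order fits need more than 3 time
#'   points per subject to be identifiable in practice).
#' @param grid Optional explicit grid: a list of power vectors overriding
#'   \code{order}, e.g. \code{list(1)} to force the plain linear model.
#' @param wald Reference distribution for the coefficient tests: \code{"z"}
#'   (asymptotic normal, the default — mixed-model denominator degrees of
#'   freedom are contested) or \code{"t"} with residual degrees of freedom
#'   \eqn{n - p - 1}, a more conservative alternative for severely reduced
#'   designs.
#' @param quiet Suppress progress notes.
#' @return An object of class \code{"fp_screen"}: a list with a per-gene
#'   results data frame (\code{$results}), the configuration (\code{$config})
#'   and the grid used.  Columns: \code{gene_id, order, phi1, phi2, beta0,
#'   beta1, beta2, se1, se2, p1, p2, q, significant, pattern_key, n_obs,
#'   n_models_converged, unfit}.
#' @seealso [write_screen()], [pattern_groups()]
#' @export
fp_screen <- function(x, order = 1L, random = c("intercept", "slopes"),
                      fdr = 0.05, selection = c("REML", "ML"), min_obs = NULL,
                      grid = NULL, wald = c("z", "t"), quiet = FALSE) {
  stopifnot(inherits(x, "tc_data"))
  random <- match.arg(random)
  selection <- match.arg(selection)
  wald <- match.arg(wald)
  pfun <- function(z, n, P) {
    if (wald == "z") 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df = n - P)
  }
  if (!(fdr > 0 && fdr < 1)) stop("'fdr' must be in (0, 1)")
  if (is.null(grid)) {
    specs <- fp_models(order, random)
  } else {
    specs <- lapply(grid, function(pw) list(powers = as.numeric(pw), random = random))
    order <- max(lengths(lapply(specs, `[[`, "powers")))
  }
  if (is.null(min_obs)) min_obs <- if (order >= 2L) 6L else 4L
  if (min_obs < order + 3L) stop("'min_obs' must be at least order + 3")
  if (!quiet && selection == "REML" && length(specs) > 1L) {
    message("note: grid ranked by REML-based AIC; REML criteria across different fixed-effect designs are only approximately comparable (use selection = \"ML\" for strict comparability)")
  }

  G <- length(x$genes)
  acc <- list(
    order = rep(NA_integer_, G), phi1 = rep(NA_real_, G), phi2 = rep(NA_real_, G),
    beta0 = rep(NA_real_, G), beta1 = rep(NA_real_, G), beta2 = rep(NA_real_, G),
    se1 = rep(NA_real_, G), se2 = rep(NA_real_, G),
    p1 = rep(NA_real_, G), p2 = rep(NA_real_, G),
    pattern_key = rep(NA_character_, G), n_obs = integer(G),
    n_conv = integer(G), unfit = rep(TRUE, G)
  )

  chip <- chip_level_columns(x)
  fast <- !is.null(chip) && random == "intercept"
  pre <- if (fast) precompute_designs(x, chip, specs) else NULL

  for (g in seq_len(G)) {
    hit <- if (fast) {
      screen_gene_fast(x$values[g, chip], pre, specs, selection, min_obs)
    } else {
      screen_gene_long(tc_long(x, x$genes[g]), x$time_offset, specs,
                       random, selection, min_obs)
    }
    acc$n_obs[g] <- hit$n_obs
    acc$n_conv[g] <- hit$n_conv
    if (is.null(hit$beta)) next
    pw <- hit$powers
    acc$unfit[g] <- FALSE
    acc$order[g] <- length(pw)
    acc$phi1[g] <- pw[1L]
    acc$phi2[g] <- if (length(pw) > 1L) pw[2L] else NA_real_
    acc$beta0[g] <- hit$beta[1L]
    acc$beta1[g] <- hit$beta[2L]
    acc$se1[g] <- hit$se[2L]
    acc$p1[g] <- pfun(hit$beta[2L] / hit$se[2L], hit$n_obs, length(hit$beta))
    if (length(hit$beta) > 2L) {
      acc$beta2[g] <- hit$beta[3L]
      acc$se2[g] <- hit$se[3L]
      acc$p2[g] <- pfun(hit$beta[3L] / hit$se[3L], hit$n_obs, length(hit$beta))
    }
    signs <- ifelse(hit$beta[-1L] >= 0, "+", "-")
    acc$pattern_key[g] <- paste0("(", paste(pw, collapse = ","), ")",
                                 paste(signs, collapse = ""))
  }

  q <- rep(NA_real_, G)
  significant <- rep(FALSE, G)
  fitted_idx <- which(!acc$unfit)
  if (length(fitted_idx)) {
    pcomb <- acc$p1[fitted_idx]
    two <- !is.na(acc$p2[fitted_idx])
    pcomb[two] <- pmax(pcomb[two], acc$p2[fitted_idx][two])
    q[fitted_idx] <- bh_fdr(pcomb)
    significant[fitted_idx] <- q[fitted_idx] < fdr
  }
  res <- data.frame(
    gene_id = x$genes, order = acc$order, phi1 = acc$phi1, phi2 = acc$phi2,
    beta0 = acc$beta0, beta1 = acc$beta1, beta2 = acc$beta2,
    se1 = acc$se1, se2 = acc$se2, p1 = acc$p1, p2 = acc$p2,
    q = q, significant = significant, pattern_key = acc$pattern_key,
    n_obs = acc$n_obs, n_models_converged = acc$n_conv, unfit = acc$unfit,
    stringsAsFactors = FALSE
  )
  structure(
    list(results = res,
         config = list(order = order, random = random, fdr = fdr,
                       selection = selection, min_obs = min_obs,
                       wald = wald, time_offset = x$time_offset,
                       custom_grid = !is.null(grid)),
         grid = specs),
    class = "fp_screen"
  )
}

# Columns to use when missingness is chip-level: every column of the value
# matrix is entirely observed or entirely missing.  Returns the observed
# column indices, or NULL when missingness is cell-level.
chip_level_columns <- function(x) {
  nmiss <- colSums(is.na(x$values))
  if (all(nmiss == 0L | nmiss == nrow(x$values))) which(nmiss == 0L) else NULL
}

precompute_designs <- function(x, cols, specs) {
  tt <- x$samples$time_hours[cols] + x$time_offset
  subj <- factor(x$samples$subject_id[cols])
  si <- as.integer(subj)
  designs <- lapply(specs, function(sp) {
    X <- tryCatch(cbind(1, fp_transform(tt, sp$powers)),
                  error = function(e) NULL)
    if (is.null(X)) return(NULL)
    st <- ri_stats(X, numeric(length(tt)), si)
    list(X = X, XtX = st$XtX, Sx = st$Sx, n_i = st$n_i, P = ncol(X))
  })
  list(designs = designs, si = si, n = length(cols), S = nlevels(subj))
}

screen_gene_fast <- function(y, pre, specs, selection, min_obs) {
  n <- pre$n
  out <- list(n_obs = n, n_conv = 0L, beta = NULL)
  if (n < min_obs || pre$S < 2L) return(out)
  reml <- selection == "REML"
  best <- NULL; best_aic <- Inf; best_spec <- NA_integer_
  for (m in seq_along(specs)) {
    d <- pre$designs[[m]]
    if (is.null(d)) next
    k <- d$P + 2L
    if (n < k + 1L) next
    st <- list(XtX = d$XtX, Sxy = as.numeric(crossprod(d$X, y)),
               yy = sum(y * y), Sx = d$Sx, Sy = as.numeric(rowsum(y, pre$si)),
               n_i = d$n_i, n = n, P = d$P)
    opt <- tryCatch(ri_maximize(st, reml), error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$crit)) next
    out$n_conv <- out$n_conv + 1L
    aic <- opt$crit + 2 * k
    if (aic < best_aic - 1e-12) {
      best_aic <- aic
      best <- list(st = st, lambda = opt$lambda)
      best_spec <- m
    }
  }
  if (is.null(best)) return(out)
  sol <- ri_solution(best$lambda, best$st, reml)
  out$beta <- sol$beta
  out$se <- sol$se
  out$powers <- specs[[best_spec]]$powers
  out
}

screen_gene_long <- function(long, time_offset, specs, random, selection,
                             min_obs) {
  out <- list(n_obs = nrow(long), n_conv = 0L, beta = NULL)
  if (nrow(long) < min_obs) return(out)
  best <- NULL; best_aic <- Inf
  for (m in seq_along(specs)) {
    f <- fit_gcm_core(long, specs[[m]]$powers, random, time_offset,
                      method = selection, compute_both = FALSE)
    if (!f$converged) next
    out$n_conv <- out$n_conv + 1L
    aic <- model_aic(f, selection)
    if (aic < best_aic - 1e-12) {
      best_aic <- aic
      best <- f
    }
  }
  if (is.null(best)) return(out)
  out$beta <- best$beta
  out$se <- best$se
  out$powers <- best$powers
  out
}

#' @export
print.fp_screen <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "Fractional-polynomial screen: %d genes, order %d grid (%d models), random %s\n",
    nrow(r), x$config$order, length(x$grid), x$config$random
  ))
  cat(sprintf("  fitted: %d   unfit: %d   significant at FDR < %g: %d\n",
              sum(!r$unfit), sum(r$unfit), x$config$fdr, sum(r$significant)))
  invisible(x)
}

#' @export
summary.fp_screen <- function(object, ...) {
  r <- object$results
  sig <- r[r$significant, , drop = FALSE]
  cat(sprintf("%d of %d genes significant at FDR < %g\n",
              nrow(sig), sum(!r$unfit), object$config$fdr))
  if (nrow(sig)) {
    cat("Pattern families among significant genes:\n")
    print(sort(table(sig$pattern_key), decreasing = TRUE))
  }
  invisible(r)
}

#' Write screening results as TSV
#'
#' @param x An \code{fp_screen} object.
#' @param path Output path.
#' @param seed Optional integer recorded in the header for provenance.
#' @export
write_screen <- function(x, path, seed = NA) {
  stopifnot(inherits(x, "fp_screen"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(x$config, seed), con)
  utils::write.table(x$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
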