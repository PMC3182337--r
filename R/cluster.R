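#' Per-gene mean trajectories over the nominal time grid
#'
#' For each gene and nominal time point, the mean of the observed values over
#' subjects; missing cells are excluded from both numerator and count.  This
#' is the summary displayed by time-course heatmaps, with columns ordered
#' sequentially with time.
#'
#' @param x A [time_course_data()] object.
#' @param gene_ids Genes to profile (default all).
#' @return Object of class \code{"mean_profiles"}: a gene-by-time matrix of
#'   means (\code{NA} where no subject was observed) with attribute
#'   \code{n_per_time}, the matching count matrix.
#' @export
mean_profiles <- function(x, gene_ids = x$genes) {
  stopifnot(inherits(x, "tc_data"))
  miss <- setdiff(gene_ids, x$genes)
  if (length(miss)) stop(sprintf("unknown gene(s): %s", paste(miss, collapse = ", ")))
  tms <- sort(unique(x$samples$time_hours))
  V <- x$values[gene_ids, , drop = FALSE]
  tcol <- match(x$samples$time_hours, tms)
  means <- matrix(NA_real_, length(gene_ids), length(tms),
                  dimnames = list(gene_ids, format(tms, trim = TRUE)))
  counts <- matrix(0L, length(gene_ids), length(tms),
                   dimnames = dimnames(means))
  for (k in seq_along(tms)) {
    sub <- V[, tcol == k, drop = FALSE]
    counts[, k] <- rowSums(!is.na(sub))
    mk <- rowMeans(sub, na.rm = TRUE)
    mk[counts[, k] == 0L] <- NA_real_
    means[, k] <- mk
  }
  if (any(rowSums(counts) == 0L)) {
    bad <- gene_ids[rowSums(counts) == 0L]
    stop(sprintf("gene(s) with zero observations at every time: %s",
                 paste(bad, collapse = ", ")))
  }
  structure(means, n_per_time = counts, times = tms, class = "mean_profiles")
}

#' Hierarchical clustering of mean time-course profiles
#'
#' Agglomerative clustering of per-gene mean trajectories.  Profiles are by
#' default standardized per gene (zero mean, unit variance over time) so the
#' clustering groups curve shapes rather than expression levels; per-time
#' means missing for a gene are imputed by that gene's own mean for the
#' distance computation only (with a message).  Uses Euclidean distance and
#' complete linkage by default; [stats::hclust()] merges with the smaller
#' original index first, so leaf order is deterministic.
#'
#' @param profiles A [mean_profiles()] object (2 or more genes).
#' @param metric \code{"euclidean"} or \code{"correlation"} (1 - Pearson).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param standardize Standardize each profile before computing distances.
#' @return Object of class \code{"profile_clust"}: list with the
#'   \code{hclust} tree, \code{leaf_order}, \code{labels} and the processed
#'   profile matrix.
#' @export
cluster_profiles <- function(profiles, metric = c("euclidean", "correlation"),
                             linkage = "complete", standardize = TRUE) {
  stopifnot(inherits(profiles, "mean_profiles"))
  metric <- match.arg(metric)
  M <- unclass(profiles)
  attributes(M)[c("n_per_time", "times", "class")] <- NULL
  if (nrow(M) < 2L) stop("need at least 2 profiles to cluster")
  if (anyNA(M)) {
    message("imputing per-time means missing for some genes by the gene mean (distance computation only)")
    for (i in seq_len(nrow(M))) M[i, is.na(M[i, ])] <- mean(M[i, ], na.rm = TRUE)
  }
  if (standardize) {
    mu <- rowMeans(M)
    sdv <- apply(M, 1, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    M <- (M - mu) / sdv
  }
  d <- if (metric == "euclidean") {
    stats::dist(M)
  } else {
    stats::as.dist(1 - stats::cor(t(M)))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, leaf_order = hc$order,
                 labels = rownames(M)[hc$order], profiles = M,
                 metric = metric, linkage = linkage),
            class = "profile_clust")
}

#' @export
print.profile_clust <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d mean profiles (%s distance, %s linkage)\n",
              length(x$labels), x$metric, x$linkage))
  cat("Leaf order:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Group significant genes into (power, sign) pattern families
#'
#' Partitions the significant genes of a screen by the powers of their best
#' fractional-polynomial model and the signs of its time coefficients; genes
#' sharing powers and signs trace curves of the same qualitative shape.  Each
#' group carries the fitted population curves \eqn{E[y](t)} evaluated on a
#' dense time grid for export or plotting.
#'
#' @param screen An \code{fp_screen} result.
#' @param time_range Raw time range to evaluate curves over; default the
#'   range implied by the screen is unknown here, so supply the observed
#'   range, e.g. \code{range(x$samples$time_hours)}.
#' @param n_grid Number of curve evaluation points.
#' @return List of class \code{"pattern_groups"}; one element per pattern,
#'   each with \code{key}, \code{powers}, \code{signs}, \code{members} and
#'   \code{curves} (data frame \code{gene_id, time, value}).  Empty list when
#'   no gene is significant.
#' @export
pattern_groups <- function(screen, time_range, n_grid = 50L) {
  stopifnot(inherits(screen, "fp_screen"))
  r <- screen$results[screen$results$significant, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(structure(list(), class = "pattern_groups"))
  }
  off <- screen$config$time_offset
  tg <- seq(time_range[1L], time_range[2L], length.out = n_grid)
  out <- list()
  for (key in unique(r$pattern_key)) {
    rk <- r[r$pattern_key == key, , drop = FALSE]
    pw <- c(rk$phi1[1L], rk$phi2[1L])
    pw <- pw[!is.na(pw)]
    Fm <- cbind(1, fp_transform(tg + off, pw))
    curves <- do.call(rbind, lapply(seq_len(nrow(rk)), function(i) {
      beta <- c(rk$beta0[i], rk$beta1[i], rk$beta2[i])
      beta <- beta[!is.na(beta)]
      data.frame(gene_id = rk$gene_id[i], time = tg,
                 value = as.numeric(Fm %*% beta), stringsAsFactors = FALSE)
    }))
    out[[key]] <- list(key = key, powers = pw,
                       signs = ifelse(c(rk$beta1[1L], rk$beta2[1L])[!is.na(c(rk$beta1[1L], rk$beta2[1L]))] >= 0, "+", "-"),
                       members = rk$gene_id, curves = curves)
  }
  structure(out, class = "pattern_groups")
}

#' @export
print.pattern_groups <- function(x, ...) {
  if (!length(x)) {
    cat("No significant genes; no pattern groups.\n")
    return(invisible(x))
  }
  cat(sprintf("%d time-course pattern families:\n", length(x)))
  for (g in x) {
    cat(sprintf("  %-14s %d gene(s): %s\n", g$key, length(g$members),
                paste(utils::head(g$members, 6), collapse = ", ")))
  }
  invisible(x)
}

#' Write clustering and pattern-group outputs
#'
#' Writes \code{leaf_order.tsv}, \code{merges.tsv}, \code{pattern_groups.json}
#' and \code{curves.tsv} into a directory; rendering (heatmaps, trajectory
#' plots) is left to thin consumers of these tables.
#'
#' @param clust A [cluster_profiles()] result (or \code{NULL} to skip).
#' @param groups A [pattern_groups()] result (or \code{NULL} to skip).
#' @param dir Output directory, created if needed.
#' @param seed Optional integer recorded in headers.
#' @export
write_cluster_outputs <- function(clust, groups, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(list(module = "pattern_cluster"), seed)
  if (!is.null(clust)) {
    p1 <- file.path(dir, "leaf_order.tsv")
    con <- file(p1, "w"); writeLines(hdr, con)
    utils::write.table(data.frame(position = seq_along(clust$labels),
                                  gene_id = clust$labels),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    p2 <- file.path(dir, "merges.tsv")
    con <- file(p2, "w"); writeLines(hdr, con)
    utils::write.table(data.frame(step = seq_len(nrow(clust$hclust$merge)),
                                  left = clust$hclust$merge[, 1],
                                  right = clust$hclust$merge[, 2],
                                  height = clust$hclust$height),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(groups)) {
    meta <- lapply(unname(groups), function(g) {
      list(key = g$key, powers = g$powers, signs = g$signs, members = g$members)
    })
    jsonlite::write_json(meta, file.path(dir, "pattern_groups.json"),
                         auto_unbox = TRUE, digits = NA)
    curves <- do.call(rbind, lapply(unname(groups), function(g) {
      cbind(pattern = g$key, g$curves, stringsAsFactors = FALSE)
    }))
    p4 <- file.path(dir, "curves.tsv")
    con <- file(p4, "w"); writeLines(hdr, con)
    if (!is.null(curves)) {
      utils::write.table(curves, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    close(con)
  }
  invisible(dir)
}
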