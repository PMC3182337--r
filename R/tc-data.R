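#' Construct a time-course expression dataset
#'
#' Container for a gene-by-sample matrix of (log-scale) expression values in
#' which each sample is one microarray chip taken from one subject at one
#' time.  Missing chips or cells are stored as \code{NA}; missingness is
#' handled downstream purely by omitting the missing rows of each subject's
#' response vector, which is valid when observations are missing completely
#' at random.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.  Row
#'   names (or \code{genes}) give gene ids; column names must match
#'   \code{samples$sample_id}.
#' @param samples Data frame with columns \code{sample_id}, \code{subject_id}
#'   and \code{time_hours} (finite, non-negative).
#' @param time_offset Value added to every time before any fractional
#'   polynomial transformation.  The default adds 1 when the earliest time is
#'   0, since the power set includes logarithms and negative exponents that
#'   require strictly positive time.
#' @param genes Optional character vector of gene ids overriding row names.
#' @return An object of class \code{"tc_data"}: a list with elements
#'   \code{values}, \code{samples}, \code{genes} and \code{time_offset}.
#' @seealso [read_expression_matrix()], [tc_long()], [observation_pattern()]
#' @export
time_course_data <- function(values, samples, time_offset = NULL, genes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "time_hours")
  if (!all(req %in% names(samples))) {
    stop("'samples' must have columns sample_id, subject_id, time_hours")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$time_hours <- as.numeric(samples$time_hours)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  if (anyNA(samples$time_hours) || any(!is.finite(samples$time_hours)) ||
      any(samples$time_hours < 0)) {
    stop("time_hours must be finite and non-negative")
  }
  if (anyDuplicated(samples[c("subject_id", "time_hours")])) {
    stop("duplicate (subject_id, time_hours) pairs; repeated chips per subject-time are not supported")
  }
  if (is.null(genes)) genes <- rownames(values)
  if (is.null(genes)) stop("gene ids missing: supply 'genes' or matrix row names")
  genes <- as.character(genes)
  if (length(genes) != nrow(values)) stop("length of 'genes' does not match rows of 'values'")
  if (nrow(values) == 0L) stop("no genes: expression matrix body is empty")
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene id: '%s'", genes[duplicated(genes)][1L]))
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  miss_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(miss_meta)) {
    stop(sprintf("sample(s) without metadata: %s", paste(miss_meta, collapse = ", ")))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  rownames(values) <- genes

  # subjects with no observed cell anywhere carry no information at all
  obs_by_sample <- colSums(!is.na(values)) > 0
  subj_obs <- tapply(obs_by_sample, samples$subject_id, any)
  dead <- names(subj_obs)[!subj_obs]
  if (length(dead)) {
    warning(sprintf(
      "dropping subject(s) with no observed values: %s", paste(dead, collapse = ", ")
    ))
    keep <- !(samples$subject_id %in% dead)
    samples <- samples[keep, , drop = FALSE]
    values <- values[, keep, drop = FALSE]
  }

  if (is.null(time_offset)) {
    time_offset <- if (min(samples$time_hours) == 0) 1 else 0
  }
  if (min(samples$time_hours) + time_offset <= 0) {
    stop("time_offset leaves non-positive times; fractional polynomial transforms need t > 0")
  }
  structure(
    list(values = values, samples = samples, genes = genes,
         time_offset = as.numeric(time_offset)),
    class = "tc_data"
  )
}

#' @export
print.tc_data <- function(x, ...) {
  n_obs <- sum(!is.na(x$values))
  cat(sprintf(
    "Time-course expression dataset: %d genes x %d samples\n", nrow(x$values), ncol(x$values)
  ))
  cat(sprintf("  subjects: %d   nominal times (h): %s\n",
              length(unique(x$samples$subject_id)),
              paste(sort(unique(x$samples$time_hours)), collapse = ", ")))
  cat(sprintf("  observed cells: %d of %d (%.1f%% missing)   time offset: +%g\n",
              n_obs, length(x$values),
              100 * (1 - n_obs / length(x$values)), x$time_offset))
  invisible(x)
}

#' @export
dim.tc_data <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix and its sample metadata
#'
#' The matrix file is TSV with a header row of sample ids and a first column
#' named \code{gene_id}; cells that are empty or \code{"NA"}
#' (case-insensitive) are treated as missing, covering the common microarray
#' export dialects.  The metadata file is TSV with columns \code{sample_id},
#' \code{subject_id} and \code{time_hours}.  Every matrix column must have a
#' metadata row; extra metadata rows for absent chips are ignored.
#'
#' @param matrix_path,meta_path Paths to the two TSV files.
#' @param time_offset See [time_course_data()].
#' @param quiet Suppress the per-subject observation-count message.
#' @return A [time_course_data()] object.
#' @export
read_expression_matrix <- function(matrix_path, meta_path, time_offset = NULL,
                                   quiet = FALSE) {
  na_marks <- c("", "NA", "na", "Na", "nA")
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = na_marks,
                           colClasses = NA, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 1L || names(raw)[1L] != "gene_id") {
    stop("malformed header: first column of the expression matrix must be 'gene_id'")
  }
  if (nrow(raw) == 0L) stop("no genes: expression matrix body is empty")
  genes <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.logical(v) && all(is.na(v))) {   # fully missing column
      vals[[j]] <- as.numeric(v)
      next
    }
    if (!is.numeric(v)) {
      bad <- v[!is.na(v)][1L]
      stop(sprintf("non-numeric value '%s' in sample column '%s'", bad, names(vals)[j]))
    }
  }
  values <- as.matrix(vals)
  rownames(values) <- genes
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "time_hours")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns sample_id, subject_id, time_hours")
  }
  meta <- meta[meta$sample_id %in% colnames(values), , drop = FALSE]
  x <- time_course_data(values, meta, time_offset = time_offset)
  if (!quiet) {
    cnt <- table(x$samples$subject_id[colSums(!is.na(x$values)) > 0])
    message(sprintf(
      "read %d genes x %d samples; observed time points per subject: %s",
      nrow(x$values), ncol(x$values),
      paste(sprintf("%s=%d", names(cnt), as.integer(cnt)), collapse = " ")
    ))
  }
  x
}

#' Write a dataset back to the matrix + metadata TSV pair
#'
#' Inverse of [read_expression_matrix()]: a write followed by a read
#' reproduces values, missingness mask and metadata exactly (missing cells
#' are written as \code{NA}).
#'
#' @param x A \code{tc_data} object.
#' @param matrix_path,meta_path Output paths.
#' @export
write_expression_matrix <- function(x, matrix_path, meta_path) {
  stopifnot(inherits(x, "tc_data"))
  df <- data.frame(gene_id = x$genes, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(x$samples[c("sample_id", "subject_id", "time_hours")],
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Long-format observations for one gene
#'
#' Realizes the per-subject incomplete response vectors of the growth curve
#' model: one row per observed chip, missing cells omitted, ordered by
#' subject then time.
#'
#' @param x A \code{tc_data} object.
#' @param gene_id Gene identifier.
#' @return Data frame with columns \code{subject_id}, \code{time_hours},
#'   \code{value}.  Zero rows when the gene was never observed.
#' @export
tc_long <- function(x, gene_id) {
  stopifnot(inherits(x, "tc_data"))
  i <- match(gene_id, x$genes)
  if (is.na(i)) stop(sprintf("unknown gene_id '%s'", gene_id))
  v <- x$values[i, ]
  keep <- !is.na(v)
  out <- data.frame(
    subject_id = x$samples$subject_id[keep],
    time_hours = x$samples$time_hours[keep],
    value = unname(v[keep]),
    stringsAsFactors = FALSE
  )
  out[order(out$subject_id, out$time_hours), , drop = FALSE]
}

#' Subject-by-time observation pattern
#'
#' Tabulates which (subject, nominal time) chips carry at least one observed
#' value, in the style of a design-completeness table for an incomplete
#' time-course experiment.
#'
#' @param x A \code{tc_data} object.
#' @return Object of class \code{"missing_pattern"}: a logical subject-by-time
#'   matrix with attribute \code{n_present}.
#' @export
observation_pattern <- function(x) {
  stopifnot(inherits(x, "tc_data"))
  subs <- sort(unique(x$samples$subject_id))
  tms <- sort(unique(x$samples$time_hours))
  grid <- matrix(FALSE, length(subs), length(tms),
                 dimnames = list(subject = subs, time = format(tms, trim = TRUE)))
  obs <- colSums(!is.na(x$values)) > 0
  for (k in seq_len(ncol(x$values))) {
    if (obs[k]) {
      grid[match(x$samples$subject_id[k], subs),
           match(x$samples$time_hours[k], tms)] <- TRUE
    }
  }
  structure(grid, n_present = sum(grid), times = tms, class = "missing_pattern")
}

#' @export
print.missing_pattern <- function(x, ...) {
  m <- unclass(x)
  disp <- ifelse(m, "x", ".")
  cat(sprintf("Observation pattern: %d of %d subject-time chips present\n",
              attr(x, "n_present"), length(m)))
  print(as.table(disp))
  invisible(x)
}
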