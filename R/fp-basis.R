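#' The fixed fractional-polynomial power set
#'
#' Fractional polynomials restrict the exponents of time transformations to a
#' small fixed set that nevertheless spans a wide family of curve shapes:
#' reciprocals, reciprocal roots, logarithms, roots, linear, quadratic and
#' cubic trends.  The exponent 0 denotes a natural-log transformation, and a
#' repeated exponent denotes multiplication of the previous term by
#' \code{log(t)}.
#'
#' @return Numeric vector \code{c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)}.
#' @seealso [fp_transform()], [fp_models()]
#' @export
#' @examples
#' fp_powers()
fp_powers <- function() {
  c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
}

#' Fractional-polynomial transformation of time
#'
#' Evaluates the fractional-polynomial basis for a tuple of powers
#' \eqn{(\phi_1, \ldots, \phi_p)}: column \eqn{b} is \eqn{t^{\phi_b}}, with
#' \eqn{\phi_b = 0} meaning \eqn{\log t}, and a power equal to the previous
#' one meaning the previous column multiplied by \eqn{\log t} (so the pair
#' \eqn{(\phi, \phi)} yields \eqn{t^{\phi}} and \eqn{t^{\phi} \log t}).
#'
#' All times must be strictly positive; callers working with experiments that
#' start at time zero are expected to apply an offset (conventionally +1)
#' first, since the power set contains logs and negative exponents.
#'
#' @param times Numeric vector of strictly positive (offset) times.
#' @param powers Numeric vector of 1 or more powers, each from [fp_powers()],
#'   non-decreasing.
#' @return Numeric matrix, \code{length(times)} rows and \code{length(powers)}
#'   columns.
#' @export
#' @examples
#' fp_transform(c(1, 2, 4), c(0, 1))   # log t and t
#' fp_transform(4, c(2, 2))            # t^2 and t^2 * log t
fp_transform <- function(times, powers) {
  times <- as.numeric(times)
  powers <- as.numeric(powers)
  if (length(times) == 0L) stop("'times' is empty")
  if (anyNA(times) || any(!is.finite(times))) stop("'times' must be finite")
  if (any(times <= 0)) {
    bad <- times[times <= 0][1L]
    stop(sprintf(
      "all times must be strictly positive after the offset; found %g (apply a time offset, e.g. +1)",
      bad
    ))
  }
  if (length(powers) < 1L) stop("'powers' must contain at least one power")
  if (!all(powers %in% fp_powers())) {
    stop(sprintf(
      "powers must come from the fixed set {%s}; got (%s)",
      paste(fp_powers(), collapse = ", "), paste(powers, collapse = ", ")
    ))
  }
  if (is.unsorted(powers)) stop("'powers' must be non-decreasing")
  out <- matrix(NA_real_, length(times), length(powers))
  lt <- log(times)
  for (b in seq_along(powers)) {
    if (b > 1L && powers[b] == powers[b - 1L]) {
      out[, b] <- out[, b - 1L] * lt
    } else if (powers[b] == 0) {
      out[, b] <- lt
    } else {
      out[, b] <- times^powers[b]
    }
  }
  colnames(out) <- fp_term_names(powers)
  out
}

fp_term_names <- function(powers) {
  nm <- character(length(powers))
  for (b in seq_along(powers)) {
    if (b > 1L && powers[b] == powers[b - 1L]) {
      nm[b] <- paste0(nm[b - 1L], ".log(t)")
    } else if (powers[b] == 0) {
      nm[b] <- "log(t)"
    } else {
      nm[b] <- paste0("t^", format(powers[b]))
    }
  }
  nm
}

#' Enumerate the fixed grid of candidate fractional-polynomial models
#'
#' First-order models use one power each from the 8-element set; second-order
#' models use every pair \eqn{\phi_1 \le \phi_2}, giving \eqn{8 + 28 = 36}
#' candidates (the 8 repeated-power pairs encode a \eqn{t^\phi \log t} term).
#' The grid is returned in lexicographic power order; this canonical order is
#' also used to break AIC ties during screening, so enumeration is
#' deterministic across platforms and runs.
#'
#' @param order Integer, 1 or 2 (higher orders are rejected: second-order
#'   fractional polynomials already cover the curvature shapes of interest and
#'   higher orders overfit short series).
#' @param random Random-effect structure attached to each spec:
#'   \code{"intercept"} (subject-level random intercept only) or
#'   \code{"slopes"} (a random effect for every fixed time term as well).
#' @return A list of model specifications, each a list with elements
#'   \code{powers} (numeric vector) and \code{random} (character), of length 8
#'   (order 1) or 36 (order 2).
#' @export
#' @examples
#' length(fp_models(2))       # 36
#' fp_models(1)[[6]]$powers   # 1: the linear model
fp_models <- function(order = 2L, random = c("intercept", "slopes")) {
  random <- match.arg(random)
  if (!order %in% c(1L, 2L)) {
    stop("'order' must be 1 or 2; higher-order fractional polynomials are not supported")
  }
  pw <- fp_powers()
  specs <- list()
  if (order == 1L) {
    for (p1 in pw) specs[[length(specs) + 1L]] <- list(powers = p1, random = random)
  } else {
    for (i in seq_along(pw)) {
      for (j in i:length(pw)) {
        specs[[length(specs) + 1L]] <- list(powers = c(pw[i], pw[j]), random = random)
      }
    }
  }
  specs
}

#' Build fixed- and random-effect design matrices for one subject
#'
#' The fixed design is \code{X = [1 | fp_transform(times, powers)]}.  The
#' random design \code{Z} is the first column of \code{X} for a
#' random-intercept model, or all of \code{X} when every fixed time term has a
#' corresponding random effect.
#'
#' @param times Strictly positive (offset) observation times for one subject.
#' @param spec A model specification as produced by [fp_models()], or any list
#'   with elements \code{powers} and \code{random}.
#' @return List with matrices \code{X} and \code{Z}.
#' @export
#' @examples
#' fp_design(c(1, 2), list(powers = 1, random = "intercept"))
fp_design <- function(times, spec) {
  Fm <- fp_transform(times, spec$powers)
  X <- cbind(`(Intercept)` = 1, Fm)
  Z <- if (identical(spec$random, "slopes")) X else X[, 1L, drop = FALSE]
  list(X = X, Z = Z)
}
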