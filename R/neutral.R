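# The neutral-evolution test: under neutral growth the cumulative count of
# subclonal mutations M(f) is linear in the inverse allele frequency,
# M(f) = (mu/beta) * (1/f - 1/f_max). The fit is a zero-intercept least
# squares regression of M on x = 1/f - 1/f_max evaluated at the observed
# frequencies; goodness-of-fit is R^2 about the mean of M (so R^2 can go
# negative for fits worse than a flat line), and neutrality is declared by a
# strict R^2 threshold.

#' Subclonal frequency window
#'
#' Restricts purity-adjusted VAFs to the subclonal window, strict on both
#' sides by default: clonal variants (`f >= f_max`) and unreliable
#' low-frequency variants (`f <= f_min`) are removed. Set
#' `inclusive_lower = TRUE` for the public-data reading that admits
#' `f = f_min`.
#'
#' @param adjusted_vafs Numeric vector of purity-adjusted VAFs in `[0, 1]`.
#' @param f_min,f_max Window bounds (defaults 0.10 and 0.25).
#' @param inclusive_lower Keep `f == f_min` as well (default `FALSE`).
#' @param source Label for the sample, or `"pooled"`.
#' @return An object of class `subclonal_set` with fields `vafs`, `f_min`,
#'   `f_max`, `source`.
#' @export
subclonal_window <- function(adjusted_vafs, f_min = 0.10, f_max = 0.25,
                             inclusive_lower = FALSE, source = "sample") {
  adjusted_vafs <- adjusted_vafs[!is.na(adjusted_vafs)]
  stopifnot(all(adjusted_vafs >= 0 & adjusted_vafs <= 1), f_min < f_max)
  keep <- if (inclusive_lower) adjusted_vafs >= f_min else adjusted_vafs > f_min
  keep <- keep & adjusted_vafs < f_max
  structure(list(vafs = adjusted_vafs[keep], f_min = f_min, f_max = f_max,
                 source = source),
            class = "subclonal_set")
}

#' @export
print.subclonal_set <- function(x, ...) {
  cat(sprintf("<subclonal_set> %s: %d variants in (%g, %g)\n",
              x$source, length(x$vafs), x$f_min, x$f_max))
  invisible(x)
}

#' Cumulative subclonal mutation distribution M(f)
#'
#' With `eval = "observed"` (default) frequencies are sorted in descending
#' order and the cumulative count is evaluated at each observed frequency:
#' `M_i = i` is the number of mutations with frequency at least `f_(i)`,
#' plotted against `x_i = 1/f_(i) - 1/f_max`; tied frequencies keep
#' distinct consecutive ranks (stable descending order). With
#' `eval = "grid"` the curve is evaluated at `grid_points` equally spaced
#' values of `1/f - 1/f_max` spanning the window, the canonical binned form
#' of the test (and the default used by [fit_neutral_model()], which is
#' less sensitive to mutations tied on a shared genealogical branch).
#'
#' @param s A [subclonal_window()] result.
#' @param eval `"observed"` or `"grid"`.
#' @param grid_points Number of grid points for `eval = "grid"`.
#' @return A data frame with columns `f`, `x` and `M`; the window's `f_max`
#'   and the variant count are attached as attributes.
#' @export
cumulative_mf <- function(s, eval = c("observed", "grid"),
                          grid_points = 100L) {
  stopifnot(inherits(s, "subclonal_set"))
  eval <- match.arg(eval)
  if (!length(s$vafs)) {
    out <- data.frame(f = numeric(), x = numeric(), M = integer())
  } else if (eval == "observed") {
    f <- sort(s$vafs, decreasing = TRUE)
    out <- data.frame(f = f, x = 1 / f - 1 / s$f_max, M = seq_along(f))
  } else {
    x <- seq(0, 1 / s$f_min - 1 / s$f_max,
             length.out = grid_points + 1L)[-1L]
    f <- 1 / (x + 1 / s$f_max)
    M <- vapply(f, function(ff) sum(s$vafs >= ff), numeric(1))
    out <- data.frame(f = f, x = x, M = M)
  }
  attr(out, "f_max") <- s$f_max
  attr(out, "source") <- s$source
  attr(out, "n_variants") <- length(s$vafs)
  out
}

#' @noRd
fit_pairs_origin <- function(d) {
  slope <- max(0, sum(d$x * d$M) / sum(d$x^2))
  sstot <- sum((d$M - mean(d$M))^2)
  r2 <- if (sstot > 0) 1 - sum((d$M - slope * d$x)^2) / sstot else NA_real_
  list(slope = slope, r2 = r2)
}

#' Fit the neutral 1/f model
#'
#' Zero-intercept least squares of `M` on `x`: the fitted slope
#' `sum(x*M)/sum(x^2)` estimates the effective mutation rate per effective
#' division (mu/beta) in model units. `R^2 = 1 - SSres/SStot` with the
#' total sum of squares taken about the mean of `M`; fits worse than a flat
#' line therefore give negative values. For a [subclonal_window()] input
#' the curve is evaluated on a fixed inverse-frequency grid by default
#' (`mf_eval = "grid"`, see [cumulative_mf()]); `mf_eval = "observed"`
#' evaluates at the observed frequencies instead. `n_variants` is always
#' the number of subclonal variants, not the number of evaluation points.
#' With fewer than 10 variants the fit is re-computed dropping each variant
#' (or point) in turn, and `flagged_single_point_influence` is set when any
#' single removal changes the classification.
#'
#' @param x A [subclonal_window()] result, or a data frame with columns `x`
#'   and `M` (as produced by [cumulative_mf()]).
#' @param r2_threshold Strict R^2 threshold for neutrality (default 0.98).
#' @param min_variants Minimum variant count for classification (default 2,
#'   the least that admits a fit; use 12 for sparse public-data mode).
#' @param mf_eval Evaluation of M(f) for subclonal-set input: `"grid"`
#'   (default) or `"observed"`.
#' @param grid_points Grid resolution for `mf_eval = "grid"`.
#' @return An object of class `neutral_fit` with components `slope`,
#'   `r_squared`, `n_variants`, `classification` (`"neutral"`,
#'   `"non_neutral"` or `"insufficient"`), `flagged_single_point_influence`,
#'   `data`, `source`, `r2_threshold`, `min_variants`.
#' @export
fit_neutral_model <- function(x, r2_threshold = 0.98, min_variants = 2L,
                              mf_eval = c("grid", "observed"),
                              grid_points = 100L) {
  mf_eval <- match.arg(mf_eval)
  source <- "data"
  vafs <- NULL
  set <- NULL
  if (inherits(x, "subclonal_set")) {
    set <- x
    source <- x$source
    vafs <- x$vafs
    x <- cumulative_mf(set, eval = mf_eval, grid_points = grid_points)
  } else if (!is.null(attr(x, "source"))) {
    source <- attr(x, "source")
  }
  stopifnot(is.data.frame(x), all(c("x", "M") %in% names(x)))
  n <- if (!is.null(vafs)) length(vafs) else nrow(x)
  wrap <- function(slope, r2, cls, flagged) {
    structure(
      list(slope = slope, r_squared = r2, n_variants = n,
           classification = cls, flagged_single_point_influence = flagged,
           data = x, source = source, r2_threshold = r2_threshold,
           min_variants = min_variants),
      class = "neutral_fit")
  }
  if (n < 2L || nrow(x) < 2L || length(unique(x$x)) < 2L) {
    f <- if (nrow(x) >= 1L) fit_pairs_origin(x)
         else list(slope = NA_real_, r2 = NA_real_)
    return(wrap(f$slope, f$r2, "insufficient", FALSE))
  }
  f <- fit_pairs_origin(x)
  cls <- classify_evolution(f$r2, n_variants = n, r2_threshold = r2_threshold,
                            min_variants = min_variants)
  flagged <- FALSE
  if (n < 10L) {
    refit <- function(i) {
      if (!is.null(set)) {
        s2 <- set; s2$vafs <- vafs[-i]
        fit_pairs_origin(cumulative_mf(s2, eval = mf_eval,
                                       grid_points = grid_points))$r2
      } else {
        fit_pairs_origin(x[-i, , drop = FALSE])$r2
      }
    }
    for (i in seq_len(n)) {
      ci <- classify_evolution(refit(i), n_variants = n - 1L,
                               r2_threshold = r2_threshold,
                               min_variants = min(min_variants, n - 1L))
      if (!identical(ci, cls)) { flagged <- TRUE; break }
    }
  }
  wrap(f$slope, f$r2, cls, flagged)
}

#' Classify a fit as neutral or non-neutral
#'
#' Neutral exactly when `r_squared > r2_threshold` (strict) and the variant
#' count reaches `min_variants`; `"insufficient"` when the count falls short.
#'
#' @param x A `neutral_fit` or a bare R^2 value.
#' @param n_variants Variant count (taken from the fit when `x` is one;
#'   `NULL` skips the count check).
#' @param r2_threshold Strict threshold (default 0.98).
#' @param min_variants Minimum count (default 0 for a bare value).
#' @return `"neutral"`, `"non_neutral"` or `"insufficient"`.
#' @export
classify_evolution <- function(x, n_variants = NULL, r2_threshold = 0.98,
                               min_variants = 0L) {
  if (inherits(x, "neutral_fit")) {
    n_variants <- x$n_variants
    x <- x$r_squared
  }
  if (!is.null(n_variants) && n_variants < min_variants) return("insufficient")
  if (is.na(x)) return("insufficient")
  if (x > r2_threshold) "neutral" else "non_neutral"
}

#' Pooled (collective) fit over several samples
#'
#' Concatenates the subclonal VAFs of all samples into one pooled set (all
#' windows must agree) and fits the 1/f model to the pooled cumulative
#' distribution.
#'
#' @param samples List of [subclonal_window()] results with identical
#'   windows.
#' @param ... Passed to [fit_neutral_model()].
#' @return A `neutral_fit` with `source = "pooled"`.
#' @export
pooled_fit <- function(samples, ...) {
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "subclonal_set")))
  fmin <- unique(vapply(samples, function(s) s$f_min, numeric(1)))
  fmax <- unique(vapply(samples, function(s) s$f_max, numeric(1)))
  if (length(fmin) != 1L || length(fmax) != 1L) {
    stop("cannot pool subclonal sets with different windows", call. = FALSE)
  }
  pooled <- structure(
    list(vafs = unlist(lapply(samples, function(s) s$vafs), use.names = FALSE),
         f_min = fmin, f_max = fmax, source = "pooled"),
    class = "subclonal_set")
  fit_neutral_model(pooled, ...)
}

#' Paired diagnosis-to-relapse R^2 shift summary
#'
#' @param fits Data frame with columns `patient_id`, `r2_diagnosis`,
#'   `r2_relapse` (one row per analyzable pair).
#' @return A list: `table` (input plus logical `decreased`), `n_pairs`,
#'   `n_decreased`, and `sign_test_p` (two-sided exact sign test on the
#'   direction of change, ties dropped; `NA` with no untied pairs).
#' @export
paired_shift_summary <- function(fits) {
  stopifnot(is.data.frame(fits),
            all(c("patient_id", "r2_diagnosis", "r2_relapse") %in% names(fits)))
  fits$decreased <- fits$r2_relapse < fits$r2_diagnosis
  untied <- fits$r2_relapse != fits$r2_diagnosis
  p <- if (any(untied)) {
    stats::binom.test(sum(fits$decreased[untied]), sum(untied),
                      p = 0.5)$p.value
  } else NA_real_
  list(table = fits, n_pairs = nrow(fits),
       n_decreased = sum(fits$decreased), sign_test_p = p)
}

# --------------------------------------------------------------------------
# Methods for the neutral_fit model object
# --------------------------------------------------------------------------

#' @export
print.neutral_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Neutral-evolution 1/f fit (%s)\n", x$source))
  cat(sprintf("  n = %d subclonal variants\n", x$n_variants))
  if (!is.na(x$slope)) {
    cat(sprintf("  slope (mu/beta): %.*g\n", digits, x$slope))
  }
  if (!is.na(x$r_squared %||% NA)) {
    cat(sprintf("  R-squared: %s\n", display_r2(x$r_squared)))
  }
  cat(sprintf("  classification: %s (R^2 > %g, n >= %d)\n",
              x$classification, x$r2_threshold, x$min_variants))
  if (x$flagged_single_point_influence) {
    cat("  note: classification changes if a single point is removed\n")
  }
  invisible(x)
}

#' @export
summary.neutral_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 residual_summary = if (length(res)) summary(res) else NULL),
            class = "summary.neutral_fit")
}

#' @export
print.summary.neutral_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$residual_summary)) {
    cat("Residuals (M - slope * x):\n")
    print(x$residual_summary)
  }
  invisible(x)
}

#' @export
coef.neutral_fit <- function(object, ...) c(slope = object$slope)

#' @export
fitted.neutral_fit <- function(object, ...) object$slope * object$data$x

#' @export
residuals.neutral_fit <- function(object, ...) {
  object$data$M - fitted(object)
}

#' Predict the cumulative mutation count at given frequencies
#'
#' @param object A `neutral_fit`.
#' @param newdata Optional data frame with a column `x` (inverse-frequency
#'   offsets) or `f` (frequencies, converted using the fit's window).
#' @param ... Unused.
#' @return Numeric vector of predicted M values.
#' @export
predict.neutral_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  x <- if ("x" %in% names(newdata)) {
    newdata$x
  } else if ("f" %in% names(newdata)) {
    fmax <- attr(object$data, "f_max")
    if (is.null(fmax)) stop("fit carries no window; supply 'x' directly",
                            call. = FALSE)
    1 / newdata$f - 1 / fmax
  } else {
    stop("newdata must have a column 'x' or 'f'", call. = FALSE)
  }
  object$slope * x
}

#' Plot a neutral fit
#'
#' Cumulative M(f) against `1/f - 1/f_max` with the fitted zero-intercept
#' line.
#'
#' @param x A `neutral_fit`.
#' @param ... Passed to [plot.default()].
#' @export
plot.neutral_fit <- function(x, ...) {
  d <- x$data
  plot(d$x, d$M, xlab = expression(1 / f - 1 / f[max]),
       ylab = "M(f): cumulative mutations", pch = 19,
       main = sprintf("%s: R² = %s (%s)", x$source,
                      display_r2(x$r_squared), x$classification), ...)
  if (!is.na(x$slope)) graphics::abline(0, x$slope, col = "firebrick")
  invisible(x)
}
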