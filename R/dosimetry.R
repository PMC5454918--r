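#' Biological dosimetry from per-nucleus ALU point counts
#'
#' The number of ALU COMBO-FISH signals detected per nucleus decreases with
#' absorbed radiation dose. The calibration curve is the quadratic
#' dose-effect model
#'
#'   N(D) = a * D^2 + b * D + c
#'
#' with N the detected point count, D the dose in Gy and a, b, c empirical
#' fit constants. Fitting is ordinary least squares on the per-dose mean
#' counts (a per-cell fit is available); dose estimation inverts the fitted
#' curve on its calibrated, decreasing branch.
#'
#' @name dosimetry
NULL

#' Count localizations of a channel inside a nucleus boundary
#'
#' @param points localization table.
#' @param channel channel label to count; must exist in the table (an empty
#'   table counts 0 for any channel).
#' @param boundary optional two-column matrix of polygon vertices (nm); when
#'   NULL all points of the channel are counted.
#' @return integer count.
#' @export
count_points <- function(points, channel, boundary = NULL) {
  if (nrow(points) == 0L) return(0L)
  cl_assert(channel %in% points$channel, "unknown channel: ", channel)
  sel <- points$channel == channel
  if (is.null(boundary)) return(sum(sel))
  cl_assert(is.matrix(boundary) && ncol(boundary) == 2L && nrow(boundary) >= 3L,
            "boundary must be a polygon matrix with >= 3 vertices")
  inside <- mgcv::in.out(boundary, cbind(points$x_nm[sel], points$y_nm[sel]))
  sum(inside)
}

#' Fit the quadratic dose-effect model
#'
#' Ordinary least squares of the count on (D^2, D, 1). With
#' `method = "per_dose_mean"` (default) the response is the mean count per
#' dose; `method = "per_cell"` fits all cells directly. Three distinct
#' noiseless dose means are interpolated exactly.
#'
#' @param counts data frame with `dose_gy` and `count` (one row per cell).
#' @param method "per_dose_mean" (default) or "per_cell".
#' @return object of class `dose_response_fit`: list with `a`, `b`, `c`,
#'   `rss`, `doses`, `n_per_dose`, `method`.
#' @export
fit_dose_response <- function(counts, method = c("per_dose_mean", "per_cell")) {
  method <- match.arg(method)
  cl_assert(all(c("dose_gy", "count") %in% names(counts)),
            "counts needs columns dose_gy and count")
  doses <- sort(unique(counts$dose_gy))
  cl_assert(length(doses) >= 3L, "at least 3 distinct doses are required")
  if (method == "per_dose_mean") {
    y <- tapply(counts$count, counts$dose_gy, mean)
    d <- as.numeric(names(y))
    y <- as.numeric(y)
  } else {
    d <- counts$dose_gy
    y <- counts$count
  }
  fit <- stats::lm(y ~ d + I(d^2))
  co <- stats::coef(fit)
  structure(list(a = unname(co[["I(d^2)"]]), b = unname(co[["d"]]),
                 c = unname(co[["(Intercept)"]]),
                 rss = sum(stats::residuals(fit)^2),
                 doses = doses,
                 n_per_dose = as.integer(table(counts$dose_gy)[as.character(doses)]),
                 method = method),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Quadratic dose-effect fit N(D) = a D^2 + b D + c (%s)\n", x$method))
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g, rss = %.6g\n", x$a, x$b, x$c, x$rss))
  cat(sprintf("  doses (Gy): %s\n", paste(x$doses, collapse = ", ")))
  invisible(x)
}

#' Predict the expected count at a dose
#'
#' @param fit a `dose_response_fit` (or any list with `a`, `b`, `c`).
#' @param dose_gy dose(s) in Gy, >= 0.
#' @return expected count(s) a*D^2 + b*D + c.
#' @export
predict_count <- function(fit, dose_gy) {
  cl_assert(all(dose_gy >= 0), "dose_gy must be >= 0")
  fit$a * dose_gy^2 + fit$b * dose_gy + fit$c
}

#' Estimate the dose from an observed count
#'
#' Inverts the fitted curve: returns the smallest non-negative root of
#' a*D^2 + b*D + (c - N) inside the calibrated interval. For a > 0 the
#' inversion is restricted to the decreasing branch `[0, -b/(2a)]`
#' (capped at the largest calibrated dose); counts outside the attainable
#' range raise an out-of-calibration error.
#'
#' @param fit a `dose_response_fit`.
#' @param observed_count the measured per-nucleus count.
#' @return estimated dose in Gy.
#' @export
estimate_dose <- function(fit, observed_count) {
  hi <- max(fit$doses)
  if (fit$a > 0 && fit$b < 0) hi <- min(hi, -fit$b / (2 * fit$a))
  roots <- if (abs(fit$a) < 1e-12) {
    cl_assert(abs(fit$b) > 0, "degenerate fit: a = b = 0")
    (observed_count - fit$c) / fit$b
  } else {
    disc <- fit$b^2 - 4 * fit$a * (fit$c - observed_count)
    if (disc < 0) numeric(0) else
      (-fit$b + c(-1, 1) * sqrt(disc)) / (2 * fit$a)
  }
  eps <- 1e-9 * max(1, hi)
  roots <- roots[roots >= -eps & roots <= hi + eps]
  if (length(roots) == 0L) {
    cl_stop("observed count ", observed_count,
            " is out of calibration for this fit (interval [0, ",
            signif(hi, 6), "] Gy)")
  }
  max(0, min(roots))
}
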