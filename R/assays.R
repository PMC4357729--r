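#' Pearson colocalization of two fluorescence channels
#'
#' Sample Pearson correlation of paired per-pixel intensities from two
#' channels of one cell; the cell is classified as showing colocalization
#' when the coefficient reaches the threshold (inclusive). If either
#' channel is constant the coefficient is undefined and reported as `NA`
#' with `colocalized = FALSE`.
#'
#' @param x,y Numeric intensity vectors of equal length (>= 2).
#' @param threshold Classification threshold on the coefficient,
#'   inclusive. Default 0.3.
#' @return List with `rho` and `colocalized`.
#' @export
pearson_colocalization <- function(x, y, threshold = 0.3) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2, all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, colocalized = FALSE))
  }
  rho <- stats::cor(x, y)
  list(rho = rho, colocalized = rho >= threshold)
}

#' Dual-sensor reporter normalization
#'
#' Normalized activity of a miRNA luciferase sensor: the mean luminescence
#' of the wild-type sensor (carrying functional miRNA binding sites)
#' divided by the mean of the mutant sensor (mismatched sites, insensitive
#' to the miRNA). Lower activity means stronger repression, i.e. higher
#' miRNA activity. Optionally rescaled to a reference condition.
#'
#' @param wt_wells Replicate luminescence values of the wild-type sensor.
#' @param mut_wells Replicate values of the mutant sensor.
#' @param reference Optional reference: a `reporter_result` or a single
#'   positive number; the returned activity is divided by it.
#' @return A `reporter_result`: list with `wt_mean`, `mut_mean` and
#'   `activity`.
#' @export
normalize_reporter <- function(wt_wells, mut_wells, reference = NULL) {
  stopifnot(is.numeric(wt_wells), is.numeric(mut_wells),
            length(wt_wells) >= 1, length(mut_wells) >= 1)
  if (any(!is.finite(wt_wells)) || any(!is.finite(mut_wells)) ||
      any(wt_wells <= 0) || any(mut_wells <= 0)) {
    stop("luminescence values must be positive", call. = FALSE)
  }
  activity <- mean(wt_wells) / mean(mut_wells)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "reporter_result"))
      reference$activity else reference
    stopifnot(is.numeric(ref), length(ref) == 1, ref > 0)
    activity <- activity / ref
  }
  structure(list(wt_mean = mean(wt_wells), mut_mean = mean(mut_wells),
                 activity = activity),
            class = "reporter_result")
}

#' @export
print.reporter_result <- function(x, ...) {
  cat(sprintf("<reporter_result> activity = %.4g (wt %.4g / mut %.4g)\n",
              x$activity, x$wt_mean, x$mut_mean))
  invisible(x)
}
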