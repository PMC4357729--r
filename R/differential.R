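#' Configuration for the intensity-binned robust z-test
#'
#' Differential abundance between the differentiating and proliferating
#' samples is assessed on the log2 count ratio. Because spectral-count
#' ratio noise shrinks with abundance, proteins are binned by intensity
#' (log2 mean count) and each bin supplies its own null location and scale,
#' estimated robustly by two-sided trimming.
#'
#' @param trim_fraction Fraction trimmed on each side of a bin before
#'   computing mean and SD. Default 0.025 (2.5% per side).
#' @param bin_target Target bin occupancy (proteins per bin). Default 150.
#' @param bin_min Minimum occupancy; a trailing bin smaller than this is
#'   merged into its neighbor. Default 50.
#' @param alpha_diff Significance threshold; calls need `p < alpha_diff`
#'   (strict). Default 0.1.
#' @param lfc_threshold Absolute log2 fold-change a call must exceed
#'   (strict). Default 0.5.
#' @param two_sided Two-sided p-values? Default `TRUE` (both directions are
#'   reported against a single threshold).
#' @param consistency_correction Divide the trimmed SD by the
#'   truncated-normal consistency constant (about 0.8711 at 2.5% per side)
#'   so z-scores are calibrated under normality? Default `TRUE`.
#' @param normalize_depth Rescale each sample's counts so sample totals are
#'   equal to their mean before forming intensities and ratios? Default
#'   `TRUE`.
#' @return A `differential_config` list.
#' @export
differential_config <- function(trim_fraction = 0.025, bin_target = 150,
                                bin_min = 50, alpha_diff = 0.1,
                                lfc_threshold = 0.5, two_sided = TRUE,
                                consistency_correction = TRUE,
                                normalize_depth = TRUE) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5,
            bin_target >= 1, bin_min >= 1,
            alpha_diff > 0, alpha_diff < 1, lfc_threshold >= 0)
  structure(list(trim_fraction = trim_fraction,
                 bin_target = as.integer(bin_target),
                 bin_min = as.integer(bin_min),
                 alpha_diff = alpha_diff, lfc_threshold = lfc_threshold,
                 two_sided = isTRUE(two_sided),
                 consistency_correction = isTRUE(consistency_correction),
                 normalize_depth = isTRUE(normalize_depth)),
            class = "differential_config")
}

#' Consistency constant for a two-sided trimmed SD
#'
#' The SD of a standard normal sample trimmed by `trim_fraction` per side
#' converges to `sqrt(1 - 2 a phi(a) / (2 Phi(a) - 1))` with
#' `a = qnorm(1 - trim_fraction)`; dividing the trimmed SD by this constant
#' makes it a consistent estimate of the untrimmed SD under normality.
#'
#' @param trim_fraction Trim fraction per side, in `[0, 0.5)`.
#' @return The consistency constant (about 0.8711 at 0.025).
#' @export
trim_consistency_factor <- function(trim_fraction) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  if (trim_fraction == 0) return(1)
  a <- stats::qnorm(1 - trim_fraction)
  sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
}

#' Assign proteins to equal-occupancy intensity bins
#'
#' Proteins are ranked by intensity (ties broken by `ids` for determinism)
#' and cut into consecutive bins of `bin_target` members; a trailing
#' remainder smaller than `bin_min` is merged into the last full bin.
#'
#' @param intensity Numeric vector of intensities (finite).
#' @param cfg A [differential_config()].
#' @param ids Optional tie-break keys (default: input order).
#' @return Integer bin index per input element (1 = lowest intensity).
#' @export
assign_bins <- function(intensity, cfg = differential_config(),
                        ids = seq_along(intensity)) {
  n <- length(intensity)
  if (n == 0) return(integer(0))
  stopifnot(all(is.finite(intensity)), length(ids) == n)
  ord <- order(intensity, ids)
  n_full <- n %/% cfg$bin_target
  if (n_full == 0) {
    sizes <- n
  } else {
    sizes <- rep(cfg$bin_target, n_full)
    rem <- n - n_full * cfg$bin_target
    if (rem >= cfg$bin_min) sizes <- c(sizes, rem)
    else sizes[n_full] <- sizes[n_full] + rem
  }
  bin <- integer(n)
  bin[ord] <- rep.int(seq_along(sizes), sizes)
  bin
}

#' Trimmed, consistency-corrected location and scale of a bin
#'
#' Removes the `floor(trim_fraction * n)` smallest and largest ratios, then
#' computes the mean and sample SD of the remainder; with
#' `consistency_correction` the SD is divided by
#' [trim_consistency_factor()] so it estimates the untrimmed SD under
#' normality.
#'
#' @param ratios Numeric vector of log2 ratios.
#' @param cfg A [differential_config()].
#' @return List with `n`, `n_trimmed` (members kept), `mean`, `sd_raw`
#'   (uncorrected trimmed SD, `NA` if fewer than 2 kept) and `sd`
#'   (corrected; equal to `sd_raw` when correction is off).
#' @export
trimmed_bin_stats <- function(ratios, cfg = differential_config()) {
  n <- length(ratios)
  stopifnot(n >= 1, all(is.finite(ratios)))
  k <- floor(cfg$trim_fraction * n)
  x <- sort(ratios)
  kept <- if (k > 0) x[(k + 1):(n - k)] else x
  mu <- mean(kept)
  sd_raw <- if (length(kept) >= 2) stats::sd(kept) else NA_real_
  cf <- if (cfg$consistency_correction)
    trim_consistency_factor(cfg$trim_fraction) else 1
  list(n = n, n_trimmed = length(kept), mean = mu, sd_raw = sd_raw,
       sd = sd_raw / cf)
}

#' Intensity-binned robust z-test on precomputed ratios
#'
#' The workhorse behind [differential_test()], exposed directly so
#' calibration can be studied on arbitrary (intensity, ratio) data. Every
#' protein - including those trimmed away when estimating the bin
#' statistics - is standardized with its bin's trimmed mean and corrected
#' SD (the within-bin standardization is extended linearly beyond the
#' trimmed range), then converted to a normal p-value.
#'
#' Bins whose trimmed SD is zero (or undefined) fall back to the pooled
#' corrected trimmed SD over all ratios; if that is also degenerate, the
#' affected proteins get `p = 1` and a warning is issued.
#'
#' @param intensity Numeric intensities (binning variable).
#' @param ratio Numeric log2 ratios, same length.
#' @param cfg A [differential_config()].
#' @param ids Optional protein identifiers (tie-breaks and output).
#' @return List with `records` (tibble `id`, `intensity`, `ratio`, `bin`,
#'   `z`, `p_value`) and `bins` (tibble of per-bin statistics:
#'   `bin`, `n`, `n_trimmed`, `intensity_min`, `intensity_max`, `mean`,
#'   `sd_raw`, `sd`, `sd_used`, `degenerate`).
#' @export
binned_z_test <- function(intensity, ratio, cfg = differential_config(),
                          ids = NULL) {
  n <- length(intensity)
  stopifnot(length(ratio) == n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0) {
    return(list(
      records = tibble::tibble(id = character(0), intensity = numeric(0),
                               ratio = numeric(0), bin = integer(0),
                               z = numeric(0), p_value = numeric(0)),
      bins = tibble::tibble(bin = integer(0), n = integer(0),
                            n_trimmed = integer(0),
                            intensity_min = numeric(0),
                            intensity_max = numeric(0), mean = numeric(0),
                            sd_raw = numeric(0), sd = numeric(0),
                            sd_used = numeric(0), degenerate = logical(0))
    ))
  }
  bin <- assign_bins(intensity, cfg, ids = ids)
  stats_list <- lapply(sort(unique(bin)), function(b) {
    s <- trimmed_bin_stats(ratio[bin == b], cfg)
    tibble::tibble(bin = b, n = s$n, n_trimmed = s$n_trimmed,
                   intensity_min = min(intensity[bin == b]),
                   intensity_max = max(intensity[bin == b]),
                   mean = s$mean, sd_raw = s$sd_raw, sd = s$sd)
  })
  bins <- dplyr::bind_rows(stats_list)
  pooled <- trimmed_bin_stats(ratio, cfg)$sd
  bins$degenerate <- !is.finite(bins$sd) | bins$sd == 0
  bins$sd_used <- ifelse(bins$degenerate, pooled, bins$sd)
  if (any(bins$degenerate)) {
    if (!is.finite(pooled) || pooled == 0) {
      warning("all ratios are degenerate (zero spread); ",
              "affected proteins get p = 1", call. = FALSE)
      bins$sd_used[!is.finite(bins$sd_used) | bins$sd_used == 0] <- NA_real_
    }
  }
  idx <- match(bin, bins$bin)
  z <- (ratio - bins$mean[idx]) / bins$sd_used[idx]
  z[!is.finite(z)] <- 0
  p <- if (cfg$two_sided) 2 * stats::pnorm(-abs(z)) else
    stats::pnorm(z, lower.tail = FALSE)
  p[!is.finite(bins$sd_used[idx])] <- 1
  list(records = tibble::tibble(id = ids, intensity = intensity,
                                ratio = ratio, bin = bin, z = z,
                                p_value = p),
       bins = bins)
}

#' Differential abundance between differentiating and proliferating samples
#'
#' Takes the enriched, identified-in-both protein set with its whole-sample
#' counts, optionally equalizes sequencing-depth-like differences in total
#' spectral counts, computes per-protein intensity (log2 mean normalized
#' count) and log2 ratio (differentiating over proliferating), and applies
#' the intensity-binned robust z-test. A protein is called differential
#' when `p < alpha_diff` and `|log2 ratio| > lfc_threshold` (both strict).
#'
#' @param records Data frame with columns `protein_id`, `differentiating`,
#'   `proliferating`; all counts must be positive (use the `enriched &
#'   in_both` subset of [enrichment_filter()]).
#' @param cfg A [differential_config()].
#' @return Object of class `differential_result`: list with `records`
#'   (tibble `protein_id`, counts, normalized counts, `intensity`,
#'   `log2_ratio`, `bin`, `z`, `p_value`, `direction`, `differential`) and
#'   `bins` (per-bin statistics, see [binned_z_test()]).
#' @export
differential_test <- function(records, cfg = differential_config()) {
  records <- tibble::as_tibble(records)
  required <- c("protein_id", "differentiating", "proliferating")
  stopifnot(all(required %in% names(records)))
  if (nrow(records) == 0) {
    out <- binned_z_test(numeric(0), numeric(0), cfg)
    empty <- tibble::tibble(protein_id = character(0),
                            differentiating = integer(0),
                            proliferating = integer(0),
                            norm_differentiating = numeric(0),
                            norm_proliferating = numeric(0),
                            intensity = numeric(0), log2_ratio = numeric(0),
                            bin = integer(0), z = numeric(0),
                            p_value = numeric(0), direction = character(0),
                            differential = logical(0))
    return(structure(list(records = empty, bins = out$bins),
                     class = "differential_result"))
  }
  if (any(records$differentiating <= 0) || any(records$proliferating <= 0)) {
    stop("all proteins must have positive counts in both NSC samples; ",
         "filter to the enriched & in_both set first", call. = FALSE)
  }
  totals <- c(sum(records$differentiating), sum(records$proliferating))
  scale_to <- if (cfg$normalize_depth) mean(totals) else NA
  nd <- if (cfg$normalize_depth)
    records$differentiating * scale_to / totals[1] else
      as.numeric(records$differentiating)
  np <- if (cfg$normalize_depth)
    records$proliferating * scale_to / totals[2] else
      as.numeric(records$proliferating)
  intensity <- log2((nd + np) / 2)
  ratio <- log2(nd / np)
  zres <- binned_z_test(intensity, ratio, cfg, ids = records$protein_id)
  rec <- zres$records
  out <- tibble::tibble(
    protein_id = records$protein_id,
    differentiating = records$differentiating,
    proliferating = records$proliferating,
    norm_differentiating = nd,
    norm_proliferating = np,
    intensity = intensity,
    log2_ratio = ratio,
    bin = rec$bin,
    z = rec$z,
    p_value = rec$p_value,
    direction = dplyr::case_when(
      ratio > 0 ~ "up-in-differentiation",
      ratio < 0 ~ "up-in-maintenance",
      .default = "null"
    )
  )
  out$differential <- out$p_value < cfg$alpha_diff &
    abs(out$log2_ratio) > cfg$lfc_threshold
  structure(list(records = out, bins = zres$bins),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf(
    "<differential_result> %d proteins in %d bins; %d up, %d down\n",
    nrow(x$records), nrow(x$bins),
    sum(x$records$differential &
          x$records$direction == "up-in-differentiation"),
    sum(x$records$differential &
          x$records$direction == "up-in-maintenance")))
  invisible(x)
}
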