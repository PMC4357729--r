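#' Configuration for the negative-control enrichment test
#'
#' Settings for the per-protein one-sided exact test of the two bait
#' pull-down samples (proliferating and differentiating NSCs) against the
#' sparse negative control.
#'
#' Two methods are available. `"conditional-binomial"` (default) is the
#' uniformly-most-powerful-unbiased exact comparison of Poisson rates:
#' under the null of equal per-sample rates, with one control sample and
#' two NSC samples, the control count conditional on the total
#' `t = c + s_d + s_p` is Binomial(`t`, 1/3), and the one-sided p-value for
#' "NSC rate > control rate" is `P(X <= c)`. `"poisson-tail"` is a literal
#' Poisson-tail reading: `p = P(Y >= round(m))` for `Y ~ Poisson(max(c,
#' pseudocount))` with `m = (s_d + s_p)/2` the mean NSC count; the
#' pseudocount guards the degenerate zero-rate control.
#'
#' @param alpha_enrich Significance threshold; a protein is enriched when
#'   `p < alpha_enrich` (strict). Default 0.1.
#' @param method `"conditional-binomial"` or `"poisson-tail"`.
#' @param pseudocount Control rate floor used only by `"poisson-tail"`
#'   when the control count is 0. Default 0.5.
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(alpha_enrich = 0.1,
                              method = c("conditional-binomial",
                                         "poisson-tail"),
                              pseudocount = 0.5) {
  method <- match.arg(method)
  stopifnot(is.numeric(alpha_enrich), length(alpha_enrich) == 1,
            alpha_enrich > 0, alpha_enrich < 1,
            is.numeric(pseudocount), pseudocount >= 0)
  structure(list(alpha_enrich = alpha_enrich, method = method,
                 nsc_aggregation = switch(method,
                                          "conditional-binomial" =
                                            "sum-with-exposure",
                                          "poisson-tail" = "rounded-mean"),
                 pseudocount = pseudocount),
            class = "enrichment_config")
}

#' One-sided enrichment p-value against the negative control
#'
#' Vectorized exact test of the alternative "NSC rate > control rate" for
#' non-negative integer spectral counts; proteins missing from a sample are
#' assumed to have a count of zero.
#'
#' @param control Negative-control count(s).
#' @param differentiating Differentiating-sample count(s).
#' @param proliferating Proliferating-sample count(s).
#' @param cfg An [enrichment_config()].
#' @return Numeric vector of one-sided p-values in `[0, 1]`; all-zero input
#'   yields `p = 1`.
#' @examples
#' enrichment_pvalue(0, 5, 3)          # (2/3)^8, enriched at 0.1
#' enrichment_pvalue(2, 2, 2)          # ~0.68, not enriched
#' @export
enrichment_pvalue <- function(control, differentiating, proliferating,
                              cfg = enrichment_config()) {
  counts <- cbind(control, differentiating, proliferating)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  control <- unname(counts[, 1]); s_d <- unname(counts[, 2])
  s_p <- unname(counts[, 3])
  if (cfg$method == "conditional-binomial") {
    total <- control + s_d + s_p
    stats::pbinom(control, total, 1 / 3)
  } else {
    # half-up rounding of the mean NSC count, independent of the platform's
    # round-half-to-even convention
    k <- floor((s_d + s_p) / 2 + 0.5)
    lambda <- pmax(control, cfg$pseudocount)
    ifelse(k == 0, 1,
           stats::ppois(k - 1, lambda, lower.tail = FALSE))
  }
}

#' Flag proteins enriched over the negative control
#'
#' Applies [enrichment_pvalue()] to every protein of a merged count matrix
#' containing the three canonical samples `control`, `proliferating` and
#' `differentiating`. The subset with `enriched & in_both` is the input to
#' the differential stage: only proteins observed in both NSC samples have
#' a defined fold change.
#'
#' @param cm A merged [count_matrix()].
#' @param cfg An [enrichment_config()].
#' @return Tibble with one row per protein present in any sample:
#'   `protein_id`, the three counts, `p_value`, `enriched`
#'   (`p < alpha_enrich`) and `in_both` (both NSC counts > 0).
#' @export
enrichment_filter <- function(cm, cfg = enrichment_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is_merged(cm)) {
    stop("sum_fractions() must be applied before the enrichment test",
         call. = FALSE)
  }
  canonical <- c("control", "proliferating", "differentiating")
  missing_samples <- setdiff(canonical, unique(cm$sample))
  if (length(missing_samples) > 0) {
    stop("count matrix lacks canonical sample(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  wide <- tibble::as_tibble(cm) |>
    dplyr::filter(.data$sample %in% canonical) |>
    tidyr::pivot_wider(id_cols = "protein_id", names_from = "sample",
                       values_from = "count", values_fill = 0L) |>
    dplyr::arrange(.data$protein_id)
  for (s in canonical) {
    if (!s %in% names(wide)) wide[[s]] <- 0L
  }
  wide <- dplyr::filter(wide, .data$control > 0 | .data$proliferating > 0 |
                          .data$differentiating > 0)
  wide |>
    dplyr::mutate(
      p_value = enrichment_pvalue(.data$control, .data$differentiating,
                                  .data$proliferating, cfg),
      enriched = .data$p_value < cfg$alpha_enrich,
      in_both = .data$differentiating > 0 & .data$proliferating > 0
    ) |>
    dplyr::select("protein_id", "control", "differentiating",
                  "proliferating", "p_value", "enriched", "in_both")
}
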