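#' One-sided Fisher (hypergeometric) enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for `X` hypergeometric with `N`
#' background proteins of which `K` are annotated and a test set of size
#' `n`: the one-sided Fisher's exact test for over-representation.
#' Vectorized over all four arguments.
#'
#' @param k Annotated proteins in the test set.
#' @param n Test-set size.
#' @param K Annotated proteins in the background.
#' @param N Background size.
#' @return One-sided p-value(s).
#' @export
fisher_enrichment <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  if (any(!is.finite(args)) || any(args < 0) ||
      any(args != floor(args))) {
    stop("k, n, K, N must be non-negative integers", call. = FALSE)
  }
  k <- unname(args[, 1]); n <- unname(args[, 2])
  K <- unname(args[, 3]); N <- unname(args[, 4])
  if (any(K > N) || any(n > N) || any(k > n) || any(k > K)) {
    stop("arguments must satisfy k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_{j >= i} ( m p_(j) / j )`, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' GO over-representation of a protein set
#'
#' Tests every GO term annotating at least `min_test` test-set proteins and
#' at least `min_background` background proteins with a one-sided Fisher's
#' exact test, adjusts across exactly the tested terms by
#' Benjamini-Hochberg, and flags terms with `q < alpha_go` (strict) as
#' significantly enriched. Restricting the tested universe avoids vacuous
#' terms inflating the BH denominator.
#'
#' @param test_set Character vector of test proteins (must be a subset of
#'   `background`; typically the up-in-differentiation call set).
#' @param background Character vector of background proteins (all proteins
#'   identified in any sample).
#' @param annotations An [annotation_map()].
#' @param alpha_go Significance threshold on the adjusted p-value.
#'   Default 0.1.
#' @param min_test Minimum test-set annotation count for a term to be
#'   tested. Default 1.
#' @param min_background Minimum background annotation count. Default 2.
#' @return Tibble with one row per tested term: `go_id`, optional `name`,
#'   `k`, `n`, `K`, `N`, `p_value`, `q_value`, `significant`; ordered by
#'   `p_value`.
#' @export
go_enrichment <- function(test_set, background, annotations,
                          alpha_go = 0.1, min_test = 1,
                          min_background = 2) {
  stopifnot(inherits(annotations, "annotation_map"),
            alpha_go > 0, alpha_go < 1)
  test_set <- unique(test_set)
  background <- unique(background)
  stray <- setdiff(test_set, background)
  if (length(stray) > 0) {
    stop("test set contains proteins absent from the background: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ...", call. = FALSE)
  }
  ann <- tibble::as_tibble(annotations) |>
    dplyr::filter(.data$protein_id %in% background)
  N <- length(background)
  n <- length(test_set)
  per_term <- ann |>
    dplyr::group_by(.data$go_id) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$protein_id),
                     k = dplyr::n_distinct(
                       .data$protein_id[.data$protein_id %in% test_set]),
                     .groups = "drop") |>
    dplyr::filter(.data$k >= min_test, .data$K >= min_background)
  if (nrow(per_term) == 0 || n == 0) {
    out <- tibble::tibble(go_id = character(0), k = integer(0),
                          n = integer(0), K = integer(0), N = integer(0),
                          p_value = numeric(0), q_value = numeric(0),
                          significant = logical(0))
    return(out)
  }
  out <- per_term |>
    dplyr::mutate(n = n, N = N,
                  p_value = fisher_enrichment(.data$k, n, .data$K, N)) |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value),
                  significant = .data$q_value < alpha_go) |>
    dplyr::select("go_id", "k", "n", "K", "N", "p_value", "q_value",
                  "significant") |>
    dplyr::arrange(.data$p_value, .data$go_id)
  term_names <- attr(annotations, "term_names")
  if (!is.null(term_names)) {
    out <- dplyr::left_join(out, tibble::as_tibble(term_names),
                            by = "go_id") |>
      dplyr::relocate("name", .after = "go_id")
  }
  out
}
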