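#' Spectral-count matrices
#'
#' A `count_matrix` is a tidy (long) table of spectral counts with columns
#' `protein_id`, `sample`, `fraction` and `count`, carrying a `merged`
#' attribute that records whether subcellular fractions have already been
#' summed into a single `"whole"` fraction per (protein, sample). Triples
#' absent from the table are interpreted as a count of zero, which is the
#' natural convention for sparse AP-MS identifications.
#'
#' @param counts A data frame with columns `protein_id`, `sample`,
#'   `fraction` (character) and `count` (non-negative integer).
#' @param merged Logical; have fractions already been summed?
#' @return A `count_matrix`: a tibble with the columns above.
#' @examples
#' cm <- count_matrix(tibble::tibble(
#'   protein_id = c("P1", "P1"), sample = "differentiating",
#'   fraction = c("cytoplasmic", "nuclear"), count = c(3L, 2L)
#' ))
#' sum_fractions(cm)
#' @export
count_matrix <- function(counts, merged = FALSE) {
  counts <- tibble::as_tibble(counts)
  required <- c("protein_id", "sample", "fraction", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("count table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # rebuild column by column so stray attributes of the input do not leak
  counts <- tibble::tibble(
    protein_id = as.character(counts$protein_id),
    sample = as.character(counts$sample),
    fraction = as.character(counts$fraction),
    count = counts$count
  )
  if (any(!is.finite(counts$count)) ||
      any(counts$count < 0) ||
      any(counts$count != floor(counts$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts$count <- as.integer(counts$count)
  key <- paste(counts$protein_id, counts$sample, counts$fraction, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- counts[duplicated(key), , drop = FALSE]
    stop("duplicated (protein, sample, fraction) triple(s), e.g. (",
         dup$protein_id[1], ", ", dup$sample[1], ", ", dup$fraction[1], ")",
         call. = FALSE)
  }
  if (isTRUE(merged) && !all(counts$fraction == "whole")) {
    stop("a merged count_matrix must use the single fraction \"whole\"",
         call. = FALSE)
  }
  new_count_matrix(counts, merged = isTRUE(merged))
}

new_count_matrix <- function(counts, merged) {
  structure(counts,
            class = c("count_matrix", class(tibble::tibble())),
            merged = merged)
}

#' @rdname count_matrix
#' @param x Object to test or print.
#' @export
is_merged <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  isTRUE(attr(x, "merged"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d proteins x %d samples (%s)\n",
              length(unique(x$protein_id)), length(unique(x$sample)),
              if (is_merged(x)) "fractions merged" else "per-fraction"))
  NextMethod()
}

#' Read a long-format spectral-count table
#'
#' Parses a tab-separated file with header columns `protein_id`, `sample`,
#' `fraction`, `count`. Counts must be non-negative integers; duplicated
#' (protein, sample, fraction) rows are an error. Sample labels are kept
#' verbatim.
#'
#' @param path Path to a TSV file.
#' @param merged Logical; set `TRUE` if the file already contains a single
#'   `"whole"` fraction per (protein, sample).
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, merged = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("protein_id", "sample", "fraction", "count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("count table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  count_num <- suppressWarnings(as.numeric(raw$count))
  bad <- which(!is.finite(count_num) | count_num < 0 |
                 count_num != floor(count_num))
  if (length(bad) > 0) {
    # +1 for the header line
    stop("invalid count \"", raw$count[bad[1]], "\" at line ", bad[1] + 1L,
         " of ", path, " (counts must be non-negative integers)",
         call. = FALSE)
  }
  raw$count <- as.integer(count_num)
  count_matrix(raw, merged = merged)
}

#' Sum subcellular fractions into whole-sample counts
#'
#' Spectral counts of all fractions of a (protein, sample) pair (for
#' instance cytoplasmic and nuclear) are summed prior to quantification;
#' fractions from which a protein is absent contribute zero. The result
#' carries the single fraction `"whole"`.
#'
#' @param cm An unmerged [count_matrix()].
#' @return A merged [count_matrix()] with identical protein and sample sets.
#' @export
sum_fractions <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is_merged(cm)) {
    stop("fractions have already been summed", call. = FALSE)
  }
  merged <- tibble::as_tibble(cm) |>
    dplyr::group_by(.data$protein_id, .data$sample) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(fraction = "whole") |>
    dplyr::select("protein_id", "sample", "fraction", "count")
  new_count_matrix(merged, merged = TRUE)
}

#' Per-sample identification summary
#'
#' Counts proteins identified (whole-sample count > 0) per sample, in the
#' union of all samples, and in each pairwise intersection.
#'
#' @param cm A merged [count_matrix()].
#' @return A `sample_summary`: list with elements `per_sample` (tibble
#'   `sample`, `n_proteins`), `n_union`, and `intersections` (tibble
#'   `sample_a`, `sample_b`, `n_proteins`).
#' @export
sample_summary <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is_merged(cm)) {
    stop("sum_fractions() must be applied before summarising", call. = FALSE)
  }
  present <- tibble::as_tibble(cm) |>
    dplyr::filter(.data$count > 0)
  samples <- sort(unique(cm$sample))
  sets <- lapply(samples, function(s) {
    unique(present$protein_id[present$sample == s])
  })
  names(sets) <- samples
  per_sample <- tibble::tibble(
    sample = samples,
    n_proteins = unname(vapply(sets, length, integer(1)))
  )
  pairs <- if (length(samples) >= 2) utils::combn(samples, 2) else
    matrix(character(0), nrow = 2)
  intersections <- tibble::tibble(
    sample_a = pairs[1, ],
    sample_b = pairs[2, ],
    n_proteins = vapply(seq_len(ncol(pairs)), function(i) {
      length(intersect(sets[[pairs[1, i]]], sets[[pairs[2, i]]]))
    }, integer(1))
  )
  structure(
    list(per_sample = per_sample,
         n_union = length(unique(unlist(sets))),
         intersections = intersections),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("<sample_summary>\n")
  print(x$per_sample)
  cat("union:", x$n_union, "proteins\n")
  if (nrow(x$intersections) > 0) print(x$intersections)
  invisible(x)
}
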