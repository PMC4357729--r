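#' Run the full AP-MS spectral-count analysis pipeline
#'
#' Executes the stages end to end: fraction summation, per-sample summary,
#' negative-control enrichment test, intensity-binned differential test on
#' the enriched set identified in both NSC samples, GO over-representation
#' of the up-in-differentiation call set against all identified proteins,
#' and extraction of the first-neighbor subnetwork around the enriched set
#' from the physical PPI edges. Stage subsets are chained exactly:
#' GO test set (subset of) differential calls (subset of) enriched &
#' in-both (subset of) identified proteins.
#'
#' The run is deterministic: identical inputs and configuration reproduce
#' byte-identical output files.
#'
#' @param counts A [count_matrix()] (merged or not) or a path to a count
#'   TSV readable by [read_count_table()].
#' @param annotations Optional [annotation_map()] or annotation TSV path;
#'   when absent the GO stage is skipped.
#' @param edges Optional [edge_list()] or SIF path; when absent the
#'   network stage is skipped.
#' @param out_dir Optional output directory; when given, all result tables
#'   plus SIF/node files and a manifest are written there.
#' @param enrichment An [enrichment_config()].
#' @param differential A [differential_config()].
#' @param alpha_go GO significance threshold on adjusted p-values.
#' @param excluded_types Interaction types removed before the network
#'   stage.
#' @return An `apmsde_results` list: `summary`, `enrichment`,
#'   `differential`, `go`, `network`, and the configuration used.
#' @export
run_pipeline <- function(counts, annotations = NULL, edges = NULL,
                         out_dir = NULL,
                         enrichment = enrichment_config(),
                         differential = differential_config(),
                         alpha_go = 0.1,
                         excluded_types = c("transcription regulation",
                                            "transport")) {
  if (is.character(counts)) counts <- read_count_table(counts)
  stopifnot(inherits(counts, "count_matrix"))
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(edges)) edges <- read_edges(edges)
  if (!is_merged(counts)) counts <- sum_fractions(counts)

  summary <- sample_summary(counts)
  enr <- enrichment_filter(counts, enrichment)
  diff_input <- dplyr::filter(enr, .data$enriched, .data$in_both)
  diff <- differential_test(
    diff_input[c("protein_id", "differentiating", "proliferating")],
    differential
  )
  up_set <- diff$records$protein_id[
    diff$records$differential &
      diff$records$direction == "up-in-differentiation"]
  background <- enr$protein_id
  go <- NULL
  if (!is.null(annotations)) {
    go <- go_enrichment(up_set, background, annotations,
                        alpha_go = alpha_go)
  }
  network <- NULL
  if (!is.null(edges)) {
    physical <- filter_physical_edges(edges, excluded_types)
    network <- first_neighbor_subnetwork(
      physical, enr$protein_id[enr$enriched])
  }
  res <- structure(
    list(summary = summary, enrichment = enr, differential = diff,
         go = go, network = network,
         config = list(enrichment = unclass(enrichment),
                       differential = unclass(differential),
                       alpha_go = alpha_go,
                       excluded_types = excluded_types)),
    class = "apmsde_results")
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' @rdname run_pipeline
#' @param res An `apmsde_results` object.
#' @export
write_pipeline_results <- function(res, out_dir) {
  stopifnot(inherits(res, "apmsde_results"))
  summary_tbl <- dplyr::bind_rows(
    res$summary$per_sample,
    tibble::tibble(sample = "union", n_proteins = res$summary$n_union),
    tibble::tibble(
      sample = paste0("intersection:", res$summary$intersections$sample_a,
                      "&", res$summary$intersections$sample_b),
      n_proteins = res$summary$intersections$n_proteins)
  )
  tables <- list(summary = summary_tbl,
                 enrichment = res$enrichment,
                 differential = res$differential$records,
                 bins = res$differential$bins)
  if (!is.null(res$go)) tables$go <- res$go
  cfg_echo <- c(
    res$config$enrichment[c("alpha_enrich", "method", "pseudocount")],
    res$config$differential,
    list(alpha_go = res$config$alpha_go,
         excluded_types = res$config$excluded_types)
  )
  paths <- write_results(tables, out_dir, config = cfg_echo)
  if (!is.null(res$network)) {
    paths <- c(paths, write_subnetwork(
      res$network,
      file.path(out_dir, "network.sif"),
      file.path(out_dir, "network_nodes.tsv")))
    if (length(res$network$seeds_missing) > 0) {
      writeLines(res$network$seeds_missing,
                 file.path(out_dir, "seeds_missing.txt"))
      paths <- c(paths, file.path(out_dir, "seeds_missing.txt"))
    }
  }
  invisible(paths)
}

#' @export
print.apmsde_results <- function(x, ...) {
  cat("<apmsde_results>\n")
  print(x$summary)
  cat(sprintf("enriched: %d (in both NSC samples: %d)\n",
              sum(x$enrichment$enriched),
              sum(x$enrichment$enriched & x$enrichment$in_both)))
  print(x$differential)
  if (!is.null(x$go)) {
    cat(sprintf("GO: %d terms tested, %d significant\n",
                nrow(x$go), sum(x$go$significant)))
  }
  if (!is.null(x$network)) print(x$network)
  invisible(x)
}
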