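#' Read protein-to-GO annotations
#'
#' Parses a TSV with columns `protein_id` and `go_id`; duplicate
#' (protein, term) rows are collapsed. An optional sidecar TSV with columns
#' `go_id` and `name` supplies human-readable term names.
#'
#' @param path Annotation TSV path.
#' @param names_path Optional path to a (go_id, name) TSV.
#' @return An `annotation_map`: tibble (`protein_id`, `go_id`) with a
#'   `term_names` attribute (tibble or `NULL`).
#' @export
read_annotations <- function(path, names_path = NULL) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(c("protein_id", "go_id"), names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  term_names <- NULL
  if (!is.null(names_path)) {
    term_names <- readr::read_tsv(names_path,
                                  col_types = readr::cols(.default = "c"),
                                  progress = FALSE)
    if (!all(c("go_id", "name") %in% names(term_names))) {
      stop("term-name table must have columns go_id, name", call. = FALSE)
    }
  }
  annotation_map(ann[c("protein_id", "go_id")], term_names)
}

#' @rdname read_annotations
#' @param annotations Data frame with columns `protein_id`, `go_id`.
#' @param term_names Optional data frame with columns `go_id`, `name`.
#' @export
annotation_map <- function(annotations, term_names = NULL) {
  ann <- tibble::as_tibble(annotations)[c("protein_id", "go_id")] |>
    dplyr::distinct()
  structure(ann,
            class = c("annotation_map", class(tibble::tibble())),
            term_names = term_names)
}

#' Read a SIF protein-interaction edge list
#'
#' Each non-empty row must have exactly three whitespace-separated fields:
#' source, interaction type, target. Edges are undirected: endpoints are
#' canonicalized into sorted order and exact duplicates (unordered pair +
#' type) are collapsed. Interaction-type labels are kept verbatim.
#'
#' @param path SIF file path.
#' @return An `edge_list`: tibble (`source`, `interaction`, `target`).
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  # SIF convention: a line containing a tab is tab-delimited (allowing
  # spaces inside interaction-type labels), otherwise space-delimited
  fields <- lapply(trimws(lines[keep]), function(l) {
    if (grepl("\t", l, fixed = TRUE)) trimws(strsplit(l, "\t")[[1]])
    else strsplit(l, " +")[[1]]
  })
  n_fields <- lengths(fields)
  if (any(n_fields != 3)) {
    bad <- which(n_fields != 3)[1]
    stop("malformed SIF row at line ", keep[bad], " of ", path,
         " (expected 3 fields, found ", n_fields[bad], ")", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  edge_list(tibble::tibble(source = m[, 1], interaction = m[, 2],
                           target = m[, 3]))
}

#' @rdname read_edges
#' @param edges Data frame with columns `source`, `interaction`, `target`.
#' @export
edge_list <- function(edges) {
  edges <- tibble::as_tibble(edges)[c("source", "interaction", "target")]
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  canon <- tibble::tibble(source = a, interaction = edges$interaction,
                          target = b) |>
    dplyr::distinct()
  structure(canon, class = c("edge_list", class(tibble::tibble())))
}

#' Write result tables and a run manifest
#'
#' Writes each table as `<name>.tsv` in `dir` plus a plain-text
#' `MANIFEST.txt` recording the package version, a configuration echo and
#' per-table row counts. Output is deterministic: rerunning with identical
#' inputs reproduces byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @param config Named list echoed into the manifest.
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, dir, config = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tables[[nm]]), p, progress = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(
    paste0("apmsde ", as.character(utils::packageVersion("apmsde"))),
    "",
    "[config]",
    if (length(config) > 0) {
      paste0(names(config), " = ",
             vapply(config, function(v) paste(format(v), collapse = ", "),
                    character(1)))
    },
    "",
    "[tables]",
    paste0(names(tables), ".tsv: ",
           vapply(tables, nrow, integer(1)), " rows")
  )
  mp <- file.path(dir, "MANIFEST.txt")
  writeLines(manifest, mp)
  invisible(c(paths, mp))
}
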