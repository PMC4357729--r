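# toy builders shared across test files

toy_counts <- function() {
  count_matrix(tibble::tibble(
    protein_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    sample = c("differentiating", "differentiating", "proliferating",
               "differentiating", "proliferating", "control"),
    fraction = c("cytoplasmic", "nuclear", "cytoplasmic",
                 "cytoplasmic", "nuclear", "cytoplasmic"),
    count = c(3L, 2L, 4L, 7L, 1L, 5L)
  ))
}

random_counts <- function(n_proteins, seed) {
  set.seed(seed)
  grid <- expand.grid(
    protein_id = sprintf("P%03d", seq_len(n_proteins)),
    sample = c("control", "differentiating", "proliferating"),
    fraction = c("cytoplasmic", "nuclear"),
    stringsAsFactors = FALSE
  )
  keep <- runif(nrow(grid)) < 0.7
  grid <- grid[keep, , drop = FALSE]
  grid$count <- rpois(nrow(grid), 4)
  count_matrix(tibble::as_tibble(grid))
}

write_counts_tsv <- function(cm, path = withr::local_tempfile(
                               fileext = ".tsv",
                               .local_envir = parent.frame())) {
  readr::write_tsv(tibble::as_tibble(cm), path, progress = FALSE)
  path
}
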