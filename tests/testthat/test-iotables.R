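test_that("read_count_table parses valid files and reports format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tsample\tfraction\tcount",
               "P1\tcontrol\twhole\t2",
               "P1\tdifferentiating\twhole\t5",
               "P2\tcontrol\twhole\t0",
               "P2\tdifferentiating\twhole\t1"), path)
  cm <- read_count_table(path)
  expect_s3_class(cm, "count_matrix")
  expect_equal(nrow(cm), 4)
  expect_equal(length(unique(cm$protein_id)), 2)
  expect_false(is_merged(cm))

  # header only -> zero proteins
  writeLines("protein_id\tsample\tfraction\tcount", path)
  expect_equal(nrow(read_count_table(path)), 0)

  # missing column named in the error
  writeLines(c("protein_id\tsample\tcount", "P1\tcontrol\t2"), path)
  expect_error(read_count_table(path), "fraction")

  # negative / non-integer counts rejected with a line number
  writeLines(c("protein_id\tsample\tfraction\tcount",
               "P1\tcontrol\twhole\t-3"), path)
  expect_error(read_count_table(path), "line 2")
  writeLines(c("protein_id\tsample\tfraction\tcount",
               "P1\tcontrol\twhole\t2",
               "P1\tdifferentiating\twhole\t1.5"), path)
  expect_error(read_count_table(path), "line 3")

  # duplicated triple rejected
  writeLines(c("protein_id\tsample\tfraction\tcount",
               "P1\tcontrol\twhole\t2",
               "P1\tcontrol\twhole\t3"), path)
  expect_error(read_count_table(path), "duplicated")
})

test_that("sum_fractions sums with missing counts treated as zero", {
  merged <- sum_fractions(toy_counts())
  expect_true(is_merged(merged))
  expect_true(all(merged$fraction == "whole"))
  get <- function(p, s) merged$count[merged$protein_id == p &
                                       merged$sample == s]
  expect_equal(get("P1", "differentiating"), 5L)  # 3 + 2
  expect_equal(get("P1", "proliferating"), 4L)    # nuclear absent = 0
  expect_equal(get("P3", "control"), 5L)
  expect_error(sum_fractions(merged), "already")
})

test_that("sum_fractions conserves per-sample totals and keeps zeros", {
  for (seed in 1:10) {
    cm <- random_counts(12, seed)
    merged <- sum_fractions(cm)
    before <- tapply(cm$count, cm$sample, sum)
    after <- tapply(merged$count, merged$sample, sum)
    expect_equal(after[names(before)], before)
  }
  # an all-zero protein is retained after merging
  cm <- count_matrix(tibble::tibble(
    protein_id = c("A", "A"), sample = "control",
    fraction = c("cytoplasmic", "nuclear"), count = c(0L, 0L)))
  merged <- sum_fractions(cm)
  expect_equal(merged$count, 0L)
  expect_equal(merged$protein_id, "A")
})

test_that("count tables round-trip through write and read", {
  for (seed in 1:5) {
    cm <- random_counts(10, seed)
    path <- write_counts_tsv(cm)
    back <- read_count_table(path)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(cm))
  }
})

test_that("sample_summary matches brute-force set algebra", {
  cm <- count_matrix(tibble::tibble(
    protein_id = c("A", "B", "B", "C"),
    sample = c("s1", "s1", "s2", "s2"),
    fraction = "whole",
    count = c(1L, 2L, 1L, 3L)), merged = TRUE)
  s <- sample_summary(cm)
  expect_equal(s$per_sample$n_proteins, c(2L, 2L))
  expect_equal(s$n_union, 3L)
  expect_equal(s$intersections$n_proteins, 1L)

  for (seed in 1:10) {
    cm <- sum_fractions(random_counts(15, seed))
    s <- sample_summary(cm)
    present <- tibble::as_tibble(cm)[cm$count > 0, ]
    oracle_union <- length(unique(present$protein_id))
    expect_equal(s$n_union, oracle_union)
    expect_true(s$n_union >= max(s$per_sample$n_proteins))
    for (i in seq_len(nrow(s$intersections))) {
      a <- s$intersections$sample_a[i]; b <- s$intersections$sample_b[i]
      oracle <- length(intersect(
        present$protein_id[present$sample == a],
        present$protein_id[present$sample == b]))
      expect_equal(s$intersections$n_proteins[i], oracle)
      na <- s$per_sample$n_proteins[s$per_sample$sample == a]
      nb <- s$per_sample$n_proteins[s$per_sample$sample == b]
      expect_true(s$intersections$n_proteins[i] <= min(na, nb))
    }
  }
})

test_that("sample_summary handles an all-zero sample", {
  cm <- count_matrix(tibble::tibble(
    protein_id = c("A", "A"), sample = c("s1", "s2"),
    fraction = "whole", count = c(3L, 0L)), merged = TRUE)
  s <- sample_summary(cm)
  expect_equal(s$per_sample$n_proteins[s$per_sample$sample == "s2"], 0L)
  expect_equal(s$n_union, 1L)
})

test_that("annotation and SIF readers parse, deduplicate and canonicalize", {
  ann_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgo_id",
               "P1\tGO:1", "P1\tGO:1", "P2\tGO:2"), ann_path)
  ann <- read_annotations(ann_path)
  expect_s3_class(ann, "annotation_map")
  expect_equal(nrow(ann), 2)

  sif_path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp A", "A\ttransport\tC"), sif_path)
  edges <- read_edges(sif_path)
  expect_equal(nrow(edges), 2)  # A-B deduplicated after canonicalization
  expect_true(all(edges$source <= edges$target))

  writeLines(c("A pp B", "B pp"), sif_path)
  expect_error(read_edges(sif_path), "line 2")
})

test_that("write_results emits one TSV per table plus a manifest", {
  dir <- withr::local_tempdir()
  tables <- list(alpha = tibble::tibble(x = 1:3),
                 beta = tibble::tibble(y = letters[1:2]))
  paths <- write_results(tables, dir, config = list(alpha_enrich = 0.1))
  expect_true(all(file.exists(paths)))
  manifest <- readLines(file.path(dir, "MANIFEST.txt"))
  expect_true(any(grepl("alpha.tsv: 3 rows", manifest)))
  expect_true(any(grepl("alpha_enrich = 0.1", manifest)))
})
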