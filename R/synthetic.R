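#' Configuration of the synthetic AP-MS dataset generator
#'
#' Generates spectral-count matrices, GO annotations and PPI edge lists
#' with known ground truth, mirroring the statistical structure the
#' analysis assumes: Poisson-distributed counts split over cytoplasmic and
#' nuclear fractions, a sparse negative control, heteroscedastic
#' (intensity-dependent) log2-ratio noise, a minority of proteins with true
#' effects in either direction, GO terms spiked into the up-regulated set,
#' and a PPI graph attaching seeds to first neighbors.
#'
#' Defaults emulate the scale of a bait pull-down screen in neural stem
#' cells: ~2641 proteins of which ~29 appear in the negative control, NSC
#' abundance rates log-uniform on `[2, 200]` spectral counts, 10% of
#' proteins truly up in differentiation and 7% up in maintenance with
#' `|log2 effect|` uniform on `[0.8, 2.5]`.
#'
#' @param n_proteins Number of proteins. Default 2641.
#' @param control_fraction Probability a protein is genuinely present in
#'   the negative control. Default 29/2641.
#' @param lambda_control Poisson rate of control-present proteins.
#'   Default 4.
#' @param lambda_range NSC whole-sample abundance rates are log-uniform on
#'   this interval. Default `c(2, 200)`.
#' @param fraction_split Named non-negative weights allocating a sample's
#'   rate over fractions (normalized to sum 1).
#'   Default `c(cytoplasmic = 0.6, nuclear = 0.4)`.
#' @param pi_up,pi_down Fractions of proteins with a true positive /
#'   negative log2 effect (differentiating over proliferating).
#'   Defaults 0.10 and 0.07.
#' @param effect_range True `|log2 effect|` is uniform on this interval.
#'   Default `c(0.8, 2.5)`.
#' @param sigma0,sigma1 Extra-Poisson log2-ratio noise SD at intensity `I`
#'   (log2 rate) is `sigma0 + sigma1 / sqrt(2^I)`: larger for faint
#'   proteins, which is the regime where intensity binning matters.
#'   Defaults 0.1 and 0.5.
#' @param n_go_terms Number of GO terms. Default 200.
#' @param n_spiked_terms Terms preferentially annotating true-up proteins.
#'   Default 10.
#' @param spike_strength Odds multiplier of a spiked term annotating a
#'   true-up protein. Default 10.
#' @param term_prevalence_range Per-term background annotation probability
#'   is uniform on this interval. Default `c(0.01, 0.05)`.
#' @param ppi_mean_degree Mean degree of the random PPI graph. Default 4.
#' @param nonphysical_share Share of edges given a non-physical type
#'   ("transcription regulation" or "transport"). Default 0.2.
#' @param seed_attach_prob Probability that a true-up protein is guaranteed
#'   at least one physical edge. Default 1.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2641,
                       control_fraction = 29 / 2641,
                       lambda_control = 4,
                       lambda_range = c(2, 200),
                       fraction_split = c(cytoplasmic = 0.6, nuclear = 0.4),
                       pi_up = 0.10, pi_down = 0.07,
                       effect_range = c(0.8, 2.5),
                       sigma0 = 0.1, sigma1 = 0.5,
                       n_go_terms = 200, n_spiked_terms = 10,
                       spike_strength = 10,
                       term_prevalence_range = c(0.01, 0.05),
                       ppi_mean_degree = 4, nonphysical_share = 0.2,
                       seed_attach_prob = 1) {
  stopifnot(n_proteins >= 1,
            control_fraction >= 0, control_fraction <= 1,
            lambda_control > 0,
            length(lambda_range) == 2, all(lambda_range > 0),
            lambda_range[1] <= lambda_range[2],
            length(fraction_split) >= 1, all(fraction_split >= 0),
            sum(fraction_split) > 0, !is.null(names(fraction_split)),
            pi_up >= 0, pi_down >= 0, pi_up + pi_down < 1,
            length(effect_range) == 2, all(effect_range >= 0),
            sigma0 > 0, sigma1 >= 0,
            n_go_terms >= 1, n_spiked_terms >= 0,
            n_spiked_terms <= n_go_terms, spike_strength >= 1,
            length(term_prevalence_range) == 2,
            all(term_prevalence_range > 0),
            all(term_prevalence_range <= 1),
            ppi_mean_degree >= 0,
            nonphysical_share >= 0, nonphysical_share <= 1,
            seed_attach_prob >= 0, seed_attach_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic spectral-count matrix with ground truth
#'
#' Per protein, a base rate `lambda` is drawn log-uniformly; true effects
#' shift the differentiating and proliferating rates to
#' `lambda * 2^(+-(delta + eps)/2)` where `delta` is the true log2 effect
#' and `eps` is heteroscedastic ratio noise; counts are Poisson-sampled per
#' fraction. Control-present proteins get Poisson counts at
#' `lambda_control`; all other control counts are zero. Fully deterministic
#' given `(cfg, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (an unmerged [count_matrix()]; zero-count
#'   triples are omitted) and `truth` (tibble `protein_id`, `lambda`,
#'   `in_control`, `delta`, `true_direction`).
#' @export
generate_counts <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"), is.numeric(seed))
  set.seed(as.integer(seed))
  n <- cfg$n_proteins
  protein_id <- sprintf("P%05d", seq_len(n))
  lambda <- exp(stats::runif(n, log(cfg$lambda_range[1]),
                             log(cfg$lambda_range[2])))
  u <- stats::runif(n)
  true_direction <- ifelse(u < cfg$pi_up, "up",
                           ifelse(u < cfg$pi_up + cfg$pi_down, "down",
                                  "null"))
  mag <- stats::runif(n, cfg$effect_range[1], cfg$effect_range[2])
  delta <- ifelse(true_direction == "up", mag,
                  ifelse(true_direction == "down", -mag, 0))
  sigma <- cfg$sigma0 + cfg$sigma1 / sqrt(lambda)
  eps <- stats::rnorm(n, 0, sigma)
  lam_d <- lambda * 2^((delta + eps) / 2)
  lam_p <- lambda * 2^(-(delta + eps) / 2)
  in_control <- stats::runif(n) < cfg$control_fraction
  lam_c <- ifelse(in_control, cfg$lambda_control, 0)
  split <- cfg$fraction_split / sum(cfg$fraction_split)
  rows <- lapply(names(split), function(f) {
    w <- split[[f]]
    tibble::tibble(
      protein_id = rep(protein_id, 3),
      sample = rep(c("differentiating", "proliferating", "control"),
                   each = n),
      fraction = f,
      count = c(stats::rpois(n, lam_d * w), stats::rpois(n, lam_p * w),
                stats::rpois(n, lam_c * w))
    )
  })
  long <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(.data$protein_id, .data$sample, .data$fraction)
  truth <- tibble::tibble(protein_id = protein_id, lambda = lambda,
                          in_control = in_control, delta = delta,
                          true_direction = true_direction)
  list(counts = count_matrix(long, merged = FALSE), truth = truth)
}

#' Generate synthetic GO annotations with spiked terms
#'
#' Background terms annotate proteins independently at a per-term
#' prevalence; spiked terms annotate true-up proteins at
#' `spike_strength`-fold that prevalence (capped at 1), so
#' over-representation in the up-set is recoverable by construction.
#' Deterministic given `(cfg, seed)`; the random stream is derived from
#' `seed` independently of [generate_counts()].
#'
#' @param cfg A [sim_config()].
#' @param truth Ground-truth tibble from [generate_counts()].
#' @param seed Integer seed (same seed as the counts is fine).
#' @return List with `annotations` (an [annotation_map()] with term names)
#'   and `terms` (tibble `go_id`, `prevalence`, `spiked`).
#' @export
generate_annotations <- function(cfg, truth, seed) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(truth))
  set.seed(as.integer(seed) + 104729L)  # stage-specific derived stream
  n <- nrow(truth)
  terms <- tibble::tibble(
    go_id = sprintf("GO:%07d", seq_len(cfg$n_go_terms)),
    prevalence = stats::runif(cfg$n_go_terms,
                              cfg$term_prevalence_range[1],
                              cfg$term_prevalence_range[2]),
    spiked = seq_len(cfg$n_go_terms) %in%
      sample.int(cfg$n_go_terms, cfg$n_spiked_terms)
  )
  is_up <- truth$true_direction == "up"
  ann <- lapply(seq_len(cfg$n_go_terms), function(i) {
    prob <- rep(terms$prevalence[i], n)
    if (terms$spiked[i]) {
      prob[is_up] <- pmin(1, prob[is_up] * cfg$spike_strength)
    }
    hit <- stats::runif(n) < prob
    tibble::tibble(protein_id = truth$protein_id[hit],
                   go_id = terms$go_id[i])
  })
  term_names <- tibble::tibble(
    go_id = terms$go_id,
    name = paste0("synthetic process ", seq_len(cfg$n_go_terms))
  )
  list(annotations = annotation_map(dplyr::bind_rows(ann), term_names),
       terms = terms)
}

#' Generate a synthetic PPI edge list
#'
#' A random (Erdos-Renyi-like) graph over the proteins at the configured
#' mean degree, with a configured share of edges labelled with
#' non-physical types ("transcription regulation", "transport") for filter
#' testing, plus a guaranteed physical edge from each true-up protein with
#' probability `seed_attach_prob`. Deterministic given `(cfg, seed)`.
#'
#' @inheritParams generate_annotations
#' @return An [edge_list()].
#' @export
generate_ppi <- function(cfg, truth, seed) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(truth))
  set.seed(as.integer(seed) + 224737L)  # stage-specific derived stream
  n <- nrow(truth)
  ids <- truth$protein_id
  m <- max(1L, round(n * cfg$ppi_mean_degree / 2))
  a <- sample.int(n, m, replace = TRUE)
  b <- sample.int(n, m, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  physical_types <- c("binding", "pp")
  nonphysical_types <- c("transcription regulation", "transport")
  type <- ifelse(stats::runif(length(a)) < cfg$nonphysical_share,
                 sample(nonphysical_types, length(a), replace = TRUE),
                 sample(physical_types, length(a), replace = TRUE))
  seeds_up <- which(truth$true_direction == "up")
  attach <- seeds_up[stats::runif(length(seeds_up)) < cfg$seed_attach_prob]
  partner <- vapply(attach, function(i) {
    sample(setdiff(seq_len(n), i), 1)
  }, integer(1))
  edges <- tibble::tibble(
    source = c(ids[a], ids[attach]),
    interaction = c(type, rep("binding", length(attach))),
    target = c(ids[b], ids[partner])
  )
  edge_list(edges)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_counts()],
#' [generate_annotations()] and [generate_ppi()] with per-stage derived
#' random streams from one seed, so regenerating one artifact does not
#' perturb the others.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `counts`, `truth`, `annotations`, `terms`, `edges`.
#' @export
generate_dataset <- function(cfg = sim_config(), seed = 1) {
  counts <- generate_counts(cfg, seed)
  ann <- generate_annotations(cfg, counts$truth, seed)
  edges <- generate_ppi(cfg, counts$truth, seed)
  list(counts = counts$counts, truth = counts$truth,
       annotations = ann$annotations, terms = ann$terms, edges = edges)
}
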