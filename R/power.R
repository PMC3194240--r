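#' Detection power over a batch of simulated datasets
#'
#' Power is the fraction of datasets in which the detected SNP set
#' equals the true disease-marker set exactly -- every disease marker
#' recovered and zero false positives.  No partial credit is given: a
#' superset or subset of the truth counts as a failure.
#'
#' @param detections list of detected SNP-id sets (character vectors).
#' @param truths list of true disease-marker id sets, same length.
#' @return A list with \code{N} (datasets), \code{N_D} (exact
#'   recoveries), \code{power} = \code{N_D / N} and \code{mc_se}, the
#'   binomial Monte-Carlo standard error
#'   \eqn{\sqrt{p(1-p)/N}}.
#' @examples
#' compute_power(list(c("a", "b"), c("a")), list(c("a", "b"), c("a", "b")))
#' @export
compute_power <- function(detections, truths) {
  if (length(detections) != length(truths) || length(truths) < 1L)
    stop("detections and truths must be non-empty lists of equal length",
         call. = FALSE)
  hits <- mapply(function(d, t) setequal(d, t), detections, truths)
  N <- length(truths)
  N_D <- sum(hits)
  p <- N_D / N
  list(N = N, N_D = N_D, power = p, mc_se = sqrt(p * (1 - p) / N))
}

#' Run a power experiment over disease models and sample sizes
#'
#' For every (model, sample size) cell: simulate a batch of
#' case-control datasets, optionally screen candidates by marginal
#' G-squared, run the branch-and-bound parent-set search on each
#' dataset, and score exact-recovery power against the known disease
#' markers.  Sample sizes count total individuals, split evenly into
#' cases and controls.  Screening is skipped on panels at or below
#' \code{screen_threshold} markers (the search handles them directly)
#' and otherwise keeps the top \code{screen_top_k} SNPs, mirroring the
#' screen-then-search workflow used on large panels.
#'
#' @param models integer vector of disease-model numbers (1-4) or a
#'   list of [make_model()] objects.
#' @param sample_sizes integer vector of total sample sizes
#'   (cases + controls, split evenly).
#' @param n_datasets datasets per cell.
#' @param n_markers markers per dataset.
#' @param maf disease-locus minor-allele frequency.
#' @param r2 marker-locus squared allelic correlation.
#' @param search a [search_config()] template; its candidate list is
#'   set per dataset.
#' @param screen_threshold marker count above which the G-squared
#'   screen is applied before searching (default 500).
#' @param screen_top_k candidates kept by the screen (default 200).
#' @param seed master seed; per-cell and per-dataset sub-seeds are
#'   derived deterministically from it.
#' @param verbose print one line per cell as it completes.
#' @return A data frame with one row per cell: \code{model},
#'   \code{sample_size}, \code{power}, \code{N}, \code{N_D},
#'   \code{mc_se}.
#' @examples
#' \donttest{
#' run_power_experiment(models = 4, sample_sizes = 400, n_datasets = 5,
#'                      n_markers = 20, seed = 1)
#' }
#' @export
run_power_experiment <- function(models = 1:4,
                                 sample_sizes = c(400L, 1000L, 2000L, 4000L),
                                 n_datasets = 50L, n_markers = 40L,
                                 maf = 0.5, r2 = 1,
                                 search = search_config(),
                                 screen_threshold = 500L,
                                 screen_top_k = 200L,
                                 seed = 1L, verbose = FALSE) {
  if (!is.list(models)) {
    model_labels <- as.character(models)
    models <- lapply(models, disease_model)
  } else {
    model_labels <- vapply(models, function(m) m$kind, character(1))
  }
  ld <- ld_spec(r2)
  rows <- vector("list", 0L)
  cell <- 0L
  for (mi in seq_along(models)) {
    for (n_total in sample_sizes) {
      cell <- cell + 1L
      cfg <- sim_config(n_cases = ceiling(n_total / 2),
                        n_controls = floor(n_total / 2),
                        n_markers = n_markers, maf = maf,
                        seed = derive_subseed(seed, cell),
                        n_datasets = n_datasets)
      datasets <- simulate_batch(models[[mi]], ld, cfg)
      detections <- lapply(datasets, function(d) {
        cand <- if (d$n > screen_threshold)
          marginal_screen(d, top_k = screen_top_k)$snp_id
        else NULL
        sc <- search
        sc$candidates <- cand
        bnb_search(d, sc)$best_set
      })
      truths <- lapply(datasets, attr, "truth")
      pw <- compute_power(detections, truths)
      rows[[cell]] <- data.frame(model = model_labels[mi],
                                 sample_size = n_total,
                                 power = pw$power, N = pw$N, N_D = pw$N_D,
                                 mc_se = pw$mc_se,
                                 stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("model %s, n = %d: power = %.2f (%d/%d)",
                        model_labels[mi], n_total, pw$power, pw$N_D, pw$N))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
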