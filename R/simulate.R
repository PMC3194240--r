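#' Two- and three-locus disease penetrance models
#'
#' Builds the full penetrance table \eqn{f(g)} -- the probability of
#' disease given the joint genotype \eqn{g \in \{0,1,2\}^k} of the
#' disease loci -- for four epistatic disease models:
#' \describe{
#'   \item{\code{multiplicative}}{(model 1) two loci with
#'     multiplicative allele effects, odds
#'     \eqn{\alpha(1+\theta)^{g_1+g_2}}; each locus has a marginal
#'     effect.}
#'   \item{\code{interaction_multiplicative}}{(model 2) two-locus
#'     interaction-multiplicative effects, odds
#'     \eqn{\alpha(1+\theta)^{g_1 g_2}}: risk rises only when both loci
#'     carry minor alleles.}
#'   \item{\code{interaction_threshold}}{(model 3) two-locus
#'     interaction-threshold effects, odds \eqn{\alpha(1+\theta)} when
#'     \eqn{g_1 \ge 1} and \eqn{g_2 \ge 1}, else \eqn{\alpha}.}
#'   \item{\code{parity3}}{(model 4) three loci; penetrance is
#'     \eqn{f_1} when \eqn{g_1+g_2+g_3} is odd, else \eqn{f_0}.  At
#'     MAF = 0.5 every locus (and every pair) has exactly zero
#'     marginal effect -- a pure XOR-like interaction.}
#' }
#' Odds-form models convert to penetrance as
#' \eqn{f = \mathrm{odds}/(1+\mathrm{odds})}.
#'
#' @param kind model kind (see above), or via [disease_model()] the
#'   model number 1-4.
#' @param alpha baseline odds for the odds-form kinds (default 0.05).
#' @param theta effect size for the odds-form kinds; defaults 1, 2 and
#'   3 for kinds 1-3 respectively (moderate marginal effects).
#' @param f0,f1 baseline and elevated penetrance for \code{parity3}
#'   (defaults 0.01 and 0.10: a strong pure-interaction signal).
#' @return An object of class \code{penetrance_model} with components
#'   \code{kind}, \code{k} (number of disease loci), \code{params} and
#'   \code{table} (array of dimension \code{rep(3, k)}, indexed by
#'   genotype + 1).
#' @examples
#' make_model("multiplicative")$table
#' make_model("parity3")$table[2, 1, 1]   # g = (1,0,0): odd sum
#' @export
make_model <- function(kind = c("multiplicative",
                                "interaction_multiplicative",
                                "interaction_threshold", "parity3"),
                       alpha = 0.05, theta = NULL,
                       f0 = 0.01, f1 = 0.10) {
  kind <- match.arg(kind)
  if (kind == "parity3") {
    if (!(f0 > 0 && f1 < 1 && f0 < f1))
      stop("parity3 requires 0 < f0 < f1 < 1", call. = FALSE)
    k <- 3L
    g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    f <- ifelse(rowSums(g) %% 2L == 1L, f1, f0)
    params <- list(f0 = f0, f1 = f1)
  } else {
    if (is.null(theta))
      theta <- switch(kind, multiplicative = 1,
                      interaction_multiplicative = 2,
                      interaction_threshold = 3)
    if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
    if (theta <= -1) stop("theta must be > -1", call. = FALSE)
    k <- 2L
    g <- as.matrix(expand.grid(0:2, 0:2))
    odds <- switch(kind,
      multiplicative = alpha * (1 + theta)^(g[, 1] + g[, 2]),
      interaction_multiplicative = alpha * (1 + theta)^(g[, 1] * g[, 2]),
      interaction_threshold =
        ifelse(g[, 1] >= 1 & g[, 2] >= 1, alpha * (1 + theta), alpha))
    f <- odds / (1 + odds)
    params <- list(alpha = alpha, theta = theta)
  }
  if (any(f <= 0 | f >= 1))
    stop("penetrance table entries must lie strictly in (0, 1)",
         call. = FALSE)
  structure(list(kind = kind, k = k, params = params,
                 table = array(f, dim = rep(3L, k))),
            class = "penetrance_model")
}

#' @rdname make_model
#' @param model disease-model number, 1 to 4.
#' @param ... parameter overrides passed to [make_model()].
#' @export
disease_model <- function(model, ...) {
  stopifnot(model %in% 1:4)
  kind <- c("multiplicative", "interaction_multiplicative",
            "interaction_threshold", "parity3")[model]
  make_model(kind, ...)
}

#' Marginal penetrance of one disease locus
#'
#' Averages the joint penetrance table over Hardy-Weinberg genotype
#' frequencies at the other loci:
#' \deqn{f_m(g) = \sum_{g'} f(g, g') \, P(g')}
#' computed exactly over all \eqn{3^{k-1}} combinations.  For the
#' \code{parity3} model at MAF 0.5 this is \eqn{(f_0+f_1)/2} for every
#' genotype -- the zero-marginal-effect construction.
#'
#' @param model a [make_model()] result.
#' @param locus index of the locus of interest (1-based).
#' @param maf minor-allele frequency used for the other loci.
#' @return Numeric penetrance triple for genotypes 0, 1, 2.
#' @export
marginal_penetrance <- function(model, locus = 1L, maf = 0.5) {
  stopifnot(inherits(model, "penetrance_model"),
            locus >= 1L, locus <= model$k)
  p <- hw_probs(maf)
  if (model$k == 1L) return(as.numeric(model$table))
  others <- setdiff(seq_len(model$k), locus)
  grids <- do.call(expand.grid, rep(list(0:2), model$k - 1L))
  w <- apply(grids, 1L, function(gg) prod(p[gg + 1L]))
  vapply(0:2, function(g) {
    full <- matrix(0L, nrow = nrow(grids), ncol = model$k)
    full[, locus] <- g
    full[, others] <- as.matrix(grids)
    sum(model$table[full + 1L] * w)
  }, numeric(1))
}

# Hardy-Weinberg genotype probabilities for minor-allele count 0/1/2.
hw_probs <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Linkage-disequilibrium specification for simulated markers
#'
#' Each disease-linked marker is generated haplotype-wise from its
#' latent disease locus: either marker allele copies the corresponding
#' disease-locus allele with probability \eqn{\sqrt{r^2}} and is
#' otherwise drawn fresh at the same allele frequency, giving allelic
#' correlation \eqn{r} and squared correlation \eqn{r^2} between marker
#' and locus.  With \eqn{r^2 = 1} the marker is identical to the locus.
#' Marker MAF equals the disease-locus MAF.
#'
#' @param r2 squared allelic correlation in (0, 1].
#' @return An object of class \code{ld_spec}.
#' @export
ld_spec <- function(r2 = 1) {
  if (!(r2 > 0 && r2 <= 1)) stop("r2 must lie in (0, 1]", call. = FALSE)
  structure(list(r2 = r2), class = "ld_spec")
}

#' Simulation configuration for case-control datasets
#'
#' @param n_cases,n_controls case and control quotas.
#' @param n_markers total number of markers, including the
#'   disease-linked ones.
#' @param maf minor-allele frequency of the disease loci (and their
#'   linked markers), in (0, 0.5].
#' @param disease_positions marker positions (columns) of the
#'   disease-linked markers; default: evenly spaced across the panel.
#' @param background_maf_range MAF range for background markers, drawn
#'   uniformly per marker (default 0.05-0.5).
#' @param seed integer seed, or \code{NULL} to use the current RNG
#'   state.
#' @param n_datasets number of datasets for [simulate_batch()].
#' @param max_attempts rejection-sampling ceiling on individual draws
#'   per dataset (default 1e7).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_cases = 1000L, n_controls = 1000L,
                       n_markers = 100L, maf = 0.5,
                       disease_positions = NULL,
                       background_maf_range = c(0.05, 0.5),
                       seed = NULL, n_datasets = 1L,
                       max_attempts = 1e7) {
  if (n_cases < 1L || n_controls < 1L)
    stop("case and control quotas must be >= 1", call. = FALSE)
  if (!(maf > 0 && maf <= 0.5)) stop("maf must lie in (0, 0.5]",
                                     call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_markers = as.integer(n_markers), maf = maf,
                 disease_positions = disease_positions,
                 background_maf_range = background_maf_range,
                 seed = seed, n_datasets = as.integer(n_datasets),
                 max_attempts = max_attempts),
            class = "sim_config")
}

default_positions <- function(n_markers, k) {
  pos <- unique(round(n_markers * seq_len(k) / (k + 1)))
  pos[pos < 1L] <- seq_len(sum(pos < 1L))
  if (length(pos) < k) pos <- seq_len(k)  # tiny panels
  pos
}

#' Simulate one case-control dataset under a disease model
#'
#' Retrospective (case-control) sampling: individuals' disease-locus
#' genotypes are drawn haplotype-wise under Hardy-Weinberg equilibrium
#' at the disease MAF, disease status is assigned with probability
#' \eqn{f(g)} from the penetrance table, and draws are kept until both
#' the case and control quotas are filled (cases occupy the first rows
#' of the returned dataset).  Disease-linked markers are then derived
#' from the latent locus haplotypes according to the LD specification,
#' and background markers are drawn independently under
#' Hardy-Weinberg at MAFs uniform in \code{background_maf_range}.
#'
#' @param model a [make_model()] / [disease_model()] result.
#' @param ld an [ld_spec()].
#' @param config a [sim_config()]; \code{n_markers} must be at least
#'   the number of disease loci.
#' @return A [genotype_dataset] with attributes \code{truth} (the ids
#'   of the disease-linked markers) and \code{sim_stats} (a list with
#'   \code{draws}, the total individuals drawn, and \code{case_rate},
#'   the fraction of draws that developed disease -- an estimate of the
#'   population prevalence implied by the penetrance table).  The
#'   latent disease-locus genotypes are kept in attribute
#'   \code{latent} (N x k integer matrix) for LD diagnostics.
#' @examples
#' d <- simulate_dataset(disease_model(4), ld_spec(1),
#'                       sim_config(50, 50, n_markers = 10, seed = 1))
#' attr(d, "truth")
#' @export
simulate_dataset <- function(model, ld = ld_spec(), config = sim_config()) {
  stopifnot(inherits(model, "penetrance_model"), inherits(ld, "ld_spec"),
            inherits(config, "sim_config"))
  k <- model$k
  if (config$n_markers < k)
    stop("n_markers must be at least the number of disease loci (", k, ")",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  maf <- config$maf
  f_vec <- as.numeric(model$table)
  pow3 <- 3^(0:(k - 1))

  need_case <- config$n_cases
  need_ctl <- config$n_controls
  case_h1 <- case_h2 <- vector("list", 0L)
  ctl_h1 <- ctl_h2 <- vector("list", 0L)
  draws <- 0L
  case_draws <- 0L
  batch <- max(1024L, 2L * (need_case + need_ctl))
  while (need_case > 0L || need_ctl > 0L) {
    if (draws >= config$max_attempts)
      stop("rejection sampling exceeded ", config$max_attempts,
           " draws; penetrance table incompatible with the quotas",
           call. = FALSE)
    h1 <- matrix(stats::runif(batch * k) < maf, batch, k)
    h2 <- matrix(stats::runif(batch * k) < maf, batch, k)
    g <- h1 + h2
    f <- f_vec[as.vector(g %*% pow3) + 1L]
    is_case <- stats::runif(batch) < f
    draws <- draws + batch
    case_draws <- case_draws + sum(is_case)
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctl <- which(!is_case)[seq_len(min(need_ctl, sum(!is_case)))]
    if (length(take_case)) {
      case_h1 <- c(case_h1, list(h1[take_case, , drop = FALSE]))
      case_h2 <- c(case_h2, list(h2[take_case, , drop = FALSE]))
      need_case <- need_case - length(take_case)
    }
    if (length(take_ctl)) {
      ctl_h1 <- c(ctl_h1, list(h1[take_ctl, , drop = FALSE]))
      ctl_h2 <- c(ctl_h2, list(h2[take_ctl, , drop = FALSE]))
      need_ctl <- need_ctl - length(take_ctl)
    }
  }
  h1 <- rbind(do.call(rbind, case_h1), do.call(rbind, ctl_h1))
  h2 <- rbind(do.call(rbind, case_h2), do.call(rbind, ctl_h2))
  labels <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))
  N <- length(labels)

  positions <- config$disease_positions
  if (is.null(positions)) positions <- default_positions(config$n_markers, k)
  positions <- as.integer(positions)
  if (length(positions) != k || anyDuplicated(positions) ||
      any(positions < 1L | positions > config$n_markers))
    stop("disease_positions must be ", k, " distinct markers in 1..",
         config$n_markers, call. = FALSE)

  geno <- matrix(0L, nrow = N, ncol = config$n_markers)
  phi <- sqrt(ld$r2)
  for (l in seq_len(k)) {
    if (ld$r2 == 1) {
      m1 <- h1[, l]; m2 <- h2[, l]
    } else {
      copy1 <- stats::runif(N) < phi
      copy2 <- stats::runif(N) < phi
      fresh1 <- stats::runif(N) < maf
      fresh2 <- stats::runif(N) < maf
      m1 <- ifelse(copy1, h1[, l], fresh1)
      m2 <- ifelse(copy2, h2[, l], fresh2)
    }
    geno[, positions[l]] <- as.integer(m1) + as.integer(m2)
  }
  bg <- setdiff(seq_len(config$n_markers), positions)
  if (length(bg)) {
    bmaf <- stats::runif(length(bg), config$background_maf_range[1L],
                         config$background_maf_range[2L])
    for (i in seq_along(bg))
      geno[, bg[i]] <- stats::rbinom(N, 2L, bmaf[i])
  }
  wid <- max(2L, nchar(config$n_markers))
  ids <- sprintf("snp%0*d", wid, seq_len(config$n_markers))
  out <- genotype_dataset(geno, labels, ids)
  attr(out, "truth") <- ids[positions]
  latent <- h1 + h2
  storage.mode(latent) <- "integer"
  attr(out, "latent") <- latent
  attr(out, "sim_stats") <- list(draws = draws,
                                 case_rate = case_draws / draws)
  out
}

#' Simulate a batch of independent datasets
#'
#' Generates \code{config$n_datasets} datasets with per-dataset
#' sub-seeds derived deterministically from \code{config$seed}, so a
#' batch is reproducible and its members mutually independent.
#'
#' @inheritParams simulate_dataset
#' @return A list of [simulate_dataset()] results.
#' @export
simulate_batch <- function(model, ld = ld_spec(), config = sim_config()) {
  stopifnot(config$n_datasets >= 1L)
  lapply(seq_len(config$n_datasets), function(i) {
    cfg <- config
    cfg$seed <- derive_subseed(config$seed, i)
    simulate_dataset(model, ld, cfg)
  })
}

# Deterministic sub-seed stream; stays within 32-bit integer range.
derive_subseed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}
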