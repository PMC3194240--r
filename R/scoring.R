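#' Scoring specification for the disease-node local score
#'
#' Chooses the score family used to evaluate a candidate parent set of
#' the disease-status node and its tuning constants.  Four families are
#' supported:
#' \describe{
#'   \item{\code{loglik}}{maximum log-likelihood of the label given the
#'     parent configuration (natural log; no complexity penalty).}
#'   \item{\code{aic}}{log-likelihood minus the free-parameter count
#'     \eqn{C(S) = q(r-1)}.}
#'   \item{\code{bic}}{log-likelihood minus \eqn{c \, \ln(N) \, C(S)}.
#'     The classical coefficient is \eqn{c = 1/2}; the default here is
#'     the rescaled \eqn{c = 0.17}, which weakens the asymptotic penalty
#'     so that higher-order interactions remain detectable at the small
#'     sample sizes typical of case-control panels.}
#'   \item{\code{bde}}{log marginal likelihood under Dirichlet priors
#'     with equivalent sample size \code{ess} spread uniformly over the
#'     conditional table (\eqn{a_{ijk} = \mathrm{ess}/(r q)}).}
#' }
#'
#' @param family one of \code{"bic"}, \code{"aic"}, \code{"loglik"},
#'   \code{"bde"}.
#' @param penalty_coefficient positive multiplier \eqn{c} of the
#'   \eqn{\ln(N) C(S)} BIC penalty; default 0.17, classical BIC is 0.5.
#' @param ess equivalent sample size of the BDe Dirichlet prior, or
#'   \code{NULL} (default) to use the dataset size \eqn{N}.
#' @return An object of class \code{score_spec}.
#' @examples
#' score_spec("bic")              # rescaled small-sample BIC, c = 0.17
#' score_spec("bic", penalty_coefficient = 0.5)  # classical BIC
#' @export
score_spec <- function(family = c("bic", "aic", "loglik", "bde"),
                       penalty_coefficient = 0.17, ess = NULL) {
  family <- match.arg(family)
  if (!is.numeric(penalty_coefficient) || penalty_coefficient <= 0)
    stop("penalty_coefficient must be > 0", call. = FALSE)
  if (!is.null(ess) && (!is.numeric(ess) || ess <= 0))
    stop("ess must be > 0", call. = FALSE)
  structure(list(family = family,
                 penalty_coefficient = penalty_coefficient,
                 ess = ess),
            class = "score_spec")
}

# powers of 3 for mixed-radix parent-configuration indexing
.pow3 <- 3^(0:19)

# Parent-configuration index for every individual: mixed radix over the
# parents in the given order, first parent least significant, each digit
# a genotype code in {0,1,2}.  Returns 1-based indices into 1..3^k.
parent_config_index <- function(genotypes, parent_idx) {
  k <- length(parent_idx)
  if (k == 0L) return(rep.int(1L, nrow(genotypes)))
  as.integer(genotypes[, parent_idx, drop = FALSE] %*% .pow3[seq_len(k)]) + 1L
}

#' Contingency counts for the disease node under a parent set
#'
#' Tabulates \eqn{N_{jk}}: the number of individuals with disease label
#' in state \eqn{k} (0 = control, 1 = case) while the candidate parent
#' SNPs sit in joint configuration \eqn{j}.  Configurations are indexed
#' mixed-radix over the parents in the order given (first parent least
#' significant digit, digits 0/1/2).  Cardinalities are fixed at 3 per
#' SNP and 2 for the label even when a state is unobserved, so
#' \eqn{q = 3^{|S|}} always: the complexity penalty reflects the model,
#' not the realisation.
#'
#' @param data a [genotype_dataset].
#' @param parent_set SNP ids (character) or column indices (integer) of
#'   the candidate parents; may be empty.
#' @return An object of class \code{contingency_counts} with components
#'   \code{parent_set} (column indices), \code{snp_ids}, \code{r} (2),
#'   \code{q} (\eqn{3^{|S|}}), \code{N_jk} (q x 2 count matrix, columns
#'   = label 0/1), \code{N_j} (row sums) and \code{N}.
#' @examples
#' d <- genotype_dataset(matrix(c(0L, 0L, 1L, 1L), ncol = 1),
#'                       labels = c(0L, 1L, 0L, 1L), snp_ids = "A")
#' build_counts(d, "A")$N_jk
#' @export
build_counts <- function(data, parent_set = integer(0)) {
  stopifnot(inherits(data, "genotype_dataset"))
  idx <- resolve_snp_index(data, parent_set)
  q <- 3L^length(idx)
  j <- parent_config_index(data$genotypes, idx)
  cnt <- tabulate((j - 1L) * 2L + data$labels + 1L, nbins = 2L * q)
  N_jk <- matrix(cnt, nrow = q, ncol = 2L, byrow = TRUE,
                 dimnames = list(NULL, c("control", "case")))
  structure(list(parent_set = idx, snp_ids = data$snp_ids[idx],
                 r = 2L, q = q, N_jk = N_jk, N_j = rowSums(N_jk),
                 N = data$N),
            class = "contingency_counts")
}

#' Maximum log-likelihood of the disease node
#'
#' \deqn{\sum_j \sum_k N_{jk} \ln(N_{jk} / N_j)}
#' with the convention \eqn{0 \ln 0 = 0}; empty parent configurations
#' contribute nothing.  Natural logarithm; the value is always
#' \eqn{\le 0} and equals 0 only when the parents determine the label
#' perfectly.
#'
#' @param counts a [build_counts()] result.
#' @return Log-likelihood in nats.
#' @export
log_likelihood <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  Njk <- counts$N_jk
  Nj <- counts$N_j
  nz <- Njk > 0L
  sum(Njk[nz] * log(Njk[nz] / rep(Nj, 2L)[nz]))
}

#' Structure complexity of the disease node
#'
#' The free-parameter count of the node's conditional probability
#' table, \eqn{C(S) = q (r - 1)} with \eqn{q = 3^{|S|}} parent
#' configurations and \eqn{r = 2} label states.
#'
#' @param counts a [build_counts()] result.
#' @return Integer parameter count.
#' @export
complexity <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  counts$q * (counts$r - 1L)
}

#' AIC local score
#'
#' Log-likelihood penalised by the free-parameter count:
#' \eqn{\mathrm{LL} - C(S)}.
#'
#' @inheritParams log_likelihood
#' @return AIC score (larger is better).
#' @export
aic_score <- function(counts) {
  log_likelihood(counts) - complexity(counts)
}

#' BIC local score with rescaled penalty
#'
#' \deqn{\mathrm{LL} - c \, \ln(N) \, C(S)}
#' The classical BIC uses \eqn{c = 1/2}, derived in the large-sample
#' limit; that penalty is too strict for the sample sizes of typical
#' case-control studies and masks interaction terms, so the default is
#' the rescaled coefficient \eqn{c = 0.17}.
#'
#' @inheritParams log_likelihood
#' @param spec a [score_spec()]; only \code{penalty_coefficient} is
#'   used.
#' @return BIC score (larger is better).
#' @export
bic_score <- function(counts, spec = score_spec("bic")) {
  log_likelihood(counts) -
    spec$penalty_coefficient * log(counts$N) * complexity(counts)
}

#' BDe local score
#'
#' Log marginal likelihood of the label counts under independent
#' Dirichlet priors per parent configuration:
#' \deqn{\sum_j \left[\ln\Gamma(a_j) - \ln\Gamma(a_j + N_j)\right] +
#'       \sum_j \sum_k \left[\ln\Gamma(a_{jk} + N_{jk}) -
#'       \ln\Gamma(a_{jk})\right]}
#' with uniform priors \eqn{a_{jk} = \mathrm{ess}/(r q)} and
#' \eqn{a_j = \mathrm{ess}/q}.  The default equivalent sample size is
#' the dataset size \eqn{N}.  Computed with \code{lgamma} throughout,
#' so it is finite for any valid counts.
#'
#' @inheritParams log_likelihood
#' @param spec a [score_spec()]; \code{ess} sets the prior strength.
#' @return BDe score on the log scale (larger is better).
#' @export
bde_score <- function(counts, spec = score_spec("bde")) {
  ess <- if (is.null(spec$ess)) counts$N else spec$ess
  q <- counts$q
  a_jk <- ess / (counts$r * q)
  a_j <- ess / q
  if (a_jk <= 0) stop("BDe prior cells must be strictly positive",
                      call. = FALSE)
  sum(lgamma(a_j) - lgamma(a_j + counts$N_j)) +
    sum(lgamma(a_jk + counts$N_jk) - lgamma(a_jk))
}

#' Local score of the disease node for a candidate parent set
#'
#' Builds the contingency counts and dispatches to the family selected
#' in \code{spec}.  Pure function of its inputs: repeated calls with
#' identical arguments return identical values.
#'
#' @param data a [genotype_dataset].
#' @param parent_set SNP ids or column indices (possibly empty).
#' @param spec a [score_spec()].
#' @return The local score (larger is better).
#' @examples
#' d <- genotype_dataset(matrix(rep(0:1, 50), ncol = 1),
#'                       labels = rep(c(0L, 1L), 50), snp_ids = "A")
#' local_score(d, character(0))   # empty parent set
#' local_score(d, "A")            # SNP identical to the label
#' @export
local_score <- function(data, parent_set = integer(0),
                        spec = score_spec("bic")) {
  counts <- build_counts(data, parent_set)
  switch(spec$family,
         loglik = log_likelihood(counts),
         aic    = aic_score(counts),
         bic    = bic_score(counts, spec),
         bde    = bde_score(counts, spec))
}

# Fast closure used by the search: avoids object construction per node.
# Returns function(parent_idx) -> score for the given data and spec.
make_score_fun <- function(data, spec) {
  G <- data$genotypes
  labels <- data$labels
  N <- data$N
  logN <- log(N)
  fam <- spec$family
  cpen <- spec$penalty_coefficient
  ess <- if (is.null(spec$ess)) N else spec$ess
  function(parent_idx) {
    k <- length(parent_idx)
    q <- 3L^k
    j <- parent_config_index(G, parent_idx)
    cnt <- tabulate((j - 1L) * 2L + labels + 1L, nbins = 2L * q)
    if (fam == "bde") {
      a_jk <- ess / (2 * q)
      a_j <- ess / q
      Nj <- cnt[seq(1L, 2L * q, by = 2L)] + cnt[seq(2L, 2L * q, by = 2L)]
      return(sum(lgamma(a_j) - lgamma(a_j + Nj)) +
               sum(lgamma(a_jk + cnt) - lgamma(a_jk)))
    }
    Nj2 <- rep(cnt[seq(1L, 2L * q, by = 2L)] + cnt[seq(2L, 2L * q, by = 2L)],
               each = 2L)
    nz <- cnt > 0L
    ll <- sum(cnt[nz] * log(cnt[nz] / Nj2[nz]))
    switch(fam,
           loglik = ll,
           aic    = ll - q,
           bic    = ll - cpen * logN * q)
  }
}
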