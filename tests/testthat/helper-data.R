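# Shared fixtures and independent oracles, built in code.

# Small labelled dataset with known structure.
toy_dataset <- function() {
  genotype_dataset(
    matrix(c(0L, 0L, 1L, 1L,
             0L, 1L, 2L, 0L), ncol = 2),
    labels = c(0L, 1L, 0L, 1L),
    snp_ids = c("A", "B"))
}

# Random dataset with labels independent of the genotypes.
random_null_dataset <- function(N = 60L, n = 5L, seed = 1L, maf = 0.3) {
  set.seed(seed)
  genotype_dataset(matrix(rbinom(N * n, 2L, maf), N, n),
                   labels = rbinom(N, 1L, 0.5))
}

# Two-locus pure-interaction (XOR-like) dataset: the label is the
# parity of the two genotype codes, flipped with probability `flip`.
# Neither locus has any marginal association with the label.
parity2_dataset <- function(N = 1000L, flip = 0.05, n_noise = 0L,
                            seed = 1L, maf = 0.5) {
  set.seed(seed)
  g <- matrix(rbinom(N * (2L + n_noise), 2L, maf), N, 2L + n_noise)
  lab <- (g[, 1L] + g[, 2L]) %% 2L
  swap <- runif(N) < flip
  lab[swap] <- 1L - lab[swap]
  genotype_dataset(g, as.integer(lab))
}

# Independent BDe oracle: for integer counts the log-Gamma ratio
# telescopes into an exact product, lgamma(a + n) - lgamma(a) =
# sum_{i=0}^{n-1} log(a + i).  No lgamma call anywhere.
log_gamma_ratio <- function(a, n) {
  if (n == 0L) return(0)
  sum(log(a + seq_len(n) - 1))
}

bde_oracle <- function(N_jk, ess) {
  q <- nrow(N_jk)
  a_jk <- ess / (2 * q)
  a_j <- ess / q
  s <- 0
  for (j in seq_len(q)) {
    nj <- sum(N_jk[j, ])
    s <- s - log_gamma_ratio(a_j, nj)
    for (k in 1:2) s <- s + log_gamma_ratio(a_jk, N_jk[j, k])
  }
  s
}

# Reference Hardy-Weinberg genotype proportions.
hw_probs_ref <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# Brute-force G^2 from first principles (explicit margins, no shortcuts).
g2_oracle <- function(O) {
  total <- sum(O)
  g2 <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    if (O[i, j] > 0) {
      E <- sum(O[i, ]) * sum(O[, j]) / total
      g2 <- g2 + 2 * O[i, j] * log(O[i, j] / E)
    }
  }
  g2
}

# All subsets of `cand` up to size kmax, scored directly with
# local_score (independent of the search machinery's fast path).
best_subset_oracle <- function(data, cand, kmax, spec) {
  best_ids <- character(0)
  best <- local_score(data, integer(0), spec)
  for (k in seq_len(kmax)) {
    if (k > length(cand)) break
    sets <- combn(cand, k)
    for (col in seq_len(ncol(sets))) {
      s <- local_score(data, sets[, col], spec)
      ids <- sort(data$snp_ids[sets[, col]])
      if (s > best ||
          (s == best && (length(ids) < length(best_ids) ||
                         (length(ids) == length(best_ids) &&
                          paste(ids, collapse = "\r") <
                            paste(best_ids, collapse = "\r"))))) {
        best <- s
        best_ids <- ids
      }
    }
  }
  list(best_set = best_ids, best_score = best)
}
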