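test_that("contingency counts tally label by parent configuration", {
  d <- toy_dataset()

  c0 <- build_counts(d, integer(0))
  expect_equal(c0$q, 1L)
  expect_equal(unname(c0$N_jk), matrix(c(2L, 2L), nrow = 1))
  expect_equal(c0$N_j, 4)

  cA <- build_counts(d, "A")   # A = (0,0,1,1), labels (0,1,0,1)
  expect_equal(cA$q, 3L)
  expect_equal(unname(cA$N_jk),
               matrix(c(1L, 1L, 1L, 1L, 0L, 0L), nrow = 3, byrow = TRUE))
  expect_equal(sum(cA$N_jk), cA$N)
  expect_equal(cA$N_j, rowSums(cA$N_jk))

  expect_error(build_counts(d, c("A", "A")), "duplicate")
  expect_error(build_counts(d, 5L), "out of range")
})

test_that("configuration indexing is mixed-radix over parents in order", {
  d <- genotype_dataset(matrix(c(1L, 2L, 0L, 1L), nrow = 2), c(0L, 1L),
                        snp_ids = c("A", "B"))
  # individual 1: A=1, B=0 -> config 1 + 0*3 = index 2
  # individual 2: A=2, B=1 -> config 2 + 1*3 = index 6
  cc <- build_counts(d, c("A", "B"))
  expect_equal(cc$q, 9L)
  expect_equal(unname(cc$N_jk[2, "control"]), 1)
  expect_equal(unname(cc$N_jk[6, "case"]), 1)
  expect_equal(sum(cc$N_jk), 2)
})

test_that("log-likelihood matches closed forms and conventions", {
  d <- genotype_dataset(matrix(0L, 100, 1), rep(c(0L, 1L), 50))
  expect_equal(log_likelihood(build_counts(d)), 100 * log(0.5),
               tolerance = 1e-12)

  # unobserved parent configurations (N_j = 0) contribute nothing
  cc <- build_counts(d, 1L)  # SNP constant 0: rows for g=1,2 empty
  expect_equal(log_likelihood(cc), 100 * log(0.5), tolerance = 1e-12)

  # label perfectly determined by the parent -> LL = 0
  dp <- genotype_dataset(matrix(rep(0:1, 50), ncol = 1),
                         labels = rep(c(0L, 1L), 50))
  expect_equal(log_likelihood(build_counts(dp, 1L)), 0)
  expect_lte(log_likelihood(build_counts(dp)), 0)
})

test_that("complexity is the free-parameter count q(r-1)", {
  d <- random_null_dataset(n = 4L)
  expect_equal(complexity(build_counts(d)), 1L)
  expect_equal(complexity(build_counts(d, 1L)), 3L)
  expect_equal(complexity(build_counts(d, 1:3)), 27L)
})

test_that("AIC and BIC match hand-evaluated values", {
  d <- genotype_dataset(matrix(0L, 100, 1), rep(c(0L, 1L), 50))
  c0 <- build_counts(d)
  ll <- 100 * log(0.5)

  expect_equal(aic_score(c0), ll - 1, tolerance = 1e-9)
  expect_equal(bic_score(c0, score_spec("bic")),
               ll - 0.17 * log(100), tolerance = 1e-9)
  expect_equal(bic_score(c0, score_spec("bic", penalty_coefficient = 0.5)),
               ll - 0.5 * log(100), tolerance = 1e-9)

  # SNP coded identically to the label: perfect fit, C(S) = 3
  dp <- genotype_dataset(matrix(rep(0:1, 50), ncol = 1),
                         labels = rep(c(0L, 1L), 50))
  s1 <- bic_score(build_counts(dp, 1L), score_spec("bic"))
  expect_equal(s1, -0.17 * log(100) * 3, tolerance = 1e-9)
  expect_gt(s1, bic_score(build_counts(dp), score_spec("bic")))

  # perfect-fit 1-parent AIC
  expect_equal(aic_score(build_counts(dp, 1L)), -3, tolerance = 1e-9)
})

test_that("BDe matches its closed form and an exact Gamma-ratio oracle", {
  # N = 1, empty parents, one case: a_j = 1, a_jk = 0.5
  d1 <- genotype_dataset(matrix(integer(0), nrow = 1, ncol = 0), labels = 1L)
  expect_equal(bde_score(build_counts(d1)), log(0.5), tolerance = 1e-9)

  # a fully empty configuration contributes zero
  d <- genotype_dataset(matrix(0L, 10, 1), rep(c(0L, 1L), 5))
  cc <- build_counts(d, 1L)   # rows g=1, g=2 empty
  cc_small <- build_counts(d) # same counts, q = 1
  spec10 <- score_spec("bde", ess = 10)
  a <- bde_score(cc, score_spec("bde", ess = 30))  # a_jk = 5 in each row
  b <- bde_score(cc_small, spec10)                 # a_jk = 5, single row
  expect_equal(a, b, tolerance = 1e-9)

  # random count tables vs the telescoped-product oracle
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(0:2, 1)
    N <- sample(4:40, 1)
    dat <- genotype_dataset(matrix(rbinom(N * 3L, 2L, 0.4), N, 3L),
                            labels = rbinom(N, 1L, 0.5))
    parents <- if (k == 0) integer(0) else seq_len(k)
    cc <- build_counts(dat, parents)
    expect_equal(bde_score(cc, score_spec("bde")),
                 bde_oracle(cc$N_jk, ess = N), tolerance = 1e-9)
  }
})

test_that("local_score dispatches each family and is deterministic", {
  d <- random_null_dataset(seed = 5)
  c1 <- build_counts(d, 2L)
  expect_identical(local_score(d, 2L, score_spec("loglik")),
                   log_likelihood(c1))
  expect_identical(local_score(d, 2L, score_spec("aic")), aic_score(c1))
  expect_identical(local_score(d, 2L, score_spec("bic")),
                   bic_score(c1, score_spec("bic")))
  expect_identical(local_score(d, 2L, score_spec("bde")),
                   bde_score(c1, score_spec("bde")))
  expect_identical(local_score(d, c(1L, 3L), score_spec("bic")),
                   local_score(d, c(1L, 3L), score_spec("bic")))
})

test_that("likelihood is monotone in nested parent sets and scores finite", {
  for (seed in 1:5) {
    d <- random_null_dataset(N = 50L, n = 4L, seed = seed)
    sets <- list(integer(0), 1L, c(1L, 2L), c(1L, 2L, 3L), c(1L, 2L, 3L, 4L))
    ll <- vapply(sets, function(s) local_score(d, s, score_spec("loglik")),
                 numeric(1))
    expect_true(all(diff(ll) >= -1e-10))
    for (fam in c("loglik", "aic", "bic", "bde"))
      for (s in sets)
        expect_true(is.finite(local_score(d, s, score_spec(fam))))
  }
})

test_that("BDe and classical BIC agree on the top set for strong signals", {
  for (seed in 1:3) {
    set.seed(seed)
    N <- 400L
    g <- matrix(rbinom(N * 6L, 2L, 0.5), N, 6L)
    lab <- as.integer((g[, 1] >= 1 & g[, 2] >= 1) | runif(N) < 0.02)
    d <- genotype_dataset(g, lab)
    top <- function(spec)
      best_subset_oracle(d, seq_len(6L), 2L, spec)$best_set
    expect_identical(top(score_spec("bde")),
                     top(score_spec("bic", penalty_coefficient = 0.5)))
  }
})

test_that("score_spec validates its arguments", {
  expect_error(score_spec("bic", penalty_coefficient = 0), "> 0")
  expect_error(score_spec("bde", ess = -1), "> 0")
  expect_error(score_spec("mdl"))
})
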