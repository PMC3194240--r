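test_that("penetrance tables match the odds-form definitions", {
  m1 <- make_model("multiplicative", alpha = 0.05, theta = 1)
  expect_equal(m1$table[1, 1], 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(m1$table[3, 3], 0.8 / 1.8, tolerance = 1e-12)
  expect_equal(m1$table[2, 3], 0.4 / 1.4, tolerance = 1e-12)

  m3 <- make_model("interaction_threshold", alpha = 0.05, theta = 3)
  expect_equal(m3$table[2, 1], 0.05 / 1.05, tolerance = 1e-12)  # g=(1,0)
  expect_equal(m3$table[1, 3], 0.05 / 1.05, tolerance = 1e-12)  # g=(0,2)
  expect_equal(m3$table[2, 2], 0.2 / 1.2, tolerance = 1e-12)    # g=(1,1)

  m2 <- make_model("interaction_multiplicative", alpha = 0.05, theta = 2)
  expect_equal(m2$table[1, 3], 0.05 / 1.05, tolerance = 1e-12)  # g1*g2 = 0
  expect_equal(m2$table[3, 3], (0.05 * 3^4) / (1 + 0.05 * 3^4),
               tolerance = 1e-12)

  m4 <- make_model("parity3", f0 = 0.01, f1 = 0.10)
  expect_equal(m4$table[2, 2, 2], 0.10)  # g = (1,1,1), odd sum
  expect_equal(m4$table[3, 1, 1], 0.01)  # g = (2,0,0), even sum
  expect_true(all(m4$table > 0 & m4$table < 1))

  expect_error(make_model("parity3", f0 = 0.2, f1 = 0.1), "f0 < f1")
  expect_error(make_model("multiplicative", alpha = -1), "alpha")
  expect_error(make_model("multiplicative", theta = -2), "theta")
  expect_identical(disease_model(4)$kind, "parity3")
})

test_that("parity3 at MAF 0.5 has exactly zero marginal effects", {
  m <- make_model("parity3", f0 = 0.01, f1 = 0.10)
  for (locus in 1:3) {
    fm <- marginal_penetrance(m, locus, maf = 0.5)
    expect_equal(fm, rep((0.01 + 0.10) / 2, 3), tolerance = 1e-15)
  }
  # away from MAF 0.5 the cancellation breaks
  expect_false(isTRUE(all.equal(marginal_penetrance(m, 1, maf = 0.3),
                                rep(0.055, 3))))
})

test_that("multiplicative marginal penetrance increases with genotype", {
  m <- make_model("multiplicative")
  fm <- marginal_penetrance(m, 1, maf = 0.5)
  expect_true(all(diff(fm) > 0))
  # exact check against a direct weighted sum over the other locus
  p <- c(0.25, 0.5, 0.25)
  expect_equal(fm[2], sum(m$table[2, ] * p), tolerance = 1e-12)
})

test_that("simulated datasets honour quotas, truth ids and r2 = 1", {
  cfg <- sim_config(150, 100, n_markers = 10, maf = 0.5, seed = 5)
  d <- simulate_dataset(disease_model(1), ld_spec(1), cfg)
  expect_equal(sum(d$labels == 1L), 150L)
  expect_equal(sum(d$labels == 0L), 100L)
  expect_equal(d$n, 10L)
  truth <- attr(d, "truth")
  expect_length(truth, 2L)
  expect_true(all(truth %in% d$snp_ids))
  # with r2 = 1 the disease markers ARE the latent loci
  latent <- attr(d, "latent")
  expect_identical(d$genotypes[, match(truth, d$snp_ids)], latent)
})

test_that("marker allele frequencies track their targets", {
  d <- simulate_dataset(disease_model(4), ld_spec(1),
                        sim_config(1000, 1000, n_markers = 6, maf = 0.5,
                                   seed = 19))
  truth_idx <- match(attr(d, "truth"), d$snp_ids)
  maf_hat <- colMeans(d$genotypes[, truth_idx]) / 2
  expect_true(all(abs(maf_hat - 0.5) < 0.03))
})

test_that("background markers follow Hardy-Weinberg proportions", {
  cfg <- sim_config(1000, 1000, n_markers = 5, maf = 0.5,
                    background_maf_range = c(0.3, 0.3), seed = 23)
  d <- simulate_dataset(disease_model(1), ld_spec(1), cfg)
  bg <- setdiff(seq_len(d$n), match(attr(d, "truth"), d$snp_ids))
  for (j in bg) {
    obs <- tabulate(d$genotypes[, j] + 1L, 3L) / d$N
    expect_true(all(abs(obs - hw_probs_ref(0.3)) < 0.04))
  }
})

test_that("r2 = 0.7 markers correlate with their latent loci as specified", {
  d <- simulate_dataset(disease_model(1), ld_spec(0.7),
                        sim_config(1000, 1000, n_markers = 4, maf = 0.5,
                                   seed = 29))
  latent <- attr(d, "latent")
  idx <- match(attr(d, "truth"), d$snp_ids)
  for (l in 1:2) {
    r2_hat <- cor(d$genotypes[, idx[l]], latent[, l])^2
    expect_true(abs(r2_hat - 0.7) < 0.05)
  }
})

test_that("parity enrichment in cases matches the analytic value", {
  d <- simulate_dataset(make_model("parity3", f0 = 0.01, f1 = 0.10),
                        ld_spec(1),
                        sim_config(2000, 2000, n_markers = 3, maf = 0.5,
                                   seed = 37))
  idx <- match(attr(d, "truth"), d$snp_ids)
  parity <- rowSums(d$genotypes[, idx]) %% 2L
  # P(odd | case) = f1 / (f0 + f1) at MAF 0.5
  expect_equal(mean(parity[d$labels == 1L]), 0.10 / 0.11, tolerance = 0.03)
  expect_equal(mean(parity[d$labels == 0L]),
               0.90 / (0.90 + 0.99), tolerance = 0.03)
})

test_that("observed case rate matches the implied population prevalence", {
  m <- disease_model(1)
  prev <- sum(as.numeric(m$table) *
                as.numeric(outer(hw_probs_ref(0.5), hw_probs_ref(0.5))))
  d <- simulate_dataset(m, ld_spec(1),
                        sim_config(1500, 1500, n_markers = 2, maf = 0.5,
                                   seed = 41))
  stats <- attr(d, "sim_stats")
  expect_gt(stats$draws, 0)
  expect_equal(stats$case_rate, prev, tolerance = 0.03)
})

test_that("batches are reproducible and internally independent", {
  cfg <- sim_config(60, 60, n_markers = 8, seed = 11, n_datasets = 3)
  b1 <- simulate_batch(disease_model(2), ld_spec(1), cfg)
  b2 <- simulate_batch(disease_model(2), ld_spec(1), cfg)
  expect_length(b1, 3L)
  for (i in 1:3) {
    expect_identical(b1[[i]]$genotypes, b2[[i]]$genotypes)
    expect_equal(sum(b1[[i]]$labels), 60L)
  }
  expect_false(identical(b1[[1]]$genotypes, b1[[2]]$genotypes))
})

test_that("simulator validates its configuration", {
  expect_error(sim_config(0, 10), "quotas")
  expect_error(sim_config(10, 10, maf = 0.7), "maf")
  expect_error(ld_spec(0), "r2")
  expect_error(ld_spec(1.2), "r2")
  expect_error(simulate_dataset(disease_model(4), ld_spec(1),
                                sim_config(5, 5, n_markers = 2)),
               "disease loci")
  expect_error(simulate_dataset(disease_model(1), ld_spec(1),
                                sim_config(5, 5, n_markers = 10,
                                           disease_positions = c(1, 1))),
               "distinct")
})
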