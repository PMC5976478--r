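test_that("per-patient hit probability follows the closed form", {
  expect_equal(per_patient_hit_prob(0, 3100, 62e6), 0)
  expect_equal(per_patient_hit_prob(5, 62e6, 62e6), 1)
  expect_equal(per_patient_hit_prob(62, 3100, 62e6),
               1 - (1 - 5e-5)^62, tolerance = 1e-15)
  expect_equal(per_patient_hit_prob(62, 3100, 62e6), 3.0953e-3,
               tolerance = 1e-4)
  expect_error(per_patient_hit_prob(5, 100, 50), "exceed")
})

test_that("Poisson-binomial tail matches hand-computed values", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 1), 0.75)
  expect_equal(poisson_binomial_tail(c(0.1, 0.1, 0.1), 2), 0.028,
               tolerance = 1e-12)
  expect_equal(poisson_binomial_tail(c(0.3, 0.9), 0), 1)
  expect_equal(poisson_binomial_tail(c(0.3, 0.9), 3), 0)
  expect_error(poisson_binomial_tail(c(0.5, 1.2), 1), "\\[0, 1\\]")
  expect_error(poisson_binomial_tail(c(0.5), 3), "k must be")
})

test_that("Poisson-binomial tail equals exhaustive enumeration up to n = 12", {
  set.seed(99)
  for (n in c(1, 2, 3, 5, 8, 12)) {
    probs <- stats::runif(n)
    for (k in 0:n) {
      expect_equal(poisson_binomial_tail(probs, k), pb_tail_enum(probs, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("tail is monotone in k and in every success probability", {
  set.seed(5)
  probs <- stats::runif(8)
  tails <- vapply(0:8, function(k) poisson_binomial_tail(probs, k), numeric(1))
  expect_true(all(diff(tails) <= 1e-12))
  for (i in seq_along(probs)) {
    bumped <- probs
    bumped[i] <- min(1, probs[i] + 0.2)
    for (k in 0:8) {
      expect_gte(poisson_binomial_tail(bumped, k) + 1e-12,
                 poisson_binomial_tail(probs, k))
    }
  }
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("BH agrees with a literal step-up oracle and is permutation-stable", {
  set.seed(13)
  for (rep in 1:10) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    # q is monotone along sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("gene_significance matches the subset-enumeration oracle on small cohorts", {
  set.seed(41)
  params <- simulation_params(n_samples = 6, load_range = c(5, 15),
                              n_shared_pairs = 0, n_shared_triples = 0,
                              gene_lengths = stats::setNames(rep(20000, 40),
                                                             sprintf("G%02d", 1:40)),
                              seed = 41)
  cohort <- simulate_cohort(params)
  res <- gene_significance(cohort, params$gene_lengths)
  rec <- cohort$records
  qual <- rec[!(rec$consequence %in% silent_consequences()) & !is.na(rec$gene), ]
  n_i <- table(factor(qual$sample_id, levels = sort(unique(rec$sample_id))))
  for (i in seq_len(nrow(res))) {
    g <- res$gene[i]
    probs <- per_patient_hit_prob(as.integer(n_i), 20000, 62e6)
    expect_equal(res$p_value[i], pb_tail_enum(probs, res$k[i]),
                 tolerance = 1e-12)
  }
  expect_equal(res$q_value, bh_fdr(res$p_value), tolerance = 1e-12)
})

test_that("a gene spiked into 6 of 8 patients attains the minimum p-value", {
  lengths <- stats::setNames(rep(1500, 1000), sprintf("GENE%04d", 1:1000))
  lengths["SPIKED"] <- 1500
  params <- simulation_params(spike_genes = c(SPIKED = 6),
                              gene_lengths = lengths, seed = 77)
  cohort <- simulate_cohort(params)
  res <- gene_significance(cohort, lengths)
  expect_equal(res$gene[which.min(res$p_value)], "SPIKED")
  expect_equal(res$k[res$gene == "SPIKED"], 6L)
  expect_true(res$flagged[res$gene == "SPIKED"])
})

test_that("unobserved genes and missing lengths behave as documented", {
  cohort <- make_cohort(c("S1", "S2"), gene = c("A1", "A2"), pos = c(101L, 202L))
  lengths <- c(A1 = 1000, A2 = 1000, A3 = 1000)
  res <- gene_significance(cohort, lengths)
  expect_setequal(res$gene, c("A1", "A2"))   # k = 0 genes are not tested
  expect_error(gene_significance(cohort, c(A1 = 1000)), "A2")
  # a gene hit by zero patients has tail P(X >= 0) = 1 by construction
  expect_equal(poisson_binomial_tail(c(0.01, 0.02), 0), 1)
})

test_that("the mutation-count statistic variant uses the binomial background", {
  cohort <- make_cohort(c("S1", "S1", "S2"), gene = "A1",
                        pos = c(101L, 150L, 202L))
  lengths <- c(A1 = 1000)
  res <- gene_significance(cohort, lengths, statistic = "mutations")
  expect_equal(res$k, 3L)
  expect_equal(res$p_value,
               stats::pbinom(2, 3, 1000 / 62e6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("null cohorts keep the q < 0.10 discovery fraction under control", {
  # genes tile the whole territory, so every mutation lands in a gene and the
  # background model holds exactly; 500 seeded replicates
  n_genes <- 800
  territory_bp <- 62e6
  lengths <- stats::setNames(rep(territory_bp / n_genes, n_genes),
                             sprintf("GENE%04d", 1:n_genes))
  set.seed(2024)
  n_tested <- 0
  n_flagged <- 0
  for (rep in 1:500) {
    loads <- sample(19:74, 8, replace = TRUE)
    gene <- sample(names(lengths), sum(loads), replace = TRUE)
    rec <- data.frame(
      sample_id = rep(sprintf("S%d", 1:8), loads),
      gene = gene, chrom = "1", pos = seq_along(gene) + 100L,
      ref = "C", alt = "T", flank5 = "A", flank3 = "G",
      consequence = "missense", stringsAsFactors = FALSE
    )
    res <- gene_significance(cohort_variants(rec), lengths)
    n_tested <- n_tested + nrow(res)
    n_flagged <- n_flagged + sum(res$flagged)
  }
  frac <- n_flagged / n_tested
  se <- sqrt(0.10 * 0.90 / n_tested)
  expect_lte(frac, 0.10 + 3 * se)
})
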