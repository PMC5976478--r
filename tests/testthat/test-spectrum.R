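test_that("substitution normalization follows the pyrimidine convention", {
  expect_equal(normalize_substitution("C", "T", "A", "G"),
               data.frame(class = "C>T", context = "ACG>ATG"))
  # same event read from the purine strand
  expect_equal(normalize_substitution("G", "A", "C", "G"),
               data.frame(class = "C>T", context = "CCG>CTG"))
  expect_error(normalize_substitution("C", "C", "A", "G"), "differ")
  expect_error(normalize_substitution("C", "N", "A", "G"), "A, C, G or T")
})

test_that("full input enumeration collapses to exactly 96 categories", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, f5 = bases, f3 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]          # 4*3*4*4 = 192 inputs
  norm <- normalize_substitution(grid$ref, grid$alt, grid$f5, grid$f3)
  expect_equal(length(unique(norm$context)), 96L)
  expect_setequal(unique(norm$context), trinucleotide_contexts())
  expect_setequal(unique(norm$class), substitution_classes())
  # every category is reachable from exactly two strand representations
  expect_true(all(table(norm$context) == 2L))
})

test_that("normalization is invariant under reverse complement (involution)", {
  set.seed(7)
  rows <- random_snv_rows(500)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  fwd <- normalize_substitution(rows$ref, rows$alt, rows$flank5, rows$flank3)
  rev <- normalize_substitution(unname(rc[rows$ref]), unname(rc[rows$alt]),
                                unname(rc[rows$flank3]), unname(rc[rows$flank5]))
  expect_equal(fwd, rev)
})

test_that("build_spectrum conserves counts and keeps zero categories", {
  empty <- make_cohort(character(0), pos = integer(0))
  sp0 <- build_spectrum(empty)
  expect_length(sp0$context_counts, 96)
  expect_true(all(sp0$context_counts == 0))

  one <- make_cohort("S1", ref = "C", alt = "T", flank5 = "A", flank3 = "G")
  sp1 <- build_spectrum(one)
  expect_equal(unname(sp1$context_counts["ACG>ATG"]), 1L)
  expect_equal(sum(sp1$context_counts), 1L)

  set.seed(11)
  cohort <- cohort_variants(random_snv_rows(400))
  sp <- build_spectrum(cohort)
  expect_equal(sum(sp$context_counts), 400L)
  expect_equal(sum(sp$class_counts), 400L)
  expect_equal(sum(sp$class_counts), sum(sp$context_counts))
})

test_that("simulated C>T fraction matches its generating parameter", {
  params <- simulation_params(n_samples = 8, n_private = 2000,
                              n_shared_pairs = 0, n_shared_triples = 0,
                              ct_fraction = 0.39, seed = 23)
  sp <- build_spectrum(simulate_cohort(params))
  frac <- sp$class_counts[["C>T"]] / sum(sp$class_counts)
  se <- sqrt(0.39 * 0.61 / 2000)
  expect_lt(abs(frac - 0.39), 3 * se)
})

test_that("mutation_rate is a guarded division", {
  expect_equal(mutation_rate(62, 62), 1)
  expect_equal(mutation_rate(0, 62), 0)
  expect_equal(mutation_rate(117, 62), 117 / 62, tolerance = 1e-12)
  expect_error(mutation_rate(10, 0), "positive")
})

test_that("load_stats uses the even-n midpoint median and range", {
  cohort <- make_cohort(c(rep("A", 37), rep("B", 38)),
                        pos = 1:75 + 100L)
  st <- load_stats(cohort)
  expect_equal(st$median, 37.5)

  cohort2 <- make_cohort(c(rep("A", 19), rep("B", 74)), pos = 1:93 + 10L)
  st2 <- load_stats(cohort2)
  expect_equal(st2$minimum, 19L)
  expect_equal(st2$maximum, 74L)
  expect_equal(st2$mean, 46.5)
  expect_error(load_stats(make_cohort(character(0), pos = integer(0))), "empty")
})

test_that("load_stats median matches a sort-based oracle on simulated loads", {
  set.seed(3)
  loads <- sample(19:74, 8, replace = TRUE)
  ids <- rep(sprintf("S%02d", 1:8), loads)
  cohort <- make_cohort(ids, pos = seq_along(ids) + 50L)
  st <- load_stats(cohort)
  sorted <- sort(loads)
  expect_equal(st$median, (sorted[4] + sorted[5]) / 2)
  expect_equal(unname(st$per_sample_counts), loads)
})

test_that("non-silent rate excludes the configured silent classes", {
  cohort <- make_cohort(rep("S1", 4),
                        consequence = c("missense", "synonymous", "intron", "nonsense"),
                        pos = 101:104)
  st <- load_stats(cohort)
  expect_equal(st$total_rate_per_mbp, 4 / 62)
  expect_equal(st$nonsilent_rate_per_mbp, 2 / 62)
  st2 <- load_stats(cohort, silent_classes = "synonymous")
  expect_equal(st2$nonsilent_rate_per_mbp, 3 / 62)
})

test_that("recurrence collapse keys variants by position and alleles", {
  trio <- make_cohort(c("S1", "S2", "S3"), pos = rep(1000L, 3))
  rc <- collapse_recurrence(trio)
  expect_equal(rc$total_observations, 3L)
  expect_equal(rc$unique_variants, 1L)
  expect_equal(rc$multiplicity_histogram, c("3" = 1L))

  private <- make_cohort(rep("S1", 12), pos = 1:12 + 500L)
  rp <- collapse_recurrence(private)
  expect_equal(rp$total_observations, 12L)
  expect_equal(rp$unique_variants, 12L)
})

test_that("recurrence identities hold under random sharing structures", {
  set.seed(19)
  for (rep in 1:5) {
    rows <- random_snv_rows(120)
    # clone some rows into other samples to create sharing
    clones <- rows[sample(nrow(rows), 30), ]
    clones$sample_id <- sample(sprintf("S%02d", 1:8), 30, replace = TRUE)
    cohort <- cohort_variants(rbind(rows, clones))
    rc <- collapse_recurrence(cohort)
    k <- as.integer(names(rc$multiplicity_histogram))
    expect_equal(rc$total_observations, sum(k * rc$multiplicity_histogram))
    expect_equal(rc$unique_variants, sum(rc$multiplicity_histogram))
  }
})

test_that("the published sharing structure collapses to 310 total / 303 unique", {
  params <- simulation_params(n_private = 297, n_shared_pairs = 5,
                              n_shared_triples = 1, seed = 17)
  rc <- collapse_recurrence(simulate_cohort(params))
  expect_equal(rc$total_observations, 310L)
  expect_equal(rc$unique_variants, 303L)
  expect_equal(rc$multiplicity_histogram,
               c("1" = 297L, "2" = 5L, "3" = 1L))
})
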