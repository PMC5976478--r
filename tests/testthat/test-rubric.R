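table1 <- load_table1_evidence()
row1 <- function(label) table1[table1$variant_label == label, ]

test_that("algorithm votes count pathogenic calls, missing never votes", {
  blank <- evidence_record("X")
  expect_equal(algorithm_votes(blank), 0L)

  pik3ca <- row1("p.E545K c.1633G>A")
  expect_equal(algorithm_votes(pik3ca), 4L)   # FATHMM, PolyPhen, GV/GD, CHASM

  ak8 <- row1("p.T101P c.301A>C")
  expect_equal(algorithm_votes(ak8), 1L)      # only GV/GD C35

  # system 2 drops the GV/GD algorithm
  expect_equal(algorithm_votes(pik3ca, system = 2), 3L)
  expect_equal(algorithm_votes(ak8, system = 2), 0L)
})

test_that("GV/GD votes from C35 upward and CHASM below alpha", {
  base <- evidence_record("X")
  for (cls in c("C0", "C15", "C25")) {
    base$gvgd_class <- cls
    expect_equal(algorithm_votes(base), 0L)
  }
  for (cls in c("C35", "C45", "C55", "C65")) {
    base$gvgd_class <- cls
    expect_equal(algorithm_votes(base), 1L)
  }
  e <- evidence_record("X", chasm_p = 0.049)
  expect_equal(algorithm_votes(e), 1L)
  e$chasm_p <- 0.05           # threshold is strict
  expect_equal(algorithm_votes(e), 0L)
})

test_that("System-1 scores reproduce the printed totals on the verified rows", {
  verified <- c("p.E545K c.1633G>A", "p.H1047R c.3140A>G", "p.H1047L c.3140A>T",
                "p.P443T c.1327C>A",   # CIITA
                "p.R590W c.1768C>T",   # CACNA1E
                "p.T101P c.301A>C",    # AK8
                "p.R472G c.1414C>G",   # CILP2
                "p.S283* c.848C>G",    # NOL9
                "p.R898* c.2692C>T",   # TTC21B
                "p.R1166C c.3496C>T",  # FLG
                "p.R541Q c.1622G>A",   # POC5
                "p.E718D c.2154G>C",   # FAM65B
                "p.E501G c.1502A>G",   # MYO1H
                "p.R277P c.830G>C",    # SLC13A1
                "p.G183V c.548G>T")    # ZNF33A
  sub <- table1[table1$variant_label %in% verified, ]
  expect_equal(nrow(sub), 15L)
  sc <- score_system1(sub)
  expect_equal(sc$score, sub$printed_total)
  expect_equal(sc$label, sub$printed_label)
})

test_that("itemized points always sum to the score", {
  sc <- score_system1(table1)
  pts <- rowSums(sc[, grep("^pts_", names(sc))])
  expect_equal(pts, sc$score)
})

test_that("a bare nonsense variant earns only the truncating bonus", {
  e <- evidence_record("NOL9", consequence = "nonsense", fathmm = "neutral")
  expect_equal(score_system1(e)$score, 1.5)
  expect_equal(score_system1(e)$label, "Neutral")
  expect_equal(score_system1(evidence_record("X"))$score, 0)
})

test_that("System 2 uses the two-tier four-algorithm vote", {
  two <- evidence_record("X", fathmm = "pathogenic", polyphen = "deleterious")
  expect_equal(score_system2(two)$score, 0.5)
  expect_equal(score_system1(two)$score, 0)      # system 1 has no 2-vote tier
  four <- evidence_record("X", cgc = TRUE, fathmm = "pathogenic",
                          polyphen = "deleterious", sift = "not_tolerated",
                          chasm_p = 1e-4)
  expect_equal(score_system2(four)$score, 4)     # 3 CGC + 1 vote point
  expect_equal(score_system2(evidence_record("X"))$score, 0)
})

test_that("classification thresholds and the CGC override", {
  expect_equal(classify_driver(4.0, FALSE), "PD")
  expect_equal(classify_driver(3.5, FALSE), "PD")
  expect_equal(classify_driver(2.0, FALSE), "pd")
  expect_equal(classify_driver(1.5, FALSE), "Neutral")
  expect_equal(classify_driver(0.0, TRUE), "CGC")
  expect_error(classify_driver(-1, FALSE), ">= 0")
})

test_that("printed totals and CGC flags reproduce every printed label", {
  labels <- classify_driver(table1$printed_total, table1$cgc)
  expect_equal(labels, table1$printed_label)
  non_cgc_ge2 <- unique(table1$gene[!table1$cgc & table1$printed_total >= 2])
  expect_length(non_cgc_ge2, 20)
  expect_length(unique(table1$gene[table1$cgc]), 5)
})

test_that("score is monotone in every boolean criterion and vote", {
  base <- evidence_record("X", ccgd_ranks = "D", freq_all_cancers = 0.002,
                          fathmm = "pathogenic", polyphen = "deleterious")
  s0 <- score_system1(base)$score
  flips <- list(
    function(e) { e$cgc <- TRUE; e },
    function(e) { e$functional_domain <- TRUE; e },
    function(e) { e$same_variant_bc <- TRUE; e },
    function(e) { e$same_variant_other <- TRUE; e },
    function(e) { e$freq_all_cancers <- 0.02; e },
    function(e) { e$freq_bc <- 0.02; e },
    function(e) { e$consequence <- "nonsense"; e },
    function(e) { e$sift <- "not_tolerated"; e },   # adds the 3rd vote
    function(e) { e$gvgd_class <- "C65"; e },
    function(e) { e$chasm_p <- 1e-4; e }
  )
  for (flip in flips) {
    for (scorer in list(score_system1, score_system2)) {
      expect_gte(scorer(flip(base))$score, s0)
    }
  }
})

test_that("scores are non-negative multiples of 0.5 over the evidence lattice", {
  # exhaustive booleans x vote counts; frequencies/ranks at their extremes
  bools <- expand.grid(cgc = c(FALSE, TRUE), dom = c(FALSE, TRUE),
                       same = c(FALSE, TRUE), fa = c(FALSE, TRUE),
                       fb = c(FALSE, TRUE), trunc = c(FALSE, TRUE),
                       rank = c("", "A"), votes = 0:5,
                       stringsAsFactors = FALSE)
  algs <- function(k) {
    list(fathmm = if (k >= 1) "pathogenic" else "neutral",
         polyphen = if (k >= 2) "deleterious" else "benign",
         sift = if (k >= 3) "not_tolerated" else "tolerated",
         gvgd_class = if (k >= 4) "C65" else "C0",
         chasm_p = if (k >= 5) 1e-4 else 0.9)
  }
  scores <- vapply(seq_len(nrow(bools)), function(i) {
    row <- bools[i, ]
    a <- algs(row$votes)
    e <- evidence_record("X", cgc = row$cgc,
                         ccgd_ranks = row$rank,
                         functional_domain = row$dom,
                         same_variant_bc = row$same,
                         freq_all_cancers = if (row$fa) 0.02 else 0.001,
                         freq_bc = if (row$fb) 0.02 else 0.001,
                         consequence = if (row$trunc) "nonsense" else "missense",
                         fathmm = a$fathmm, polyphen = a$polyphen, sift = a$sift,
                         gvgd_class = a$gvgd_class, chasm_p = a$chasm_p)
    score_system1(e)$score
  }, numeric(1))
  expect_true(all(scores >= 0))
  expect_true(all(abs(scores * 2 - round(scores * 2)) < 1e-9))
  # maximum attainable with a missense variant under defaults
  expect_equal(max(scores[!bools$trunc]), 3 + 2 + 0.5 * 4 + 1)
  expect_equal(max(scores), 3 + 2 + 0.5 * 4 + 1 + 1.5)
})

test_that("score_table counts distinct genes per label", {
  res <- score_table(table1, system = 1)
  expect_equal(nrow(res$scores), nrow(table1))
  # label counts partition the distinct (gene, label) pairs
  pairs <- unique(res$scores[, c("gene", "label")])
  expect_equal(sum(res$label_counts), nrow(pairs))

  empty <- table1[0, ]
  res0 <- score_table(empty)
  expect_equal(nrow(res0$scores), 0L)
  expect_true(all(res0$label_counts == 0))

  set.seed(31)
  params <- simulation_params(seed = 31)
  ev <- simulate_evidence(simulate_cohort(params), params)
  res2 <- score_table(ev, system = 2)
  pairs2 <- unique(res2$scores[, c("gene", "label")])
  expect_equal(sum(res2$label_counts), nrow(pairs2))
})
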