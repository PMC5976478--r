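# Small constructors and independent oracles shared across the suite.

# build a cohort from terse per-record vectors
make_cohort <- function(sample_id, gene = "GENE1", chrom = "1",
                        pos = seq_along(sample_id) + 100L,
                        ref = "C", alt = "T", flank5 = "A", flank3 = "G",
                        consequence = "missense", territory_mbp = 62) {
  n <- length(sample_id)
  cohort_variants(data.frame(
    sample_id = sample_id,
    gene = rep_len(gene, n), chrom = rep_len(chrom, n),
    pos = rep_len(pos, n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    flank5 = rep_len(flank5, n), flank3 = rep_len(flank3, n),
    consequence = rep_len(consequence, n),
    stringsAsFactors = FALSE
  ), territory_mbp = territory_mbp)
}

# random valid SNV rows for property tests
random_snv_rows <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(
    sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
    gene = sample(sprintf("G%03d", 1:50), n, replace = TRUE),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n) + 1L,
    ref = ref, alt = unname(alt),
    flank5 = sample(bases, n, replace = TRUE),
    flank3 = sample(bases, n, replace = TRUE),
    consequence = sample(consequence_levels(), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# exhaustive 2^n Poisson-binomial tail: enumerate every outcome vector
pb_tail_enum <- function(probs, k) {
  n <- length(probs)
  if (k == 0) return(1)
  if (k > n) return(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# literal step-up BH definition, independent of stats::p.adjust
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
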