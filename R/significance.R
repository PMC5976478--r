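#' Per-patient probability of a background hit in one gene
#'
#' Under a per-patient uniform background — mutations independent among
#' nucleotides and homogeneous across the coding territory — a patient who
#' carries `n_i` non-synonymous mutations hits a gene of coding length `L_g`
#' at least once with probability `1 - (1 - L_g / territory_bp)^n_i`.
#'
#' @param n_i Non-negative integer mutation count(s) for the patient(s).
#' @param gene_length_bp Gene coding length in base pairs (positive, at most
#'   `territory_bp`).
#' @param territory_bp Total coding territory in base pairs.
#' @return Probability vector.
#' @examples
#' per_patient_hit_prob(62, 3100, 62e6)   # ~3.1e-3
#' @export
per_patient_hit_prob <- function(n_i, gene_length_bp, territory_bp) {
  if (any(n_i < 0)) stop_lum("n_i must be non-negative")
  if (any(gene_length_bp <= 0)) stop_lum("gene_length_bp must be positive")
  if (any(territory_bp <= 0)) stop_lum("territory_bp must be positive")
  if (any(gene_length_bp > territory_bp)) {
    stop_lum("gene_length_bp cannot exceed territory_bp")
  }
  1 - (1 - gene_length_bp / territory_bp)^n_i
}

#' Exact Poisson-binomial upper tail
#'
#' Probability that the sum of independent Bernoulli trials with success
#' probabilities `probs` reaches at least `k`, computed exactly by iterative
#' convolution of the count distribution. Suitable for small cohorts, where
#' normal or Poisson approximations are unreliable.
#'
#' @param probs Vector of success probabilities in `[0, 1]`.
#' @param k Integer threshold, `0 <= k <= length(probs) + 1`.
#' @return `P(X >= k)`.
#' @examples
#' poisson_binomial_tail(c(0.5, 0.5), 1)      # 0.75
#' poisson_binomial_tail(c(0.1, 0.1, 0.1), 2) # 0.028
#' @export
poisson_binomial_tail <- function(probs, k) {
  assert_prob(probs)
  n <- length(probs)
  if (length(k) != 1 || is.na(k) || k != round(k) || k < 0 || k > n + 1) {
    stop_lum("k must be a single integer in 0..length(probs)+1")
  }
  if (k == 0) return(1)
  if (k > n) return(0)
  # pmf[j + 1] = P(X = j) after convolving each trial in turn
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  # guard against tiny negative round-off
  max(0, min(1, sum(pmf[(k + 1):(n + 1)])))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false discovery rate q-values,
#' `q_(i) = min_{j >= i} m p_(j) / j` clipped at 1 and mapped back to input
#' order (ties broken by original index).
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  assert_prob(p_values, "p-values")
  stats::p.adjust(p_values, method = "BH")
}

#' Background-rate significance of recurrently mutated genes
#'
#' For each gene carrying at least one qualifying (by default non-silent) SNV,
#' tests whether the number of patients hit exceeds what the per-patient
#' uniform background predicts. Patient `i`'s background hit probability for
#' gene `g` is `1 - (1 - L_g/T)^{n_i}` where `n_i` is that patient's own
#' qualifying mutation total (heterogeneous across patients, homogeneous
#' within), and the p-value is the exact Poisson-binomial tail of the number
#' of patients hit. Q-values are Benjamini-Hochberg over all tested genes.
#'
#' `statistic = "mutations"` is an alternative reading that tests the total
#' qualifying mutation count in the gene against a binomial background over
#' all patients' trials; `background = "all"` calibrates `n_i` on every
#' observation (silent included) instead of the qualifying ones.
#'
#' @param cohort A [cohort_variants] object.
#' @param gene_lengths Named numeric vector: gene symbol to coding length in
#'   bp. Every tested gene must be present.
#' @param q_threshold FDR flagging threshold (default 0.10).
#' @param statistic `"patients"` (default; number of distinct patients hit)
#'   or `"mutations"` (total mutation count).
#' @param silent_classes Consequences excluded from the test and (by default)
#'   from the background totals.
#' @param background `"nonsilent"` (default) or `"all"`: which observations
#'   calibrate the per-patient totals `n_i`.
#' @return A `significance_result` data frame: `gene`, `k`, `p_value`,
#'   `q_value`, `flagged`, sorted by p-value.
#' @export
gene_significance <- function(cohort, gene_lengths, q_threshold = 0.10,
                              statistic = c("patients", "mutations"),
                              silent_classes = silent_consequences(),
                              background = c("nonsilent", "all")) {
  stopifnot(inherits(cohort, "cohort_variants"))
  statistic <- match.arg(statistic)
  background <- match.arg(background)
  if (is.null(names(gene_lengths)) || any(names(gene_lengths) == "")) {
    stop_lum("gene_lengths must be a named vector")
  }
  territory_bp <- cohort$territory_mbp * 1e6
  if (any(gene_lengths <= 0) || any(gene_lengths > territory_bp)) {
    stop_lum("gene lengths must be positive and no larger than the territory")
  }
  rec <- cohort$records
  samples <- sort(unique(rec$sample_id))
  qualifying <- !(rec$consequence %in% silent_classes) & !is.na(rec$gene)
  qrec <- rec[qualifying, , drop = FALSE]
  genes <- sort(unique(qrec$gene))
  missing_genes <- setdiff(genes, names(gene_lengths))
  if (length(missing_genes)) {
    stop_lum("gene(s) absent from gene_lengths: ",
             paste(utils::head(missing_genes, 10), collapse = ", "))
  }
  if (!length(genes)) {
    out <- data.frame(gene = character(), k = integer(), p_value = numeric(),
                      q_value = numeric(), flagged = logical())
    class(out) <- c("significance_result", "data.frame")
    return(out)
  }
  n_i <- if (background == "nonsilent") {
    table(factor(qrec$sample_id, levels = samples))
  } else {
    table(factor(rec$sample_id, levels = samples))
  }
  n_i <- stats::setNames(as.integer(n_i), samples)
  p_value <- numeric(length(genes))
  k <- integer(length(genes))
  for (j in seq_along(genes)) {
    g <- genes[[j]]
    L <- gene_lengths[[g]]
    in_gene <- qrec$gene == g
    if (statistic == "patients") {
      k[[j]] <- length(unique(qrec$sample_id[in_gene]))
      probs <- per_patient_hit_prob(n_i, L, territory_bp)
      p_value[[j]] <- poisson_binomial_tail(probs, k[[j]])
    } else {
      k[[j]] <- sum(in_gene)
      p_value[[j]] <- stats::pbinom(k[[j]] - 1, sum(n_i), L / territory_bp,
                                    lower.tail = FALSE)
    }
  }
  q_value <- bh_fdr(p_value)
  out <- data.frame(gene = genes, k = k, p_value = p_value,
                    q_value = q_value, flagged = q_value < q_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("significance_result", "data.frame")
  out
}
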