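#' Synthetic cohort parameters
#'
#' Parameter bundle for the seeded synthetic-data generator. The defaults
#' emulate the study conditions of an 8-sample early-onset luminal breast
#' cancer exome cohort: per-tumor SNV loads in 19-74, a C>T-dominated
#' substitution spectrum (fraction 0.39), sparse cross-sample recurrence
#' (five variants shared by two samples, one by three) and a 62 Mbp exome
#' territory.
#'
#' @param n_samples Number of tumor samples (default 8).
#' @param load_range Integer pair: per-sample SNV loads are drawn uniformly
#'   from this range (default `c(19, 74)`). Ignored when `n_private` is set.
#' @param n_private Optional exact number of private (single-sample)
#'   variants, split across samples at random; used to construct cohorts with
#'   a prescribed recurrence structure.
#' @param ct_fraction Fraction of substitutions in the C>T class (default
#'   0.39). The other five classes share the remainder in fixed proportions.
#' @param class_probs Optional explicit 6-vector of substitution-class
#'   probabilities (named as [substitution_classes()], summing to 1 within
#'   1e-9); overrides `ct_fraction`.
#' @param n_shared_pairs Variants shared by exactly two samples (default 5).
#' @param n_shared_triples Variants shared by exactly three samples
#'   (default 1).
#' @param spike_genes Optional named integer vector: gene symbol to the
#'   number of samples that each receive one extra missense SNV in that gene
#'   (signal injection for the significance test).
#' @param consequence_probs Optional named probability vector over
#'   [consequence_levels()]; the default mirrors an exome call set dominated
#'   by intergenic, UTR, missense, intron and synonymous classes.
#' @param gene_lengths Optional named numeric vector of gene coding lengths
#'   in bp; genic variants pick their gene proportionally to length. By
#'   default a pool of 1000 equal-length genes (`GENE0001`...) is used.
#' @param evidence_priors Optional list of categorical priors for
#'   [simulate_evidence()]; see [default_evidence_priors()].
#' @param territory_mbp Exome territory in Mbp (default 62).
#' @param seed Integer seed; every draw of the generator flows from it.
#' @return A `simulation_params` object (list).
#' @export
simulation_params <- function(n_samples = 8,
                              load_range = c(19, 74),
                              n_private = NULL,
                              ct_fraction = 0.39,
                              class_probs = NULL,
                              n_shared_pairs = 5,
                              n_shared_triples = 1,
                              spike_genes = NULL,
                              consequence_probs = NULL,
                              gene_lengths = NULL,
                              evidence_priors = NULL,
                              territory_mbp = 62,
                              seed = 1) {
  if (is.null(class_probs)) {
    # residual classes keep the proportions of a luminal breast spectrum
    rest <- c("C>A" = 0.12, "C>G" = 0.10, "T>A" = 0.08, "T>C" = 0.21, "T>G" = 0.10)
    class_probs <- c(rest * (1 - ct_fraction) / sum(rest), "C>T" = ct_fraction)
    class_probs <- class_probs[substitution_classes()]
  }
  if (!all(substitution_classes() %in% names(class_probs)) ||
      abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0)) {
    stop_lum("class_probs must be a probability vector over the 6 substitution classes")
  }
  if (is.null(consequence_probs)) {
    consequence_probs <- c(missense = 0.22, nonsense = 0.02, frameshift = 0,
                           synonymous = 0.10, splice = 0.02, utr3 = 0.15,
                           utr5 = 0.04, intron = 0.18, intergenic = 0.25,
                           other = 0.02)
  }
  if (!all(names(consequence_probs) %in% consequence_levels()) ||
      abs(sum(consequence_probs) - 1) > 1e-9 || any(consequence_probs < 0)) {
    stop_lum("consequence_probs must be a probability vector over consequence_levels()")
  }
  if (n_samples < 1) stop_lum("n_samples must be >= 1")
  if (n_shared_pairs > 0 && n_samples < 2) {
    stop_lum("shared pairs require at least 2 samples")
  }
  if (n_shared_triples > 0 && n_samples < 3) {
    stop_lum("shared triples require at least 3 samples")
  }
  if (is.null(gene_lengths)) {
    gene_lengths <- stats::setNames(rep(1500, 1000),
                                    sprintf("GENE%04d", seq_len(1000)))
  }
  structure(list(
    n_samples = n_samples, load_range = load_range, n_private = n_private,
    ct_fraction = ct_fraction, class_probs = class_probs[substitution_classes()],
    n_shared_pairs = n_shared_pairs, n_shared_triples = n_shared_triples,
    spike_genes = spike_genes,
    consequence_probs = consequence_probs,
    gene_lengths = gene_lengths,
    evidence_priors = evidence_priors %||% default_evidence_priors(),
    territory_mbp = territory_mbp, seed = as.integer(seed)
  ), class = "simulation_params")
}

# draw m substitution events: class, flanks, strand representation
draw_substitutions <- function(m, class_probs) {
  cls <- sample(substitution_classes(), m, replace = TRUE, prob = class_probs)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  f5 <- sample(DNA_BASES, m, replace = TRUE)
  f3 <- sample(DNA_BASES, m, replace = TRUE)
  # half the events are reported on the purine strand, as in real call sets
  flip <- stats::runif(m) < 0.5
  data.frame(
    ref = ifelse(flip, revcomp_base(ref), ref),
    alt = ifelse(flip, revcomp_base(alt), alt),
    flank5 = ifelse(flip, revcomp_base(f3), f5),
    flank3 = ifelse(flip, revcomp_base(f5), f3),
    stringsAsFactors = FALSE
  )
}

draw_positions <- function(m) {
  chrom <- as.character(sample(1:22, m, replace = TRUE))
  pos <- sample.int(2e8L, m, replace = TRUE) + 1L
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {          # collisions are ~never, but keep keys unique
    dup <- duplicated(key)
    pos[dup] <- sample.int(2e8L, sum(dup), replace = TRUE) + 1L
    key <- paste(chrom, pos)
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

draw_attributes <- function(m, params) {
  consequence <- sample(names(params$consequence_probs), m, replace = TRUE,
                        prob = params$consequence_probs)
  gene <- rep(NA_character_, m)
  genic <- consequence != "intergenic"
  # spiked genes are reserved for their injected observations
  pool <- params$gene_lengths[setdiff(names(params$gene_lengths),
                                      names(params$spike_genes))]
  if (any(genic)) {
    gene[genic] <- sample(names(pool), sum(genic), replace = TRUE, prob = pool)
  }
  data.frame(gene = gene, consequence = consequence, stringsAsFactors = FALSE)
}

#' Simulate a somatic SNV cohort
#'
#' Generates a seeded synthetic cohort with the configured load, spectrum,
#' recurrence and (optionally) spiked-gene structure. The same
#' `simulation_params` always yield byte-identical output.
#'
#' @param params A [simulation_params] object.
#' @return A [cohort_variants] object.
#' @examples
#' p <- simulation_params(seed = 7)
#' cohort <- simulate_cohort(p)
#' collapse_recurrence(cohort)
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_samples
  samples <- sprintf("S%02d", seq_len(n))

  # sharing structure: each shared variant is observed in a random subset
  share_sizes <- c(rep(2L, params$n_shared_pairs), rep(3L, params$n_shared_triples))
  share_members <- lapply(share_sizes, function(k) sample(samples, k))
  shared_per_sample <- table(factor(unlist(share_members), levels = samples))

  if (!is.null(params$n_private)) {
    private_per_sample <- stats::rmultinom(1, params$n_private, rep(1, n))[, 1]
  } else {
    loads <- sample(params$load_range[1]:params$load_range[2], n, replace = TRUE)
    private_per_sample <- loads - as.integer(shared_per_sample)
    if (any(private_per_sample < 0)) {
      stop_lum("infeasible sharing structure: a sample's shared variants exceed its load")
    }
  }

  n_shared <- length(share_sizes)
  n_priv <- sum(private_per_sample)
  m <- n_shared + n_priv
  sub <- draw_substitutions(m, params$class_probs)
  loc <- draw_positions(m)
  att <- draw_attributes(m, params)
  body <- cbind(loc, sub, att)

  rows <- list()
  if (n_shared) {
    for (j in seq_len(n_shared)) {
      for (s in share_members[[j]]) {
        rows[[length(rows) + 1]] <- cbind(data.frame(sample_id = s), body[j, ])
      }
    }
  }
  if (n_priv) {
    owner <- rep(samples, private_per_sample)
    priv <- cbind(data.frame(sample_id = owner, stringsAsFactors = FALSE),
                  body[n_shared + seq_len(n_priv), ])
    rows[[length(rows) + 1]] <- priv
  }
  records <- do.call(rbind, rows)

  # spiked genes: one extra missense observation per chosen sample
  if (!is.null(params$spike_genes)) {
    for (g in names(params$spike_genes)) {
      k <- params$spike_genes[[g]]
      if (k > n) stop_lum("spike for ", g, " exceeds the number of samples")
      hit <- sample(samples, k)
      spike <- cbind(
        data.frame(sample_id = hit, stringsAsFactors = FALSE),
        draw_positions(k),
        draw_substitutions(k, params$class_probs),
        data.frame(gene = g, consequence = "missense", stringsAsFactors = FALSE)
      )
      records <- rbind(records, spike)
    }
  }

  records <- records[order(records$sample_id, records$chrom, records$pos), ]
  records$protein_change <- NA_character_
  rownames(records) <- NULL
  cohort_variants(records[, variant_table_columns()],
                  territory_mbp = params$territory_mbp)
}

#' Default priors for synthetic evidence tables
#'
#' Categorical priors loosely matched to the marginal composition of the
#' packaged reference evidence table: rare CGC membership, CCGD ranks
#' dominated by D/absent, about half of FATHMM calls pathogenic, and so on.
#' Any element can be overridden via `simulation_params(evidence_priors=)`.
#'
#' @return Named list of prior parameters.
#' @export
default_evidence_priors <- function() {
  list(
    p_cgc = 0.12,
    rank_probs = c(none = 0.45, A = 0.05, B = 0.12, C = 0.12, D = 0.19, NR = 0.07),
    p_domain = 0.40,
    p_same_bc = 0.08,
    p_same_other = 0.12,
    freq_shape = c(0.3, 30),          # beta: mostly sub-1% gene frequencies
    p_freq_missing = 0.05,
    fathmm_probs = c(pathogenic = 0.50, neutral = 0.45, missing = 0.05),
    polyphen_probs = c(deleterious = 0.40, benign = 0.35, missing = 0.25),
    sift_probs = c(not_tolerated = 0.35, tolerated = 0.50, missing = 0.15),
    gvgd_probs = c(C0 = 0.02, C15 = 0.05, C25 = 0.05, C35 = 0.10, C45 = 0.08,
                   C55 = 0.10, C65 = 0.45, missing = 0.15),
    p_chasm_missing = 0.10,
    p_km = 0.25,
    p_literature = 0.40
  )
}

#' Simulate an evidence table for a cohort
#'
#' Draws one evidence record per missense/nonsense variant of the cohort,
#' with every annotation field sampled independently from the configured
#' priors. Deterministic for a fixed `params$seed`.
#'
#' @param cohort A [cohort_variants] object (non-empty).
#' @param params A [simulation_params] object (its `evidence_priors` and
#'   `seed` are used).
#' @return An `evidence_table` data frame.
#' @export
simulate_evidence <- function(cohort, params = simulation_params()) {
  stopifnot(inherits(cohort, "cohort_variants"),
            inherits(params, "simulation_params"))
  rec <- cohort$records
  rec <- rec[rec$consequence %in% c("missense", "nonsense") & !is.na(rec$gene), ,
             drop = FALSE]
  if (!nrow(rec)) stop_lum("cohort has no missense/nonsense variants to annotate")
  pr <- params$evidence_priors
  set.seed(params$seed + 1L)   # own stream, still derived from the run seed
  m <- nrow(rec)
  draw_cat <- function(probs) sample(names(probs), m, replace = TRUE, prob = probs)
  with_missing <- function(x) ifelse(x == "missing", NA_character_, x)
  ranks <- draw_cat(pr$rank_probs)
  ranks[ranks == "none"] <- ""
  freq <- function() {
    f <- stats::rbeta(m, pr$freq_shape[1], pr$freq_shape[2])
    ifelse(stats::runif(m) < pr$p_freq_missing, NA_real_, f)
  }
  chasm <- stats::runif(m)
  chasm[stats::runif(m) < pr$p_chasm_missing] <- NA_real_
  ev <- data.frame(
    sample_id = rec$sample_id,
    gene = rec$gene,
    variant_label = NA_character_,
    cgc = stats::runif(m) < pr$p_cgc,
    ccgd_ranks = ranks,
    functional_domain = stats::runif(m) < pr$p_domain,
    same_variant_bc = stats::runif(m) < pr$p_same_bc,
    same_variant_other = stats::runif(m) < pr$p_same_other,
    freq_all_cancers = freq(),
    freq_bc = freq(),
    consequence = rec$consequence,
    fathmm = with_missing(draw_cat(pr$fathmm_probs)),
    polyphen = with_missing(draw_cat(pr$polyphen_probs)),
    sift = with_missing(draw_cat(pr$sift_probs)),
    gvgd_class = with_missing(draw_cat(pr$gvgd_probs)),
    chasm_p = chasm,
    km_significant = stats::runif(m) < pr$p_km,
    literature_support = stats::runif(m) < pr$p_literature,
    stringsAsFactors = FALSE
  )
  validate_evidence(ev)
  class(ev) <- c("evidence_table", "data.frame")
  ev
}
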