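#' Driver-scoring rubric configuration
#'
#' Weights and thresholds of the two evidence-based driver-candidate scoring
#' systems. The defaults reproduce the published rubric:
#'
#' * Cancer Gene Census membership: 3 points;
#' * best CCGD rank: A 2, B 1.5, C 1, D 0.5, NR (not ranked) 0;
#' * named functional/Pfam domain at the site: 0.5;
#' * gene SNV frequency >= 1% in all cancers and/or in breast cancer: 0.5
#'   each;
#' * identical variant previously reported (breast or other cancers): a
#'   single 0.5;
#' * truncating consequence (nonsense/frameshift): 1.5;
#' * consensus pathogenicity vote over the function-impact algorithms —
#'   System 1 polls FATHMM, PolyPhen, SIFT, Align-GVGD and CHASM and awards 1
#'   point for >= 3 pathogenic calls; System 2 polls FATHMM, PolyPhen, SIFT
#'   and CHASM and awards 0.5 for exactly 2 calls, 1 for 3 or 4.
#'
#' An Align-GVGD call counts as pathogenic from class `gvgd_min_class`
#' (default C35) upward; a CHASM call counts when `chasm_p < chasm_alpha`
#' (default 0.05). Missing calls never vote, and the vote thresholds are
#' absolute, not fractions of available calls. Kaplan-Meier survival and
#' literature columns are modelled as optional weighted criteria with default
#' weight 0.
#'
#' Labels: `CGC` when the gene is in the Cancer Gene Census, otherwise `PD`
#' (probable driver) for scores `>= 3.5`, `pd` (possible driver) for
#' `>= 2`, else `Neutral`.
#'
#' @param w_cgc,w_domain,w_freq_all,w_freq_bc,w_same_variant,w_truncating
#'   Criterion weights (points).
#' @param rank_weights Named numeric vector of CCGD rank weights.
#' @param freq_threshold Gene-frequency threshold for the frequency bonuses
#'   (fraction; default 0.01).
#' @param gvgd_min_class Minimum Align-GVGD class counting as a pathogenic
#'   vote.
#' @param chasm_alpha CHASM p-value threshold for a pathogenic vote.
#' @param w_km,w_literature Optional weights for the survival-association and
#'   literature columns (default 0).
#' @param threshold_pd,threshold_PD Score thresholds for the `pd` and `PD`
#'   labels (`threshold_PD > threshold_pd`).
#' @return A `rubric_config` object (list).
#' @export
rubric_config <- function(w_cgc = 3,
                          rank_weights = c(A = 2, B = 1.5, C = 1, D = 0.5, NR = 0),
                          w_domain = 0.5,
                          w_freq_all = 0.5,
                          w_freq_bc = 0.5,
                          freq_threshold = 0.01,
                          w_same_variant = 0.5,
                          w_truncating = 1.5,
                          gvgd_min_class = "C35",
                          chasm_alpha = 0.05,
                          w_km = 0,
                          w_literature = 0,
                          threshold_pd = 2,
                          threshold_PD = 3.5) {
  weights <- c(w_cgc, rank_weights, w_domain, w_freq_all, w_freq_bc,
               w_same_variant, w_truncating, w_km, w_literature)
  if (any(weights < 0)) stop_lum("all rubric weights must be >= 0")
  if (!all(CCGD_RANKS %in% names(rank_weights))) {
    stop_lum("rank_weights must name all of ", paste(CCGD_RANKS, collapse = ", "))
  }
  if (!(gvgd_min_class %in% GVGD_CLASSES)) {
    stop_lum("gvgd_min_class must be one of ", paste(GVGD_CLASSES, collapse = ", "))
  }
  if (threshold_PD <= threshold_pd) {
    stop_lum("threshold_PD must exceed threshold_pd")
  }
  structure(list(
    w_cgc = w_cgc, rank_weights = rank_weights, w_domain = w_domain,
    w_freq_all = w_freq_all, w_freq_bc = w_freq_bc,
    freq_threshold = freq_threshold, w_same_variant = w_same_variant,
    w_truncating = w_truncating, gvgd_min_class = gvgd_min_class,
    chasm_alpha = chasm_alpha, w_km = w_km, w_literature = w_literature,
    threshold_pd = threshold_pd, threshold_PD = threshold_PD
  ), class = "rubric_config")
}

#' Count pathogenic votes among the function-impact algorithms
#'
#' Polls the algorithms of the chosen scoring system: FATHMM (pathogenic),
#' PolyPhen (deleterious), SIFT (not tolerated), Align-GVGD (class at or
#' above `cfg$gvgd_min_class`; System 1 only) and CHASM
#' (`chasm_p < cfg$chasm_alpha`). Missing calls contribute no vote.
#'
#' @param evidence An `evidence_table` (any number of rows).
#' @param cfg A [rubric_config].
#' @param system Scoring system, 1 (five algorithms) or 2 (four; no
#'   Align-GVGD).
#' @return Integer vector of pathogenic vote counts, one per row.
#' @export
algorithm_votes <- function(evidence, cfg = rubric_config(), system = 1) {
  stopifnot(is.data.frame(evidence))
  system <- match.arg(as.character(system), c("1", "2"))
  nz <- function(x) !is.na(x) & x   # NA never votes
  v_fathmm <- nz(evidence$fathmm == "pathogenic")
  v_polyphen <- nz(evidence$polyphen == "deleterious")
  v_sift <- nz(evidence$sift == "not_tolerated")
  v_chasm <- nz(evidence$chasm_p < cfg$chasm_alpha)
  votes <- v_fathmm + v_polyphen + v_sift + v_chasm
  if (system == "1") {
    gvgd_rank <- match(evidence$gvgd_class, GVGD_CLASSES)
    min_rank <- match(cfg$gvgd_min_class, GVGD_CLASSES)
    votes <- votes + nz(gvgd_rank >= min_rank)
  }
  as.integer(votes)
}

# vote bonus per system: System 1 awards 1 point at >=3 votes; System 2
# awards 0.5 at exactly 2 and 1 at >=3
vote_points <- function(votes, system) {
  if (system == 1) {
    ifelse(votes >= 3, 1, 0)
  } else {
    ifelse(votes >= 3, 1, ifelse(votes == 2, 0.5, 0))
  }
}

score_evidence <- function(evidence, cfg, system) {
  n <- nrow(evidence)
  ge <- function(x, thr) !is.na(x) & x >= thr   # missing frequency earns nothing
  tru <- function(x) !is.na(x) & x
  best <- best_ccgd_rank(evidence$ccgd_ranks)
  itemized <- data.frame(
    pts_cgc = ifelse(tru(evidence$cgc), cfg$w_cgc, 0),
    pts_ccgd = ifelse(is.na(best), 0, unname(cfg$rank_weights[best])),
    pts_domain = ifelse(tru(evidence$functional_domain), cfg$w_domain, 0),
    pts_freq_all = ifelse(ge(evidence$freq_all_cancers, cfg$freq_threshold),
                          cfg$w_freq_all, 0),
    pts_freq_bc = ifelse(ge(evidence$freq_bc, cfg$freq_threshold),
                         cfg$w_freq_bc, 0),
    pts_same_variant = ifelse(tru(evidence$same_variant_bc) |
                                tru(evidence$same_variant_other),
                              cfg$w_same_variant, 0),
    pts_truncating = ifelse(evidence$consequence %in% truncating_consequences(),
                            cfg$w_truncating, 0),
    pts_votes = vote_points(algorithm_votes(evidence, cfg, system), system),
    pts_km = ifelse(tru(evidence$km_significant), cfg$w_km, 0),
    pts_literature = ifelse(tru(evidence$literature_support), cfg$w_literature, 0)
  )
  score <- rowSums(itemized)
  out <- data.frame(gene = evidence$gene, sample_id = evidence$sample_id,
                    variant_label = evidence$variant_label,
                    stringsAsFactors = FALSE)
  out <- cbind(out, itemized)
  out$score <- score
  out$label <- classify_driver(score, tru(evidence$cgc), cfg)
  if (n) rownames(out) <- NULL
  class(out) <- c("driver_scores", "data.frame")
  out
}

#' Score evidence under System 1 (in-house cohort rubric)
#'
#' Applies the full five-algorithm rubric (see [rubric_config()]) to each
#' evidence row and returns the itemized points, the total score and the
#' label.
#'
#' @param evidence An `evidence_table` (one or more rows); see
#'   [evidence_record()].
#' @param cfg A [rubric_config].
#' @return A `driver_scores` data frame with per-criterion point columns
#'   (`pts_*`), `score` and `label`.
#' @examples
#' e <- evidence_record("CACNA1E", functional_domain = TRUE,
#'                      same_variant_other = TRUE,
#'                      freq_all_cancers = 0.024, freq_bc = 0.0255,
#'                      fathmm = "pathogenic", polyphen = "deleterious",
#'                      sift = "not_tolerated", gvgd_class = "C65",
#'                      chasm_p = 0.0523)
#' score_system1(e)$score   # 3
#' @export
score_system1 <- function(evidence, cfg = rubric_config()) {
  score_evidence(evidence, cfg, system = 1)
}

#' Score evidence under System 2 (literature/COSMIC cohort rubric)
#'
#' Identical to [score_system1()] except that the consensus vote polls four
#' algorithms (FATHMM, PolyPhen, SIFT, CHASM; no Align-GVGD) and is two-tier:
#' 0.5 points for exactly 2 pathogenic calls, 1 point for 3 or 4.
#'
#' @inheritParams score_system1
#' @return A `driver_scores` data frame.
#' @export
score_system2 <- function(evidence, cfg = rubric_config()) {
  score_evidence(evidence, cfg, system = 2)
}

#' Classify a driver score
#'
#' `CGC` when the gene is a Cancer Gene Census member (regardless of score);
#' otherwise `PD` for scores at or above `cfg$threshold_PD` (default 3.5,
#' the candidate-driver cut-off), `pd` at or above `cfg$threshold_pd`
#' (default 2, possible driver), else `Neutral`.
#'
#' @param score Non-negative numeric score(s).
#' @param cgc Logical CGC membership flag(s).
#' @param cfg A [rubric_config].
#' @return Character vector of labels among `CGC`, `PD`, `pd`, `Neutral`.
#' @export
classify_driver <- function(score, cgc, cfg = rubric_config()) {
  if (any(is.na(score)) || any(score < 0)) stop_lum("scores must be >= 0")
  ifelse(cgc, "CGC",
         ifelse(score >= cfg$threshold_PD, "PD",
                ifelse(score >= cfg$threshold_pd, "pd", "Neutral")))
}

#' Score a full evidence table and summarise labels
#'
#' Scores every evidence row under the chosen system and counts distinct
#' genes per label (a gene appearing with several labels is counted under
#' each label it attains).
#'
#' @param evidence An `evidence_table`.
#' @param system 1 or 2 (see [score_system1()], [score_system2()]).
#' @param cfg A [rubric_config].
#' @return A list with `scores` (a `driver_scores` data frame) and
#'   `label_counts` (named integer vector over `CGC`, `PD`, `pd`, `Neutral`:
#'   distinct genes per label).
#' @export
score_table <- function(evidence, system = 1, cfg = rubric_config()) {
  scores <- score_evidence(evidence, cfg, system = as.integer(system))
  pairs <- unique(scores[, c("gene", "label")])
  counts <- table(factor(pairs$label, levels = c("CGC", "PD", "pd", "Neutral")))
  list(scores = scores,
       label_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' @export
print.driver_scores <- function(x, ...) {
  cat(sprintf("driver_scores: %d variant(s)\n", nrow(x)))
  show <- intersect(c("gene", "sample_id", "variant_label", "score", "label"),
                    names(x))
  print.data.frame(utils::head(x[, show, drop = FALSE], 20))
  if (nrow(x) > 20) cat("...\n")
  invisible(x)
}
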