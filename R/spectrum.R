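#' The 96 trinucleotide mutation categories
#'
#' Canonical (COSMIC-style) ordering of the 96 strand-normalized trinucleotide
#' mutation types: 6 pyrimidine substitution classes (`C>A`, `C>G`, `C>T`,
#' `T>A`, `T>C`, `T>G`) crossed with the 4 possible 5' and 3' neighbour bases.
#' Each category is written as mutated triplet `>` product triplet, e.g.
#' `"ACG>ATG"`.
#'
#' @return Character vector of length 96.
#' @export
trinucleotide_contexts <- function() {
  classes <- substitution_classes()
  out <- character(0)
  for (cl in classes) {
    ref <- substr(cl, 1, 1)
    alt <- substr(cl, 3, 3)
    for (f5 in DNA_BASES) {
      for (f3 in DNA_BASES) {
        out <- c(out, paste0(f5, ref, f3, ">", f5, alt, f3))
      }
    }
  }
  out
}

#' The 6 pyrimidine substitution classes
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Strand-normalize a substitution to its pyrimidine class and context
#'
#' Maps an SNV with its immediate reference flanks to one of the 6 pyrimidine
#' substitution classes and one of the 96 trinucleotide categories. When the
#' reference base is a purine (A/G) the whole trinucleotide and the alternate
#' base are reverse-complemented, so the reported class always has a
#' pyrimidine (C/T) reference. Vectorized over all four arguments.
#'
#' @param ref,alt Reference and alternate base (A/C/G/T, `ref != alt`).
#' @param flank5,flank3 Reference bases immediately 5' and 3' of the site, on
#'   the reference strand.
#' @return Data frame with columns `class` (e.g. `"C>T"`) and `context`
#'   (e.g. `"ACG>ATG"`).
#' @examples
#' normalize_substitution("C", "T", "A", "G")   # C>T, ACG>ATG
#' normalize_substitution("G", "A", "C", "G")   # same, via the other strand
#' @export
normalize_substitution <- function(ref, alt, flank5, flank3) {
  n <- length(ref)
  if (length(alt) != n || length(flank5) != n || length(flank3) != n) {
    stop_lum("ref, alt, flank5, flank3 must have equal length")
  }
  for (v in list(ref, alt, flank5, flank3)) {
    if (any(!(v %in% DNA_BASES))) stop_lum("bases must be A, C, G or T")
  }
  if (any(ref == alt)) stop_lum("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, revcomp_base(ref), ref)
  a <- ifelse(flip, revcomp_base(alt), alt)
  f5 <- ifelse(flip, revcomp_base(flank3), flank5)
  f3 <- ifelse(flip, revcomp_base(flank5), flank3)
  data.frame(class = paste0(r, ">", a),
             context = paste0(f5, r, f3, ">", f5, a, f3),
             stringsAsFactors = FALSE)
}

#' Build the 6-class / 96-context mutation spectrum of a cohort
#'
#' Counts every SNV observation of the cohort into its pyrimidine substitution
#' class and trinucleotide category. Zero-count categories are retained, so
#' the context vector always has exactly 96 entries and both count vectors sum
#' to the number of input SNVs.
#'
#' @param cohort A [cohort_variants] object with flanks present on every
#'   record.
#' @return A `spectrum_counts` object: list with named integer vectors
#'   `class_counts` (length 6) and `context_counts` (length 96) and the total
#'   `n`.
#' @export
build_spectrum <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_variants"))
  rec <- cohort$records
  bad <- which(is.na(rec$flank5) | is.na(rec$flank3))
  if (length(bad)) {
    stop_lum("missing flanking base(s) at record(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
  }
  if (nrow(rec)) {
    norm <- normalize_substitution(rec$ref, rec$alt, rec$flank5, rec$flank3)
    class_counts <- table(factor(norm$class, levels = substitution_classes()))
    context_counts <- table(factor(norm$context, levels = trinucleotide_contexts()))
  } else {
    class_counts <- table(factor(character(), levels = substitution_classes()))
    context_counts <- table(factor(character(), levels = trinucleotide_contexts()))
  }
  structure(list(
    class_counts = stats::setNames(as.integer(class_counts), names(class_counts)),
    context_counts = stats::setNames(as.integer(context_counts), names(context_counts)),
    n = nrow(rec)
  ), class = "spectrum_counts")
}

#' @export
print.spectrum_counts <- function(x, ...) {
  cat(sprintf("spectrum_counts: %d SNV(s)\n", x$n))
  print(x$class_counts)
  invisible(x)
}

#' @export
as.data.frame.spectrum_counts <- function(x, ...) {
  ctx <- names(x$context_counts)
  data.frame(context = ctx,
             class = paste0(substr(ctx, 2, 2), ">", substr(ctx, 6, 6)),
             count = unname(x$context_counts),
             stringsAsFactors = FALSE)
}

#' Plot a trinucleotide spectrum
#'
#' Simple 96-bar barplot of the context counts, grouped and coloured by
#' substitution class.
#'
#' @param x A `spectrum_counts` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.spectrum_counts <- function(x, ...) {
  cls <- rep(substitution_classes(), each = 16)
  cols <- c("C>A" = "#2EBAED", "C>G" = "#000000", "C>T" = "#DE1C14",
            "T>A" = "#D4D2D2", "T>C" = "#ADCC54", "T>G" = "#F0D0CE")
  graphics::barplot(x$context_counts, col = cols[cls], border = NA,
                    names.arg = substr(names(x$context_counts), 1, 3),
                    las = 2, cex.names = 0.45,
                    ylab = "SNV count", ...)
}

#' Mutation rate per megabase
#'
#' @param n_snvs Non-negative SNV count.
#' @param territory_mbp Surveyed territory in Mbp (> 0).
#' @return `n_snvs / territory_mbp`, SNVs per Mbp.
#' @export
mutation_rate <- function(n_snvs, territory_mbp) {
  if (any(territory_mbp <= 0)) stop_lum("territory_mbp must be positive")
  if (any(n_snvs < 0)) stop_lum("n_snvs must be non-negative")
  n_snvs / territory_mbp
}

#' Per-sample mutation load and rate statistics
#'
#' Tabulates the SNV load of every sample and summarises the cohort: median
#' (midpoint of the middle two for an even number of samples), minimum,
#' maximum, mean, and the mean per-sample total and non-silent mutation rates
#' per Mbp.
#'
#' @param cohort A [cohort_variants] object with at least one sample.
#' @param silent_classes Consequence classes excluded from the non-silent
#'   rate; defaults to [silent_consequences()].
#' @return A `load_stats` object: list with `per_sample_counts` (named
#'   integer), `median`, `minimum`, `maximum`, `mean`, `total_rate_per_mbp`
#'   and `nonsilent_rate_per_mbp`.
#' @export
load_stats <- function(cohort, silent_classes = silent_consequences()) {
  stopifnot(inherits(cohort, "cohort_variants"))
  rec <- cohort$records
  if (!nrow(rec)) stop_lum("empty cohort: no SNV observations")
  samples <- sort(unique(rec$sample_id))
  counts <- table(factor(rec$sample_id, levels = samples))
  nonsilent <- table(factor(
    rec$sample_id[!(rec$consequence %in% silent_classes)], levels = samples))
  counts <- stats::setNames(as.integer(counts), samples)
  nonsilent <- stats::setNames(as.integer(nonsilent), samples)
  structure(list(
    per_sample_counts = counts,
    median = stats::median(counts),
    minimum = min(counts),
    maximum = max(counts),
    mean = mean(counts),
    total_rate_per_mbp = mean(mutation_rate(counts, cohort$territory_mbp)),
    nonsilent_rate_per_mbp = mean(mutation_rate(nonsilent, cohort$territory_mbp))
  ), class = "load_stats")
}

#' @export
print.load_stats <- function(x, ...) {
  cat(sprintf(
    "load_stats: %d sample(s); median %.1f (range %d-%d, mean %.1f); %.2f/Mbp total, %.2f/Mbp non-silent\n",
    length(x$per_sample_counts), x$median, x$minimum, x$maximum, x$mean,
    x$total_rate_per_mbp, x$nonsilent_rate_per_mbp))
  invisible(x)
}

#' Collapse cross-sample recurrence of identical variants
#'
#' Variant identity is positional: `(chrom, pos, ref, alt)`. Repeated
#' observations of the same substitution are counted once per sample, and the
#' multiplicity histogram records, for each number of samples `k`, how many
#' unique variants were shared by exactly `k` samples. The identities
#' `total = sum(k * hist[k])` and `unique = sum(hist[k])` always hold.
#'
#' @param cohort A [cohort_variants] object.
#' @return A `recurrence_summary` object: list with `total_observations`,
#'   `unique_variants` and the named integer vector `multiplicity_histogram`.
#' @export
collapse_recurrence <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_variants"))
  rec <- cohort$records
  if (!nrow(rec)) {
    return(structure(list(total_observations = 0L, unique_variants = 0L,
                          multiplicity_histogram = stats::setNames(integer(0), character(0))),
                     class = "recurrence_summary"))
  }
  key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":")
  obs <- unique(data.frame(key = key, sample_id = rec$sample_id,
                           stringsAsFactors = FALSE))
  mult <- table(obs$key)
  hist <- table(mult)
  structure(list(
    total_observations = nrow(obs),
    unique_variants = length(mult),
    multiplicity_histogram = stats::setNames(as.integer(hist), names(hist))
  ), class = "recurrence_summary")
}

#' @export
print.recurrence_summary <- function(x, ...) {
  cat(sprintf("recurrence_summary: %d observation(s), %d unique variant(s)\n",
              x$total_observations, x$unique_variants))
  if (length(x$multiplicity_histogram)) {
    cat("shared by k samples (k: variants): ",
        paste(sprintf("%s: %d", names(x$multiplicity_histogram),
                      x$multiplicity_histogram), collapse = ", "), "\n")
  }
  invisible(x)
}
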