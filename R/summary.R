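#' DNA-repair pathway cross-tabulation
#'
#' Projects per-sample mutated gene lists onto a DNA-repair pathway map:
#' only genes present in the map appear, each row flags the mechanisms the
#' gene participates in, and the summary reports how many samples of the
#' cohort carry at least one repair-gene SNV. The cohort denominator is an
#' explicit parameter because affected-sample tables list only the affected
#' samples.
#'
#' @param gene_lists Named list: sample id to character vector of mutated
#'   gene symbols.
#' @param pmap A [pathway_map].
#' @param cohort_size Total number of tumors in the cohort (at least the
#'   number of listed samples).
#' @return A `repair_crosstab` object: list with `rows` (data frame
#'   `sample_id`, `gene`, one logical column per mechanism),
#'   `n_samples_affected`, `fraction_affected` and the half-up rounded
#'   `percent_affected` (1 decimal).
#' @export
repair_crosstab <- function(gene_lists, pmap, cohort_size) {
  stopifnot(inherits(pmap, "pathway_map"))
  if (length(gene_lists) && is.null(names(gene_lists))) {
    stop_lum("gene_lists must be named by sample id")
  }
  rows <- list()
  for (s in names(gene_lists)) {
    genes <- unique(toupper(gene_lists[[s]]))
    hit <- genes[gene_key(genes) %in% gene_key(names(pmap$mapping))]
    for (g in hit) {
      mech <- pmap$mapping[[names(pmap$mapping)[
        match(gene_key(g), gene_key(names(pmap$mapping)))]]]
      flags <- stats::setNames(as.list(REPAIR_MECHANISMS %in% mech),
                               REPAIR_MECHANISMS)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(sample_id = s, gene = g, stringsAsFactors = FALSE),
              as.data.frame(flags))
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(sample_id = character(), gene = character()),
          as.data.frame(stats::setNames(rep(list(logical()), 7), REPAIR_MECHANISMS)))
  n_affected <- length(unique(rows$sample_id))
  if (cohort_size < n_affected) {
    stop_lum("cohort_size (", cohort_size, ") is smaller than the number of affected samples (",
             n_affected, ")")
  }
  fraction <- if (cohort_size > 0) n_affected / cohort_size else 0
  structure(list(rows = rows,
                 n_samples_affected = n_affected,
                 fraction_affected = fraction,
                 percent_affected = percent(fraction, 1)),
            class = "repair_crosstab")
}

#' @export
print.repair_crosstab <- function(x, ...) {
  cat(sprintf("repair_crosstab: %d sample(s) affected (%.1f%%), %d gene row(s)\n",
              x$n_samples_affected, 100 * x$fraction_affected, nrow(x$rows)))
  invisible(x)
}

#' Truncating-variant summary against curated gene sets
#'
#' Per sample, collects the genes carrying truncating (nonsense/frameshift)
#' SNVs and flags their membership in the CCGD rank-A, CCGD rank-B and
#' positive-regulation-of-gene-expression sets, then reports how many samples
#' of the cohort carry at least one truncating variant in an
#' expression-regulation gene.
#'
#' @param cohort A [cohort_variants] object.
#' @param ccgd_a,ccgd_b,expr_set [gene_set]s.
#' @param cohort_size Cohort denominator.
#' @return A `truncating_summary` object: list with `rows` (data frame
#'   `sample_id`, `truncating_genes`, `in_ccgd_a`, `in_ccgd_b`,
#'   `in_expr_set`, semicolon-separated), `n_samples_with_expr_gene`,
#'   `fraction` and `percent` (half-up, 0 decimals, as printed).
#' @export
truncating_summary <- function(cohort, ccgd_a, ccgd_b, expr_set, cohort_size) {
  stopifnot(inherits(cohort, "cohort_variants"))
  rec <- cohort$records
  trunc <- rec[rec$consequence %in% truncating_consequences() & !is.na(rec$gene), ,
               drop = FALSE]
  rows <- lapply(split(trunc$gene, trunc$sample_id), function(genes) {
    genes <- unique(toupper(genes))
    list(genes = genes,
         a = genes[in_gene_set(genes, ccgd_a)],
         b = genes[in_gene_set(genes, ccgd_b)],
         e = genes[in_gene_set(genes, expr_set)])
  })
  tab <- data.frame(
    sample_id = names(rows),
    truncating_genes = vapply(rows, function(r) paste(r$genes, collapse = ";"), ""),
    in_ccgd_a = vapply(rows, function(r) paste(r$a, collapse = ";"), ""),
    in_ccgd_b = vapply(rows, function(r) paste(r$b, collapse = ";"), ""),
    in_expr_set = vapply(rows, function(r) paste(r$e, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  n_expr <- sum(vapply(rows, function(r) length(r$e) > 0, logical(1)))
  fraction <- if (cohort_size > 0) n_expr / cohort_size else 0
  structure(list(rows = tab,
                 n_samples_with_expr_gene = n_expr,
                 fraction = fraction,
                 percent = percent(fraction, 0)),
            class = "truncating_summary")
}

#' @export
print.truncating_summary <- function(x, ...) {
  cat(sprintf(
    "truncating_summary: %d sample(s) with a truncated expression-regulation gene (%.1f%%)\n",
    x$n_samples_with_expr_gene, 100 * x$fraction))
  invisible(x)
}

#' Per-gene mutation frequency ranking
#'
#' Counts, for every gene, the number of samples whose gene list contains it,
#' and ranks genes by descending count (ties broken alphabetically).
#'
#' @param gene_lists Named list: sample id to character vector of gene
#'   symbols.
#' @param cohort_size Cohort denominator (> 0).
#' @return Data frame `gene`, `count`, `fraction`, `percent` (half-up,
#'   1 decimal).
#' @export
gene_frequency <- function(gene_lists, cohort_size) {
  if (cohort_size <= 0) stop_lum("cohort_size must be positive")
  genes <- unlist(lapply(gene_lists, function(g) unique(toupper(g))),
                  use.names = FALSE)
  if (!length(genes)) {
    return(data.frame(gene = character(), count = integer(),
                      fraction = numeric(), percent = numeric()))
  }
  counts <- sort(table(genes), decreasing = TRUE)
  out <- data.frame(gene = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  out$fraction <- out$count / cohort_size
  out$percent <- percent(out$fraction, 1)
  rownames(out) <- NULL
  out
}

#' Driver-candidate count per tumor
#'
#' Counts, per sample, the mutated genes belonging to the union of the
#' Cancer Gene Census and CCGD rank-A/rank-B sets, and summarises the counts
#' as in [load_stats()].
#'
#' @param gene_lists Named list: sample id to mutated gene symbols.
#' @param cgc,ccgd_a,ccgd_b [gene_set]s.
#' @return List with `per_sample_counts` (named integer), `median`,
#'   `minimum`, `maximum`.
#' @export
driver_count_per_tumor <- function(gene_lists, cgc, ccgd_a, ccgd_b) {
  counts <- vapply(gene_lists, function(genes) {
    genes <- unique(toupper(genes))
    sum(in_gene_set(genes, cgc) | in_gene_set(genes, ccgd_a) |
          in_gene_set(genes, ccgd_b))
  }, integer(1))
  list(per_sample_counts = counts,
       median = if (length(counts)) stats::median(counts) else NA_real_,
       minimum = if (length(counts)) min(counts) else NA_integer_,
       maximum = if (length(counts)) max(counts) else NA_integer_)
}

#' Read a packaged repair cross-tab table
#'
#' Reads the affected-sample repair table fixture (columns `sample_id`,
#' `gene`, `mechanisms` comma-separated, `n_variants_sample`).
#'
#' @param path Path to the TSV (defaults to the packaged fixture).
#' @return Data frame.
#' @export
read_repair_table <- function(path = lum_fixture("table2_repair.tsv")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "gene", "mechanisms") %in% names(tab))) {
    stop_lum("repair table must have columns sample_id, gene, mechanisms")
  }
  if ("n_variants_sample" %in% names(tab)) {
    tab$n_variants_sample <- as.integer(tab$n_variants_sample)
  }
  tab
}

#' Read a packaged truncating-variant table
#'
#' Reads the truncating-variant fixture (per-sample gene lists and their
#' CCGD-A/CCGD-B/expression-regulation subsets). Where the source table
#' prints only a count instead of a full gene list, the fixture stores the
#' count in the matching `n_*` column and leaves the list column empty; the
#' returned `n_*` columns are always filled (list length or stored count).
#'
#' @param path Path to the TSV (defaults to the packaged fixture).
#' @return Data frame with list columns (`;`-separated) and integer `n_*`
#'   columns.
#' @export
read_truncating_table <- function(path = lum_fixture("table3_truncating.tsv")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "truncating_genes", "ccgd_a", "ccgd_b", "expr_genes")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_lum("truncating table lacks column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  n_from_list <- function(x) {
    vapply(strsplit(x, ";"), function(g) sum(trimws(g) != ""), integer(1))
  }
  fill_n <- function(list_col, n_col) {
    n <- if (n_col %in% names(tab)) suppressWarnings(as.integer(tab[[n_col]]))
         else rep(NA_integer_, nrow(tab))
    ifelse(is.na(n), n_from_list(tab[[list_col]]), n)
  }
  tab$n_truncating <- fill_n("truncating_genes", "n_truncating")
  tab$n_ccgd_a <- fill_n("ccgd_a", "n_ccgd_a")
  tab$n_ccgd_b <- fill_n("ccgd_b", "n_ccgd_b")
  tab$n_expr <- fill_n("expr_genes", "n_expr")
  if ("n_variants_sample" %in% names(tab)) {
    tab$n_variants_sample <- as.integer(tab$n_variants_sample)
  }
  tab
}

#' Summarise a truncating-variant table over a cohort denominator
#'
#' Fixture-level counterpart of [truncating_summary()]: counts the samples
#' with at least one truncating variant in an expression-regulation gene.
#'
#' @param tab Data frame from [read_truncating_table()].
#' @param cohort_size Cohort denominator.
#' @return List with `n_samples_with_expr_gene`, `fraction` and `percent`
#'   (half-up, 0 decimals).
#' @export
summarize_truncating_table <- function(tab, cohort_size) {
  n_expr <- sum(tab$n_expr > 0)
  fraction <- n_expr / cohort_size
  list(n_samples_with_expr_gene = n_expr, fraction = fraction,
       percent = percent(fraction, 0))
}

#' Per-sample gene lists from a sample/gene table
#'
#' @param tab Data frame with columns `sample_id` and `gene`.
#' @return Named list: sample id to character vector of genes.
#' @export
gene_lists_from_table <- function(tab) {
  lapply(split(tab$gene, tab$sample_id), unique)
}

#' Per-sample mutated gene lists of a cohort
#'
#' @param cohort A [cohort_variants] object.
#' @param consequences Optional consequence filter (default: all classes).
#' @return Named list: sample id to character vector of mutated genes.
#' @export
cohort_gene_lists <- function(cohort, consequences = consequence_levels()) {
  stopifnot(inherits(cohort, "cohort_variants"))
  rec <- cohort$records
  rec <- rec[rec$consequence %in% consequences & !is.na(rec$gene), , drop = FALSE]
  lapply(split(rec$gene, rec$sample_id), unique)
}
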