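#' Path to a packaged reference fixture
#'
#' The package ships its reference tables as plain-text fixtures under
#' `extdata/`:
#'
#' * `table1_evidence.tsv` — the confirmed gene-variant evidence table of the
#'   8-sample exome cohort, including the published totals and labels
#'   (`printed_total`, `printed_label` columns);
#' * `table2_repair.tsv` — affected samples with SNVs in DNA-repair genes;
#' * `table3_truncating.tsv` — per-sample truncating (nonsense/frameshift)
#'   gene lists and their CCGD-A/CCGD-B/expression-regulation subsets;
#' * `pathway_map.tsv` — gene to DNA-repair mechanism map;
#' * `geneset_cgc_table1.txt`, `geneset_ccgd_a.txt`, `geneset_ccgd_b.txt`,
#'   `geneset_expr_regulation.txt` — the curated gene sets.
#'
#' @param name Fixture file name.
#' @return Absolute path to the installed fixture.
#' @export
lum_fixture <- function(name) {
  path <- system.file("extdata", name, package = "lumdriver")
  if (path == "") stop_lum("no packaged fixture named '", name, "'")
  path
}

lum_fixture_files <- function() {
  c("table1_evidence.tsv", "table2_repair.tsv", "table3_truncating.tsv",
    "pathway_map.tsv", "geneset_cgc_table1.txt", "geneset_ccgd_a.txt",
    "geneset_ccgd_b.txt", "geneset_expr_regulation.txt")
}

#' Load the packaged reference evidence table
#'
#' @return An `evidence_table` with the extra columns `printed_total`
#'   (numeric) and `printed_label`.
#' @export
load_table1_evidence <- function() {
  ev <- read_evidence_table(lum_fixture("table1_evidence.tsv"))
  ev$printed_total <- as.numeric(ev$printed_total)
  ev
}

#' Load a packaged gene set
#'
#' @param which One of `"cgc_table1"` (Cancer Gene Census members of the
#'   in-house cohort), `"ccgd_a"`, `"ccgd_b"` (CCGD rank A/B genes of the
#'   truncating-variant table) or `"expr_regulation"` (positive regulation of
#'   gene expression).
#' @return A [gene_set].
#' @export
load_packaged_gene_set <- function(which = c("cgc_table1", "ccgd_a", "ccgd_b",
                                             "expr_regulation")) {
  which <- match.arg(which)
  load_gene_set(lum_fixture(paste0("geneset_", which, ".txt")), name = which)
}

#' Load the packaged DNA-repair pathway map
#'
#' @return A [pathway_map] covering the repair genes of the reference
#'   cross-tab.
#' @export
load_packaged_pathway_map <- function() {
  load_pathway_map(lum_fixture("pathway_map.tsv"))
}

#' Materialise all packaged fixtures into a directory
#'
#' Copies every packaged fixture file into `out_dir` (created if needed).
#' Deterministic: re-running produces byte-identical files.
#'
#' @param out_dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- vapply(lum_fixture_files(), function(f) {
    dest <- file.path(out_dir, f)
    file.copy(lum_fixture(f), dest, overwrite = TRUE)
    dest
  }, character(1))
  invisible(unname(written))
}
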