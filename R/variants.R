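#' Construct a cohort of somatic SNV observations
#'
#' A `cohort_variants` object holds one row per somatic SNV observed in one
#' sample, together with the exome territory surveyed. Coordinates are 1-based
#' and fully closed (VCF convention); the immediate 5' and 3' reference bases
#' are carried as explicit columns so no reference genome is needed
#' downstream.
#'
#' @param records Data frame with columns `sample_id`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `flank5`, `flank3`, `consequence` and optionally
#'   `protein_change`. `gene` may be `NA` for non-genic (e.g. intergenic)
#'   observations.
#' @param territory_mbp Exome territory surveyed, in megabase pairs
#'   (default 62, a typical expanded exome capture).
#' @return An object of class `cohort_variants`: a list with elements
#'   `records` (validated data frame) and `territory_mbp`.
#' @examples
#' v <- data.frame(sample_id = "S1", gene = "PIK3CA", chrom = "3",
#'                 pos = 178936091, ref = "G", alt = "A",
#'                 flank5 = "A", flank3 = "T", consequence = "missense")
#' cohort_variants(v)
#' @export
cohort_variants <- function(records, territory_mbp = 62) {
  if (!is.data.frame(records)) stop_lum("`records` must be a data frame")
  if (!is.numeric(territory_mbp) || length(territory_mbp) != 1 ||
      !is.finite(territory_mbp) || territory_mbp <= 0) {
    stop_lum("`territory_mbp` must be a single positive number")
  }
  required <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                "flank5", "flank3", "consequence")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_lum("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"protein_change" %in% names(records)) {
    records$protein_change <- rep(NA_character_, nrow(records))
  }
  records$pos <- as.integer(records$pos)
  for (col in c("sample_id", "gene", "chrom", "ref", "alt", "flank5",
                "flank3", "consequence", "protein_change")) {
    records[[col]] <- as.character(records[[col]])
  }
  if (nrow(records)) {
    validate_variant_rows(records)
  }
  rownames(records) <- NULL
  structure(list(records = records, territory_mbp = territory_mbp),
            class = "cohort_variants")
}

# row-level invariant checks; reports offending row numbers
validate_variant_rows <- function(records) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop_lum("invalid variant row(s) [", paste(utils::head(rows, 10), collapse = ", "),
               if (length(rows) > 10) ", ..." else "", "]: ", what)
    }
  }
  base_cols <- c("ref", "alt", "flank5", "flank3")
  for (col in base_cols) {
    bad(!(records[[col]] %in% DNA_BASES),
        paste0("column '", col, "' must be a single base A/C/G/T"))
  }
  bad(records$ref == records$alt, "ref and alt must differ")
  bad(is.na(records$pos) | records$pos < 2,
      "pos must be an integer >= 2 (5' flank must exist)")
  bad(!(records$consequence %in% consequence_levels()),
      paste0("consequence must be one of: ",
             paste(consequence_levels(), collapse = ", ")))
  bad(is.na(records$sample_id) | records$sample_id == "",
      "sample_id must be non-empty")
  invisible(records)
}

#' @export
print.cohort_variants <- function(x, ...) {
  n <- nrow(x$records)
  s <- length(unique(x$records$sample_id))
  cat(sprintf("cohort_variants: %d SNV observation(s) in %d sample(s), territory %.1f Mbp\n",
              n, s, x$territory_mbp))
  invisible(x)
}

#' @export
as.data.frame.cohort_variants <- function(x, ...) x$records

variant_table_columns <- function() {
  c("sample_id", "gene", "chrom", "pos", "ref", "alt",
    "flank5", "flank3", "consequence", "protein_change")
}

#' Read a per-sample somatic SNV table
#'
#' Reads a tab-separated variant table (columns `sample_id`, `gene`, `chrom`,
#' `pos`, `ref`, `alt`, `flank5`, `flank3`, `consequence`, optional
#' `protein_change`; header required, any column order) and validates every
#' row. Empty strings and `"-"` in `gene`/`protein_change` are treated as
#' missing.
#'
#' @param path Path to the TSV file.
#' @param territory_mbp Exome territory in Mbp (default 62).
#' @return A [cohort_variants] object.
#' @seealso [write_variant_table()], [read_variant_vcf()]
#' @export
read_variant_table <- function(path, territory_mbp = 62) {
  if (!file.exists(path)) stop_lum("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  required <- setdiff(variant_table_columns(), "protein_change")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_lum("variant table ", path, " lacks mandatory column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(c("gene", "protein_change"), names(tab))) {
    tab[[col]][tab[[col]] %in% c("", "-", "ND")] <- NA_character_
  }
  cohort_variants(tab, territory_mbp = territory_mbp)
}

#' Write a cohort variant table
#'
#' Inverse of [read_variant_table()]: writing then reading any valid cohort is
#' an identity on the records.
#'
#' @param cohort A [cohort_variants] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_variants"))
  out <- cohort$records[, variant_table_columns()]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read somatic SNVs from a minimal VCF
#'
#' Optional VCF 4.x reader for SNV-only call sets. Only biallelic
#' single-nucleotide records are accepted. The sample name is taken from the
#' genotype column header (or `sample_id` argument), the consequence class
#' from the INFO key `CSQCLS` and the trinucleotide flanks from the INFO key
#' `TRICTX` (three reference bases centred on the site). Requires the vcfR
#' package.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param territory_mbp Exome territory in Mbp.
#' @param sample_id Optional sample name override.
#' @return A [cohort_variants] object.
#' @export
read_variant_vcf <- function(path, territory_mbp = 62, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_lum("read_variant_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  # v@fix is always a character matrix, also for single-record files
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop_lum("no records in VCF: ", path)
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  if (any(!snv)) {
    stop_lum("non-SNV or multi-allelic record(s) at VCF row(s): ",
             paste(utils::head(which(!snv), 10), collapse = ", "))
  }
  info_field <- function(key) {
    vcfR::extract.info(v, element = key)
  }
  csq <- info_field("CSQCLS")
  ctx <- info_field("TRICTX")
  gene <- info_field("GENE")
  if (all(is.na(csq))) stop_lum("VCF lacks INFO key CSQCLS (consequence class)")
  if (all(is.na(ctx))) stop_lum("VCF lacks INFO key TRICTX (trinucleotide context)")
  if (is.null(sample_id)) {
    samples <- colnames(v@gt)
    samples <- setdiff(samples, "FORMAT")
    sample_id <- if (length(samples) >= 1) samples[[1]] else "sample1"
  }
  records <- data.frame(
    sample_id = sample_id,
    gene = ifelse(is.na(gene) | gene == ".", NA_character_, gene),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    flank5 = substr(ctx, 1, 1),
    flank3 = substr(ctx, 3, 3),
    consequence = tolower(csq),
    stringsAsFactors = FALSE
  )
  mid <- substr(ctx, 2, 2)
  if (any(mid != records$ref)) {
    stop_lum("TRICTX centre base disagrees with REF at VCF row(s): ",
             paste(utils::head(which(mid != records$ref), 10), collapse = ", "))
  }
  cohort_variants(records, territory_mbp = territory_mbp)
}
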