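#' Construct a single evidence record
#'
#' One evidence record summarises, for one gene variant in one sample, all the
#' annotation used by the driver-candidate scoring rubrics: Cancer Gene Census
#' (CGC) membership, Candidate Cancer Gene Database (CCGD) ranks from mouse
#' insertional-mutagenesis screens, presence of a named functional/Pfam domain
#' at the mutated site, prior reports of the same variant, gene-level SNV
#' frequencies, the consequence class, and the calls of five function-impact
#' algorithms (FATHMM, PolyPhen, SIFT, Align-GVGD, CHASM).
#'
#' Missing evidence is an explicit state (`NA` / `"missing"`), never silently
#' zero; the rubric decides its weight (missing algorithm calls simply
#' contribute no pathogenicity vote).
#'
#' @param gene Gene symbol. Aliases such as `"RBM16/SCAF8"` are kept verbatim;
#'   [gene_key()] extracts the pre-slash token for set lookups.
#' @param sample_id Sample identifier.
#' @param variant_label Free-text variant label (e.g. `"p.E545K c.1633G>A"`).
#' @param cgc Logical: gene listed in the Cancer Gene Census.
#' @param ccgd_ranks Character vector (or comma-separated string) of CCGD
#'   ranks among `A`, `B`, `C`, `D`, `NR`; the best rank is scored.
#' @param functional_domain Logical: variant falls in a named functional/Pfam
#'   domain (repeat, low-complexity, disorder and coiled-coil tracks do not
#'   count).
#' @param same_variant_bc,same_variant_other Logical: identical variant
#'   previously reported in breast cancer / in other cancers.
#' @param freq_all_cancers,freq_bc Gene-level SNV frequency (fraction in
#'   `[0, 1]`) across all cancers / in breast cancer; `NA` if unknown.
#' @param consequence Consequence class (see [consequence_levels()]).
#' @param fathmm `"pathogenic"`, `"neutral"` or `NA`.
#' @param polyphen `"deleterious"`, `"benign"` or `NA`.
#' @param sift `"not_tolerated"`, `"tolerated"` or `NA`.
#' @param gvgd_class Align-GVGD class `C0`..`C65`, or `NA`.
#' @param chasm_p CHASM p-value in `[0, 1]`, or `NA`.
#' @param km_significant Optional logical: gene expression associated with
#'   overall survival (Kaplan-Meier).
#' @param literature_support Optional logical: cancer involvement supported by
#'   the literature.
#' @return A one-row `evidence_table` data frame.
#' @examples
#' evidence_record("PIK3CA", cgc = TRUE, ccgd_ranks = "B",
#'                 functional_domain = TRUE, same_variant_bc = TRUE,
#'                 freq_all_cancers = 0.0956, freq_bc = 0.2664,
#'                 fathmm = "pathogenic", polyphen = "deleterious",
#'                 sift = "tolerated", gvgd_class = "C55", chasm_p = 2e-4)
#' @export
evidence_record <- function(gene, sample_id = NA_character_,
                            variant_label = NA_character_,
                            cgc = FALSE, ccgd_ranks = character(),
                            functional_domain = FALSE,
                            same_variant_bc = FALSE,
                            same_variant_other = FALSE,
                            freq_all_cancers = NA_real_, freq_bc = NA_real_,
                            consequence = "missense",
                            fathmm = NA_character_, polyphen = NA_character_,
                            sift = NA_character_, gvgd_class = NA_character_,
                            chasm_p = NA_real_,
                            km_significant = NA, literature_support = NA) {
  ranks <- parse_ccgd_ranks(ccgd_ranks)
  rec <- data.frame(
    gene = as.character(gene), sample_id = as.character(sample_id),
    variant_label = as.character(variant_label),
    cgc = as.logical(cgc),
    ccgd_ranks = ranks,
    functional_domain = as.logical(functional_domain),
    same_variant_bc = as.logical(same_variant_bc),
    same_variant_other = as.logical(same_variant_other),
    freq_all_cancers = as.numeric(freq_all_cancers),
    freq_bc = as.numeric(freq_bc),
    consequence = as.character(consequence),
    fathmm = as.character(fathmm), polyphen = as.character(polyphen),
    sift = as.character(sift), gvgd_class = as.character(gvgd_class),
    chasm_p = as.numeric(chasm_p),
    km_significant = as.logical(km_significant),
    literature_support = as.logical(literature_support),
    stringsAsFactors = FALSE
  )
  validate_evidence(rec)
  class(rec) <- c("evidence_table", "data.frame")
  rec
}

CCGD_RANKS <- c("A", "B", "C", "D", "NR")

# normalize a vector/comma-separated string of ranks to a canonical
# comma-separated string ("" = no rank)
parse_ccgd_ranks <- function(x) {
  if (length(x) == 0) return("")
  x <- unlist(strsplit(paste(x, collapse = ","), ","))
  x <- toupper(trimws(x))
  x <- x[x != "" & x != "-" & x != "ND" & x != "NONE"]
  if (!length(x)) return("")
  unknown <- setdiff(x, CCGD_RANKS)
  if (length(unknown)) {
    stop_lum("unknown CCGD rank token(s): ", paste(unique(unknown), collapse = ", "))
  }
  paste(unique(x[order(match(x, CCGD_RANKS))]), collapse = ",")
}

# best (highest-scoring) rank of a canonical rank string, NA if none
best_ccgd_rank <- function(ranks) {
  vapply(strsplit(ranks, ","), function(r) {
    r <- r[r %in% CCGD_RANKS]
    if (!length(r)) NA_character_ else CCGD_RANKS[min(match(r, CCGD_RANKS))]
  }, character(1))
}

GVGD_CLASSES <- c("C0", "C15", "C25", "C35", "C45", "C55", "C65")

validate_evidence <- function(ev) {
  check_enum <- function(col, levels) {
    vals <- ev[[col]]
    bad <- !is.na(vals) & !(vals %in% levels)
    if (any(bad)) {
      stop_lum("unknown token(s) in evidence column '", col, "': ",
               paste(unique(vals[bad]), collapse = ", "))
    }
  }
  check_enum("fathmm", c("pathogenic", "neutral"))
  check_enum("polyphen", c("deleterious", "benign"))
  check_enum("sift", c("not_tolerated", "tolerated"))
  check_enum("gvgd_class", GVGD_CLASSES)
  check_enum("consequence", consequence_levels())
  for (col in c("freq_all_cancers", "freq_bc", "chasm_p")) {
    vals <- ev[[col]]
    ok <- is.na(vals) | (vals >= 0 & vals <= 1)
    if (!all(ok)) {
      stop_lum("evidence column '", col, "' must be a fraction in [0, 1] at row(s): ",
               paste(which(!ok), collapse = ", "))
    }
  }
  invisible(ev)
}

#' Canonical evidence-table column names
#'
#' The schema shared by [read_evidence_table()] and [write_evidence_table()].
#'
#' @return Character vector of column names.
#' @export
evidence_columns <- function() {
  c("sample_id", "gene", "variant_label", "cgc", "ccgd_ranks",
    "functional_domain", "same_variant_bc", "same_variant_other",
    "freq_all_cancers", "freq_bc", "consequence", "fathmm", "polyphen",
    "sift", "gvgd_class", "chasm_p", "km_significant", "literature_support")
}

# documented token maps for the TSV representation
MISSING_TOKENS <- c("", "-", "ND", "NA")

map_token <- function(x, map, column) {
  out <- rep(NA_character_, length(x))
  x_trim <- trimws(x)
  miss <- x_trim %in% MISSING_TOKENS
  key <- tolower(x_trim)
  hit <- match(key, tolower(names(map)))
  bad <- !miss & is.na(hit)
  if (any(bad)) {
    stop_lum("unknown token(s) in column '", column, "': ",
             paste(unique(x_trim[bad]), collapse = ", "))
  }
  out[!miss] <- unname(map[hit[!miss]])
  out
}

parse_bool <- function(x, column) {
  tok <- c("yes" = "TRUE", "no" = "FALSE", "true" = "TRUE", "false" = "FALSE")
  as.logical(map_token(x, tok, column))
}

parse_frac <- function(x, column) {
  x_trim <- trimws(x)
  out <- rep(NA_real_, length(x))
  keep <- !(x_trim %in% MISSING_TOKENS)
  val <- suppressWarnings(as.numeric(x_trim[keep]))
  if (any(is.na(val))) {
    stop_lum("non-numeric token(s) in column '", column, "': ",
             paste(unique(x_trim[keep][is.na(val)]), collapse = ", "))
  }
  out[keep] <- val
  out
}

#' Read an evidence table
#'
#' Reads a tab-separated evidence table mirroring the reference evidence
#' schema (see [evidence_record()] for the fields). Parsing is header-keyed,
#' so column order is free. Documented tokens: booleans `Yes`/`No` (or
#' `TRUE`/`FALSE`); FATHMM `Pathogenic`/`Neutral`; PolyPhen
#' `Deleterious`/`Benign`; SIFT `Not Tolerated`/`Tolerated`; GV/GD
#' `C0`..`C65`; CCGD ranks as comma-separated `A`/`B`/`C`/`D`/`NR`.
#' `ND`, `-` and the empty string always denote missing. Columns beyond the
#' schema (for example printed totals) are carried through verbatim.
#'
#' @param path Path to the TSV file.
#' @return An `evidence_table` data frame, one row per gene variant.
#' @seealso [write_evidence_table()], [lum_fixture()]
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop_lum("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  required <- setdiff(evidence_columns(), c("km_significant", "literature_support"))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_lum("evidence table ", path, " lacks mandatory column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  ev <- data.frame(
    sample_id = tab$sample_id,
    gene = toupper(tab$gene),
    variant_label = ifelse(trimws(tab$variant_label) %in% MISSING_TOKENS,
                           NA_character_, tab$variant_label),
    cgc = parse_bool(tab$cgc, "cgc"),
    ccgd_ranks = vapply(tab$ccgd_ranks, parse_ccgd_ranks, character(1),
                        USE.NAMES = FALSE),
    functional_domain = parse_bool(tab$functional_domain, "functional_domain"),
    same_variant_bc = parse_bool(tab$same_variant_bc, "same_variant_bc"),
    same_variant_other = parse_bool(tab$same_variant_other, "same_variant_other"),
    freq_all_cancers = parse_frac(tab$freq_all_cancers, "freq_all_cancers"),
    freq_bc = parse_frac(tab$freq_bc, "freq_bc"),
    consequence = map_token(tab$consequence,
                            stats::setNames(consequence_levels(), consequence_levels()),
                            "consequence"),
    fathmm = map_token(tab$fathmm,
                       c("pathogenic" = "pathogenic", "neutral" = "neutral"),
                       "fathmm"),
    polyphen = map_token(tab$polyphen,
                         c("deleterious" = "deleterious", "benign" = "benign"),
                         "polyphen"),
    sift = map_token(tab$sift,
                     c("not tolerated" = "not_tolerated",
                       "not_tolerated" = "not_tolerated",
                       "tolerated" = "tolerated"),
                     "sift"),
    gvgd_class = map_token(tab$gvgd_class,
                           stats::setNames(GVGD_CLASSES, GVGD_CLASSES),
                           "gvgd_class"),
    chasm_p = parse_frac(tab$chasm_p, "chasm_p"),
    km_significant = if ("km_significant" %in% names(tab))
      parse_bool(tab$km_significant, "km_significant") else rep(NA, n),
    literature_support = if ("literature_support" %in% names(tab))
      parse_bool(tab$literature_support, "literature_support") else rep(NA, n),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(tab), evidence_columns())
  for (col in extra) ev[[col]] <- tab[[col]]
  validate_evidence(ev)
  class(ev) <- c("evidence_table", "data.frame")
  ev
}

#' Write an evidence table
#'
#' Serialises an `evidence_table` with the documented tokens so that
#' write-then-read is an identity.
#'
#' @param evidence An `evidence_table` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  fmt_bool <- function(x) ifelse(is.na(x), "ND", ifelse(x, "Yes", "No"))
  fmt_chr <- function(x, map = NULL) {
    out <- ifelse(is.na(x), "ND", x)
    if (!is.null(map)) {
      hit <- match(out, names(map))
      out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    }
    out
  }
  fmt_num <- function(x) {
    ifelse(is.na(x), "ND",
           vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                        trim = TRUE), character(1)))
  }
  out <- data.frame(
    sample_id = evidence$sample_id,
    gene = evidence$gene,
    variant_label = fmt_chr(evidence$variant_label),
    cgc = fmt_bool(evidence$cgc),
    ccgd_ranks = evidence$ccgd_ranks,
    functional_domain = fmt_bool(evidence$functional_domain),
    same_variant_bc = fmt_bool(evidence$same_variant_bc),
    same_variant_other = fmt_bool(evidence$same_variant_other),
    freq_all_cancers = fmt_num(evidence$freq_all_cancers),
    freq_bc = fmt_num(evidence$freq_bc),
    consequence = evidence$consequence,
    fathmm = fmt_chr(evidence$fathmm,
                     c(pathogenic = "Pathogenic", neutral = "Neutral")),
    polyphen = fmt_chr(evidence$polyphen,
                       c(deleterious = "Deleterious", benign = "Benign")),
    sift = fmt_chr(evidence$sift,
                   c(not_tolerated = "Not Tolerated", tolerated = "Tolerated")),
    gvgd_class = fmt_chr(evidence$gvgd_class),
    chasm_p = fmt_num(evidence$chasm_p),
    km_significant = fmt_bool(evidence$km_significant),
    literature_support = fmt_bool(evidence$literature_support),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  extra <- setdiff(names(evidence), evidence_columns())
  for (col in extra) out[[col]] <- evidence[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "ND")
  invisible(path)
}

#' Canonical gene key
#'
#' Gene symbols are stored verbatim (upper-cased); for alias pairs written
#' `"RBM16/SCAF8"` the pre-slash token is the lookup key.
#'
#' @param gene Character vector of symbols.
#' @return Character vector of upper-cased pre-slash keys.
#' @export
gene_key <- function(gene) {
  toupper(vapply(strsplit(as.character(gene), "/", fixed = TRUE),
                 `[[`, character(1), 1))
}
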