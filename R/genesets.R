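#' Load a gene set
#'
#' Reads a plain-text gene set: one symbol per line, `#` comments allowed.
#' Symbols are upper-cased and de-duplicated (set semantics).
#'
#' @param path Path to the file.
#' @param name Optional set name (defaults to the file name sans extension).
#' @return A `gene_set` object: list with `name` and the character vector
#'   `genes`.
#' @export
load_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop_lum("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- toupper(lines[lines != ""])
  gene_set(unique(genes), name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a gene set
#'
#' @param genes Character vector of symbols (upper-cased, de-duplicated).
#' @param name Set name.
#' @return A `gene_set` object.
#' @export
gene_set <- function(genes, name = "gene_set") {
  genes <- unique(toupper(as.character(genes)))
  if (any(genes == "")) stop_lum("gene symbols must be non-empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d gene(s)\n", x$name, length(x$genes)))
  invisible(x)
}

# membership test keyed on the pre-slash token of alias pairs
in_gene_set <- function(genes, set) {
  stopifnot(inherits(set, "gene_set"))
  gene_key(genes) %in% gene_key(set$genes)
}

#' Load a DNA-repair pathway map
#'
#' Reads a two-column TSV (`gene` TAB comma-separated mechanisms) mapping each
#' gene to the DNA-repair mechanisms it participates in. Mechanism tokens are
#' validated against [repair_mechanisms()].
#'
#' @param path Path to the TSV file.
#' @return A `pathway_map` object: named list mapping gene symbol to a
#'   character vector of mechanisms.
#' @examples
#' pm <- load_packaged_pathway_map()
#' pm$mapping[["TP53"]]   # "DDC"
#' @export
load_pathway_map <- function(path) {
  if (!file.exists(path)) stop_lum("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "mechanisms") %in% names(tab))) {
    stop_lum("pathway map must have columns 'gene' and 'mechanisms'")
  }
  pathway_map(stats::setNames(
    lapply(strsplit(tab$mechanisms, ","), trimws),
    toupper(tab$gene)))
}

#' Construct a pathway map
#'
#' @param mapping Named list: gene symbol to character vector of mechanisms
#'   (subset of [repair_mechanisms()], non-empty).
#' @return A `pathway_map` object.
#' @export
pathway_map <- function(mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop_lum("pathway map entries must be named by gene symbol")
  }
  mapping <- lapply(mapping, function(m) unique(toupper(m)))
  for (g in names(mapping)) {
    m <- mapping[[g]]
    unknown <- setdiff(m, REPAIR_MECHANISMS)
    if (length(unknown)) {
      stop_lum("unknown DNA-repair mechanism token(s) for ", g, ": ",
               paste(unknown, collapse = ", "))
    }
    if (!length(m)) stop_lum("gene ", g, " maps to no mechanism")
  }
  names(mapping) <- toupper(names(mapping))
  structure(list(mapping = mapping), class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("pathway_map: %d gene(s) over mechanisms %s\n",
              length(x$mapping), paste(REPAIR_MECHANISMS, collapse = "/")))
  invisible(x)
}
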