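#' Genetic code and synonymous codon families
#'
#' Builds the codon-to-amino-acid map that defines synonymous families for
#' all downstream statistics. The default is the standard genetic code
#' (61 sense codons, 3 stops). An alternative code may be supplied as a
#' 64-row tab-separated file with columns `codon` and `amino_acid`, using
#' `"*"` for stop codons.
#'
#' @param table `NULL` for the standard code, a path to a 64-row TSV
#'   (codon, amino acid), or a named character vector mapping all 64 codons
#'   to single-letter amino-acid symbols (`"*"` = stop).
#' @return An object of class `genetic_code`: a list with elements
#'   `table` (named character over all 64 codons, alphabetical order),
#'   `codons`, `sense_codons`, `stop_codons`, `amino_acid` (named vector
#'   over sense codons) and `families` (list mapping each amino acid to its
#'   synonymous codon set).
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)        # 61
#' code$families[["L"]]             # the six leucine codons
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    tab <- Biostrings::GENETIC_CODE
  } else if (is.character(table) && length(table) == 1L && is.null(names(table))) {
    df <- utils::read.table(table, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#",
                            col.names = c("codon", "amino_acid"))
    tab <- stats::setNames(toupper(df$amino_acid), toupper(df$codon))
    tab[tab == "STOP"] <- "*"
  } else if (is.character(table) && !is.null(names(table))) {
    tab <- stats::setNames(as.character(table), toupper(names(table)))
  } else {
    stop("`table` must be NULL, a file path, or a named character vector")
  }

  all_codons <- sort(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")), 1L,
                           paste0, collapse = ""))
  if (length(tab) != 64L || !setequal(names(tab), all_codons) ||
      anyDuplicated(names(tab))) {
    stop("genetic code must map each of the 64 codons exactly once")
  }
  tab <- tab[all_codons]

  sense <- all_codons[tab != "*"]
  stops <- all_codons[tab == "*"]
  aa <- tab[sense]
  families <- split(sense, aa)

  structure(
    list(table = tab, codons = all_codons, sense_codons = sense,
         stop_codons = stops, amino_acid = aa, families = families),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons,",
      length(x$families), "amino-acid families\n")
  sizes <- lengths(x$families)
  cat("Family sizes:", paste0(names(sizes), "=", sizes, collapse = " "), "\n")
  invisible(x)
}

#' Write a genetic code to a 64-row TSV
#'
#' @param code A `genetic_code` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_code <- function(code, path) {
  stopifnot(inherits(code, "genetic_code"))
  utils::write.table(
    data.frame(codon = names(code$table), amino_acid = unname(code$table)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
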