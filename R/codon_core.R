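#' Count codons in a validated coding sequence
#'
#' Reads non-overlapping triplets left to right from position 0 of the
#' provided CDS (no ORF search) and tallies each of the 64 codons.
#'
#' @param nucleotides A single CDS string whose length is a multiple of 3
#'   (as produced by [validate_cds()]).
#' @param code A [genetic_code()].
#' @return Named integer vector over all 64 codons, alphabetical order.
#' @examples
#' count_codons("ATGTAA")[c("ATG", "TAA")]
#' @export
count_codons <- function(nucleotides, code = genetic_code()) {
  stopifnot(is.character(nucleotides), length(nucleotides) == 1L)
  len <- nchar(nucleotides)
  if (len %% 3L != 0L)
    stop("CDS length ", len, " is not a multiple of 3; run validate_cds first")
  codons <- substring(nucleotides, seq(1L, len, 3L), seq(3L, len, 3L))
  m <- match(codons, code$codons)
  if (anyNA(m))
    stop("unrecognised codon '", codons[which(is.na(m))[1L]],
         "'; run validate_cds first")
  stats::setNames(tabulate(m, nbins = 64L), code$codons)
}

## counts for many sequences at once: genes x 64 integer matrix
codon_count_matrix <- function(cds, code = genetic_code()) {
  n <- nrow(cds)
  out <- matrix(0L, nrow = n, ncol = 64L,
                dimnames = list(cds$gene_id, code$codons))
  for (i in seq_len(n)) out[i, ] <- count_codons(cds$nucleotides[i], code)
  out
}

#' Per-gene codon usage rates
#'
#' The usage rate of a codon is its count divided by the total count over
#' the included codon set. Stop codons are excluded by default, so rates
#' over the 61 sense codons sum to 1 for any gene with at least one sense
#' codon.
#'
#' @param counts Named integer vector over the 64 codons (from
#'   [count_codons()]), or a genes x 64 matrix of such counts.
#' @param code A [genetic_code()].
#' @param include_stops Include stop codons in the denominator and output.
#' @return Named numeric vector (or matrix) of rates over the included
#'   codons; all-`NA` when the gene has zero included codons.
#' @export
usage_rates <- function(counts, code = genetic_code(), include_stops = FALSE) {
  inc <- if (include_stops) code$codons else code$sense_codons
  if (is.matrix(counts)) {
    sub <- counts[, inc, drop = FALSE]
    tot <- rowSums(sub)
    r <- sub / tot
    r[tot == 0, ] <- NA_real_
    return(r)
  }
  sub <- counts[inc]
  tot <- sum(sub)
  if (tot == 0L) return(stats::setNames(rep(NA_real_, length(inc)), inc))
  sub / tot
}

#' Per-gene within-family selection rates
#'
#' For each sense codon, the selection rate is the codon's count divided by
#' the summed counts of its synonymous family (the set of codons encoding
#' the same amino acid) within the gene — the fraction of that amino
#' acid's usage the codon captures, competing against its alternative
#' synonymous codons. Families with zero observed codons in a gene are
#' `NA` for all their codons (never imputed as 0); single-codon families
#' (Met, Trp) are 1 whenever observed. Stop codons are excluded.
#'
#' @param counts Named integer vector over the 64 codons, or a genes x 64
#'   count matrix.
#' @param code A [genetic_code()].
#' @return Named numeric vector (or genes x 61 matrix) over sense codons;
#'   within every observed family the values sum to 1.
#' @examples
#' sel <- selection_rates(count_codons("ATGCTGCTGCTATAA"))
#' sel[c("ATG", "CTG", "CTA", "TTA")]   # 1, 2/3, 1/3, 0
#' @export
selection_rates <- function(counts, code = genetic_code()) {
  single <- !is.matrix(counts)
  if (single) counts <- matrix(counts, nrow = 1L,
                               dimnames = list(NULL, names(counts)))
  sense <- code$sense_codons
  out <- matrix(NA_real_, nrow = nrow(counts), ncol = length(sense),
                dimnames = list(rownames(counts), sense))
  for (fam in code$families) {
    sub <- counts[, fam, drop = FALSE]
    tot <- rowSums(sub)
    r <- sub / tot
    r[tot == 0, ] <- NA_real_
    out[, fam] <- r
  }
  if (single) out[1L, ] else out
}

#' Assemble the per-gene codon profile matrices
#'
#' Runs [count_codons()], [usage_rates()] and [selection_rates()] over a
#' deduplicated CDS set and returns the three matrices together. `NA`
#' cells mark families (or genes) with no observations and are preserved,
#' never imputed as 0.
#'
#' @param cds Data frame of validated, one-per-gene coding sequences
#'   (`gene_id`, `transcript_id`, `nucleotides`).
#' @param code A [genetic_code()].
#' @return An object of class `codon_profiles`: a list with `gene_id`,
#'   `counts` (genes x 64), `usage` (genes x 61), `selection`
#'   (genes x 61) and `code`.
#' @export
profile_matrix <- function(cds, code = genetic_code()) {
  if (anyDuplicated(cds$gene_id))
    stop("duplicate gene_id in input; run select_representative first")
  counts <- codon_count_matrix(cds, code)
  structure(
    list(gene_id = cds$gene_id, counts = counts,
         usage = usage_rates(counts, code),
         selection = selection_rates(counts, code), code = code),
    class = "codon_profiles")
}

#' @export
print.codon_profiles <- function(x, ...) {
  cat("Codon profiles:", length(x$gene_id), "genes,",
      length(x$code$sense_codons), "sense codons\n")
  cat("Total codons counted:", sum(x$counts), "\n")
  invisible(x)
}

#' Pooled selection rates over a set of genes
#'
#' Sums codon counts over the genes first, then normalises within each
#' synonymous family — the subset-level analogue of [selection_rates()],
#' used for the relative-change matrix of the pipeline output.
#'
#' @param profiles A `codon_profiles` object.
#' @param genes Gene ids to pool; default all genes in the profile.
#' @return Named numeric vector over sense codons.
#' @export
pooled_selection_rates <- function(profiles, genes = NULL) {
  stopifnot(inherits(profiles, "codon_profiles"))
  counts <- profiles$counts
  if (!is.null(genes)) {
    keep <- profiles$gene_id %in% genes
    if (!any(keep)) stop("none of the requested genes are in the profile")
    counts <- counts[keep, , drop = FALSE]
  }
  selection_rates(colSums(counts), profiles$code)
}

#' Write profile matrices to TSV
#'
#' Writes `<prefix>_counts.tsv`, `<prefix>_usage.tsv` and
#' `<prefix>_selection.tsv`, each with a leading `gene_id` column and one
#' column per codon; `NA` encodes missing families.
#'
#' @param profiles A `codon_profiles` object.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_profiles <- function(profiles, prefix) {
  paths <- paste0(prefix, "_", c("counts", "usage", "selection"), ".tsv")
  mats <- list(profiles$counts, profiles$usage, profiles$selection)
  for (i in 1:3) {
    m <- mats[[i]]
    if (!is.integer(m)) {
      ## %.17g keeps the text round-trip bit-exact
      txt <- matrix(ifelse(is.na(m), "NA", sprintf("%.17g", m)),
                    nrow = nrow(m), dimnames = dimnames(m))
    } else txt <- m
    df <- data.frame(gene_id = profiles$gene_id, txt, check.names = FALSE)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(paths)
}

#' Read a per-gene codon matrix written by [write_profiles()]
#'
#' @param path TSV with a `gene_id` column followed by codon columns.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
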