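#' Header dialects for coding-sequence FASTA files
#'
#' Coding-sequence sets such as the GENCODE protein-coding transcript FASTA
#' carry pipe-delimited headers whose fields hold transcript and gene
#' identifiers. A header dialect names the positions of those fields.
#'
#' @param name `"gencode"` for pipe-delimited headers or `"plain"`, where the
#'   whole header token is both gene id and transcript id.
#' @param gene_field 1-based position of the gene id in a pipe-split header
#'   (gencode dialect only). GENCODE puts the transcript id first and the
#'   gene id second, the default here.
#' @param transcript_field 1-based position of the transcript id.
#' @return An object of class `header_dialect`.
#' @examples
#' header_dialect("gencode", gene_field = 2, transcript_field = 1)
#' @export
header_dialect <- function(name = c("gencode", "plain"),
                           gene_field = 2L, transcript_field = 1L) {
  name <- match.arg(name)
  gene_field <- as.integer(gene_field)
  transcript_field <- as.integer(transcript_field)
  if (name == "gencode") {
    if (is.na(gene_field) || is.na(transcript_field) ||
        gene_field < 1L || transcript_field < 1L)
      stop("gencode dialect field indices must be positive integers")
    if (gene_field == transcript_field)
      stop("gencode dialect requires distinct gene and transcript fields")
  }
  structure(list(name = name, gene_field = gene_field,
                 transcript_field = transcript_field),
            class = "header_dialect")
}

#' Read coding sequences from a FASTA file
#'
#' Reads one coding sequence per FASTA record, extracting gene and
#' transcript identifiers from the header according to a dialect.
#' Sequences are normalised to uppercase and `U` is mapped to `T`;
#' any other character is left for [validate_cds()] to judge, so reading
#' is lossless. Record order is preserved.
#'
#' @param path FASTA file path (single-line or wrapped bodies).
#' @param dialect A [header_dialect()]; default GENCODE-style
#'   (`transcript|gene|...`).
#' @return A data frame with columns `gene_id`, `transcript_id`,
#'   `nucleotides` (one row per record).
#' @export
read_cds_fasta <- function(path, dialect = header_dialect("gencode")) {
  stopifnot(inherits(dialect, "header_dialect"))
  if (!file.exists(path)) stop("FASTA file not found: ", path)

  ## locate malformed leading sequence data ourselves so the error can name
  ## the offending line; Biostrings does the actual record parsing
  first <- ""
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  line_no <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    line_no <- line_no + 1L
    if (nzchar(trimws(ln))) { first <- ln; break }
  }
  if (!startsWith(first, ">"))
    stop("malformed FASTA: sequence data before first header at line ",
         line_no, " of ", path)

  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- chartr("uU", "tT", as.character(set))
  seqs <- toupper(seqs)

  if (dialect$name == "plain") {
    ids <- vapply(strsplit(headers, "[ \t]"), `[`, "", 1L)
    gene <- transcript <- ids
  } else {
    fields <- strsplit(vapply(strsplit(headers, "[ \t]"), `[`, "", 1L),
                       "|", fixed = TRUE)
    need <- max(dialect$gene_field, dialect$transcript_field)
    short <- which(lengths(fields) < need)
    if (length(short))
      stop("header lacks the gencode dialect's fields (need ", need,
           " pipe-delimited fields): '", headers[short[1L]], "'")
    gene <- vapply(fields, `[`, "", dialect$gene_field)
    transcript <- vapply(fields, `[`, "", dialect$transcript_field)
  }
  if (any(!nzchar(gene)))
    stop("empty gene id in header: '", headers[which(!nzchar(gene))[1L]], "'")

  data.frame(gene_id = gene, transcript_id = transcript,
             nucleotides = unname(seqs), stringsAsFactors = FALSE)
}

#' Write coding sequences to FASTA
#'
#' Headers are written as `gene_id|transcript_id` so that
#' `read_cds_fasta(..., header_dialect("gencode", gene_field = 1,
#' transcript_field = 2))` round-trips exactly.
#'
#' @param cds Data frame with `gene_id`, `transcript_id`, `nucleotides`.
#' @param path Output path.
#' @param width Line width for wrapped bodies.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, width = 60L) {
  set <- Biostrings::BStringSet(stats::setNames(
    cds$nucleotides, paste(cds$gene_id, cds$transcript_id, sep = "|")))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate coding sequences
#'
#' In `strict` mode a sequence is accepted iff its length is a multiple of
#' three, it is at least one codon long, and it contains only `A`, `C`,
#' `G`, `T`. In `lenient` mode any character outside `A/C/G/T` is treated
#' as `N`, a trailing partial codon is truncated, codons containing `N`
#' are dropped, and the sequence is rejected only if no complete
#' informative codon remains. Rejections are data, not errors: each
#' carries a reason code.
#'
#' @param cds Data frame with `gene_id`, `transcript_id`, `nucleotides`.
#' @param mode `"strict"` or `"lenient"`.
#' @return A list of class `cds_validation` with elements `accepted` (same
#'   columns as the input, nucleotides cleaned in lenient mode) and
#'   `rejected` (`gene_id`, `transcript_id`, `reason`).
#' @export
validate_cds <- function(cds, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  n <- nrow(cds)
  keep <- logical(n)
  reason <- character(n)
  out_nt <- cds$nucleotides

  for (i in seq_len(n)) {
    nt <- cds$nucleotides[i]
    len <- nchar(nt)
    if (mode == "strict") {
      if (grepl("[^ACGTN]", nt)) {
        reason[i] <- "invalid_characters"
      } else if (len < 3L) {
        reason[i] <- "too_short"
      } else if (len %% 3L != 0L) {
        reason[i] <- "length_not_multiple_of_3"
      } else if (grepl("N", nt, fixed = TRUE)) {
        reason[i] <- "contains_N"
      } else {
        keep[i] <- TRUE
      }
    } else {
      nt <- gsub("[^ACGT]", "N", nt)
      len <- nchar(nt) - nchar(nt) %% 3L
      if (len < 3L) {
        reason[i] <- "no_complete_codon"
        next
      }
      codons <- substring(nt, seq(1L, len, 3L), seq(3L, len, 3L))
      codons <- codons[!grepl("N", codons, fixed = TRUE)]
      if (length(codons) == 0L) {
        reason[i] <- "no_informative_codons"
      } else {
        keep[i] <- TRUE
        out_nt[i] <- paste0(codons, collapse = "")
      }
    }
  }

  accepted <- cds[keep, , drop = FALSE]
  accepted$nucleotides <- out_nt[keep]
  rownames(accepted) <- NULL
  rejected <- data.frame(gene_id = cds$gene_id[!keep],
                         transcript_id = cds$transcript_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(accepted = accepted, rejected = rejected, mode = mode),
            class = "cds_validation")
}

#' @export
print.cds_validation <- function(x, ...) {
  cat("CDS validation (", x$mode, "): ", nrow(x$accepted), " accepted, ",
      nrow(x$rejected), " rejected\n", sep = "")
  if (nrow(x$rejected))
    print(table(x$rejected$reason))
  invisible(x)
}

#' Write a rejection report as TSV
#'
#' @param validation A `cds_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(validation, path) {
  utils::write.table(validation$rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep one representative coding sequence per gene
#'
#' Gene-level codon statistics need a single CDS per gene. The `longest`
#' policy keeps the maximal-length CDS, breaking ties by lexicographically
#' smallest transcript id; `first` keeps the first record in input order.
#'
#' @param cds Data frame with `gene_id`, `transcript_id`, `nucleotides`.
#' @param policy `"longest"` or `"first"`.
#' @return Data frame with exactly one row per distinct `gene_id`, ordered
#'   by first appearance of the gene in the input.
#' @export
select_representative <- function(cds, policy = c("longest", "first")) {
  policy <- match.arg(policy)
  if (nrow(cds) == 0L) return(cds)
  idx <- seq_len(nrow(cds))
  groups <- split(idx, factor(cds$gene_id, levels = unique(cds$gene_id)))
  pick <- vapply(groups, function(g) {
    if (policy == "first") return(g[1L])
    len <- nchar(cds$nucleotides[g])
    cand <- g[len == max(len)]
    cand[order(cds$transcript_id[cand])][1L]
  }, integer(1))
  out <- cds[unname(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}
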