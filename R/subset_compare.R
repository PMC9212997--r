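#' Construct a gene subset
#'
#' @param name Subset name (non-empty).
#' @param members Character vector of gene ids; duplicates are dropped.
#' @param provenance One of `"de_up"`, `"de_down"`, `"de_both"`,
#'   `"membership_list"`, `"manual"`.
#' @return An object of class `gene_subset`.
#' @export
gene_subset <- function(name, members,
                        provenance = c("manual", "de_up", "de_down",
                                       "de_both", "membership_list")) {
  provenance <- match.arg(provenance)
  if (!nzchar(name)) stop("subset name must be non-empty")
  structure(list(name = name, members = unique(as.character(members)),
                 provenance = provenance),
            class = "gene_subset")
}

#' @export
print.gene_subset <- function(x, ...) {
  cat("Gene subset '", x$name, "' (", x$provenance, "): ",
      length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Read a differential-expression results table
#'
#' Expects a TSV in the shape of a DESeq2 results export: a gene id
#' column, a log2 fold change and an adjusted p-value. Column names are
#' configurable for other upstream tools.
#'
#' @param path TSV path with a header row.
#' @param columns Named list mapping `gene_id`, `log2fc`, `padj` to the
#'   column names in the file.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return Data frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path,
                          columns = list(gene_id = "gene_id",
                                         log2fc = "log2FoldChange",
                                         padj = "padj"),
                          sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unlist(columns), names(df))
  if (length(missing_cols))
    stop("DE table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  data.frame(gene_id = as.character(df[[columns$gene_id]]),
             log2fc = as.numeric(df[[columns$log2fc]]),
             padj = as.numeric(df[[columns$padj]]),
             stringsAsFactors = FALSE)
}

#' Define a gene subset from differential-expression thresholds
#'
#' A gene is included iff `padj < padj_max` (strict) and its log2 fold
#' change satisfies the direction with `|log2fc| > lfc_min` (strict), the
#' usual `padj < 0.05`, `|log2FC| > 0.7` screen. Genes with missing
#' `padj` (e.g. filtered by independent filtering upstream) are excluded.
#' Boundary rows sitting exactly on a threshold are excluded.
#'
#' @param records Data frame with `gene_id`, `log2fc`, `padj`.
#' @param padj_max Adjusted p-value threshold (strict), default 0.05.
#' @param lfc_min Absolute log2 fold-change threshold (strict), default 0.7.
#' @param direction `"both"` (changed either way), `"up"` or `"down"`.
#' @param name Subset name; defaults to a description of the filter.
#' @return A [gene_subset()] with provenance `de_up`/`de_down`/`de_both`.
#' @export
filter_de <- function(records, padj_max = 0.05, lfc_min = 0.7,
                      direction = c("both", "up", "down"), name = NULL) {
  direction <- match.arg(direction)
  stopifnot(padj_max > 0, lfc_min > 0)
  dup <- unique(records$gene_id[duplicated(records$gene_id)])
  if (length(dup)) {
    for (g in dup) {
      rows <- records[records$gene_id == g, c("log2fc", "padj")]
      if (nrow(unique(rows)) > 1L)
        stop("duplicate gene_id with conflicting records: ", g)
    }
    records <- records[!duplicated(records$gene_id), , drop = FALSE]
  }
  sig <- !is.na(records$padj) & records$padj < padj_max
  lfc <- records$log2fc
  dir_ok <- switch(direction,
                   up   = lfc > lfc_min,
                   down = lfc < -lfc_min,
                   both = abs(lfc) > lfc_min)
  dir_ok[is.na(dir_ok)] <- FALSE
  if (is.null(name))
    name <- sprintf("de_%s_padj%g_lfc%g", direction, padj_max, lfc_min)
  gene_subset(name, records$gene_id[sig & dir_ok],
              provenance = paste0("de_", direction))
}

#' Define a gene subset from a membership file
#'
#' Reads either a GMT file (term, description, then member genes, one term
#' per line) or a two-column TSV (`term`, `gene`) — the usual carriers of
#' Gene Ontology memberships such as GO:0001649 (osteoblast
#' differentiation). A term appearing on several lines contributes the
#' union of its genes.
#'
#' @param path GMT or two-column TSV path.
#' @param term_name Term to extract.
#' @param name Subset name; defaults to `term_name`.
#' @return A [gene_subset()] with provenance `membership_list`.
#' @export
membership_subset <- function(path, term_name, name = term_name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_gmt <- any(lengths(fields) != 2L)
  if (is_gmt) {
    terms <- vapply(fields, `[`, "", 1L)
    sets <- lapply(fields, function(f) f[-(1:2)])
  } else {
    terms <- vapply(fields, `[`, "", 1L)
    sets <- lapply(fields, `[`, 2L)
  }
  hit <- terms == term_name
  if (!any(hit))
    stop("term '", term_name, "' not found in ", path,
         "; available terms: ", paste(unique(terms), collapse = ", "))
  gene_subset(name, unique(unlist(sets[hit])), provenance = "membership_list")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes step-up q-values over the full comparison set: with the m
#' non-missing p-values sorted ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in input order. Missing entries
#' are excluded from m and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (may contain `NA`).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))   # 0.03 0.03 0.03
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  pp <- p[ok]
  o <- order(pp, decreasing = TRUE)        # largest p first
  adj <- pmin(1, cummin(pp[o] * m / (m:1)))
  q[ok[o]] <- adj
  q
}

#' Compare per-codon selection rates of a subset against a background
#'
#' The central analysis: for each sense codon, the per-gene selection
#' rates of the subset are compared with those of the background by a
#' two-tailed two-sample t-test (Student's equal-variance by default,
#' Welch optionally), and the full comparison set of p-values is adjusted
#' by Benjamini-Hochberg step-up. The background defaults to every gene in
#' the profile (the exhaustive list); subset genes are always removed from
#' the background so the two groups are disjoint.
#'
#' A codon is tested only if both groups have at least `min_n` non-missing
#' selection rates; untested codons are reported with `NA` statistics
#' rather than dropped. When both groups have zero variance (e.g. the
#' single-codon Met and Trp families, whose selection rate is constantly 1
#' where observed) the codon is flagged degenerate and reported with
#' `t = 0`, `p = 1` if the group means are equal.
#'
#' @param profiles A `codon_profiles` object from [profile_matrix()], or a
#'   genes x sense-codons selection-rate matrix with gene row names.
#' @param subset A [gene_subset()] or character vector of gene ids.
#' @param background Optional [gene_subset()] or character vector;
#'   default all profile genes.
#' @param min_n Minimum non-missing observations per group per codon.
#' @param var_equal `TRUE` for Student's pooled-variance t-test (default),
#'   `FALSE` for Welch.
#' @param code A [genetic_code()]; taken from `profiles` when available.
#' @return An object of class `codon_comparison` (a data frame with one
#'   row per sense codon): `codon`, `amino_acid`, `mean_subset`,
#'   `mean_background`, `relative_change`
#'   (`(mean_subset - mean_background) / mean_background`), `log2_ratio`,
#'   `t_stat`, `p_value`, `q_value`, `n_subset`, `n_background`,
#'   `tested`, `degenerate`.
#' @export
compare_codon_usage <- function(profiles, subset, background = NULL,
                                min_n = 10L, var_equal = TRUE,
                                code = NULL) {
  if (inherits(profiles, "codon_profiles")) {
    sel <- profiles$selection
    rownames(sel) <- profiles$gene_id
    if (is.null(code)) code <- profiles$code
  } else {
    sel <- as.matrix(profiles)
    if (is.null(code)) code <- genetic_code()
  }
  genes <- rownames(sel)
  sub_name <- if (inherits(subset, "gene_subset")) subset$name else "subset"
  sub_genes <- if (inherits(subset, "gene_subset")) subset$members else
    as.character(subset)
  bg_name <- if (inherits(background, "gene_subset")) background$name else
    "background"
  bg_genes <- if (is.null(background)) genes else
    if (inherits(background, "gene_subset")) background$members else
      as.character(background)

  sub_in <- intersect(sub_genes, genes)
  if (length(sub_in) == 0L)
    stop("subset '", sub_name, "' shares no genes with the profile matrix")
  bg_in <- setdiff(intersect(bg_genes, genes), sub_in)
  if (length(bg_in) == 0L)
    stop("background '", bg_name,
         "' is empty after removing subset genes (groups must be disjoint)")

  x <- sel[sub_in, , drop = FALSE]
  y <- sel[bg_in, , drop = FALSE]
  n1 <- colSums(!is.na(x)); n2 <- colSums(!is.na(y))
  m1 <- colMeans(x, na.rm = TRUE); m2 <- colMeans(y, na.rm = TRUE)
  v1 <- apply(x, 2L, stats::var, na.rm = TRUE)
  v2 <- apply(y, 2L, stats::var, na.rm = TRUE)

  tested <- n1 >= min_n & n2 >= min_n & n1 >= 2L & n2 >= 2L
  degenerate <- tested & v1 == 0 & v2 == 0

  tt <- pp <- rep(NA_real_, ncol(sel))
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt[tested] <- ((m1 - m2) / se)[tested]
  pp[tested] <- (2 * stats::pt(-abs(tt), df))[tested]
  ## zero variance in both groups: equal means -> no evidence (t=0, p=1);
  ## unequal means -> infinitely strong separation (p=0)
  zero_eq <- degenerate & m1 == m2
  zero_ne <- degenerate & m1 != m2
  tt[zero_eq] <- 0; pp[zero_eq] <- 1
  tt[zero_ne] <- sign(m1 - m2)[zero_ne] * Inf; pp[zero_ne] <- 0

  rel <- (m1 - m2) / m2
  rel[tested & m2 == 0] <- NA_real_
  lr <- log2(m1 / m2)
  lr[tested & (m1 == 0 | m2 == 0)] <- NA_real_

  out <- data.frame(
    codon = colnames(sel),
    amino_acid = unname(code$amino_acid[colnames(sel)]),
    mean_subset = ifelse(tested, m1, NA_real_),
    mean_background = ifelse(tested, m2, NA_real_),
    relative_change = ifelse(tested, rel, NA_real_),
    log2_ratio = ifelse(tested, lr, NA_real_),
    t_stat = tt, p_value = pp,
    q_value = bh_adjust(pp),
    n_subset = unname(n1), n_background = unname(n2),
    tested = unname(tested), degenerate = unname(degenerate),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(out,
            class = c("codon_comparison", "data.frame"),
            subset_name = sub_name, background_name = bg_name,
            n_subset_genes = length(sub_in), n_background_genes = length(bg_in),
            min_n = min_n, var_equal = var_equal)
}

#' Count genes in every region of a multi-set overlap
#'
#' Computes exact Venn-region counts for 2-4 named gene sets: each gene in
#' the union is assigned to the unique region given by its pattern of
#' memberships, so the region counts always partition the union. The
#' genes present in all sets are returned as well.
#'
#' @param subsets Named list of 2-4 character vectors, or a list of
#'   [gene_subset()] objects (names taken from the subsets).
#' @return An object of class `overlap_counts`: a list with `regions`
#'   (data frame: one `+`/`-` column per set name, `region` label,
#'   `count`, over all 2^k - 1 non-empty membership patterns),
#'   `intersection` (genes in every set), `set_names` and `union_size`.
#' @examples
#' ov <- overlap_counts(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' ov$regions
#' @export
overlap_counts <- function(subsets) {
  if (all(vapply(subsets, inherits, TRUE, "gene_subset"))) {
    names(subsets) <- vapply(subsets, `[[`, "", "name")
    subsets <- lapply(subsets, `[[`, "members")
  }
  k <- length(subsets)
  if (k < 2L || k > 4L) stop("overlap_counts needs 2 to 4 subsets")
  if (is.null(names(subsets)) || any(!nzchar(names(subsets))))
    stop("all subsets must be named")
  if (anyDuplicated(names(subsets)))
    stop("duplicate subset names: ",
         paste(unique(names(subsets)[duplicated(names(subsets))]),
               collapse = ", "))
  subsets <- lapply(subsets, unique)
  universe <- unique(unlist(subsets))
  member <- vapply(subsets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(subsets)))
  pattern <- apply(member, 1L, function(b) paste(ifelse(b, "+", "-"),
                                                 collapse = ""))
  all_patterns <- apply(as.matrix(expand.grid(rep(list(c("+", "-")), k)))[, k:1,
                                                                          drop = FALSE],
                        1L, paste, collapse = "")
  all_patterns <- sort(setdiff(all_patterns, strrep("-", k)), decreasing = TRUE)
  counts <- stats::setNames(integer(length(all_patterns)), all_patterns)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  flags <- do.call(rbind, strsplit(all_patterns, ""))
  regions <- data.frame(flags, region = all_patterns,
                        count = unname(counts), stringsAsFactors = FALSE)
  names(regions)[seq_len(k)] <- names(subsets)
  inter <- universe[rowSums(member) == k]
  structure(list(regions = regions, intersection = inter,
                 set_names = names(subsets), union_size = length(universe)),
            class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("Overlap of", length(x$set_names), "gene sets (union of",
      x$union_size, "genes)\n")
  print(x$regions, row.names = FALSE)
  cat("In all sets:", length(x$intersection), "genes\n")
  invisible(x)
}

#' Write Venn-region counts as TSV
#'
#' @param overlap An `overlap_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_tsv <- function(overlap, path) {
  utils::write.table(overlap$regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
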