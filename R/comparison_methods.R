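#' @export
print.codon_comparison <- function(x, max_rows = 10L, ...) {
  cat("Per-codon selection-rate comparison\n")
  cat("  subset '", attr(x, "subset_name"), "' (",
      attr(x, "n_subset_genes"), " genes) vs background '",
      attr(x, "background_name"), "' (", attr(x, "n_background_genes"),
      " genes), ", if (attr(x, "var_equal")) "Student" else "Welch",
      " t-test, BH-corrected\n", sep = "")
  tested <- sum(x$tested)
  sig <- sum(x$q_value < 0.05 & !x$degenerate, na.rm = TRUE)
  cat("  ", tested, " codons tested, ", sig, " at q < 0.05\n", sep = "")
  ord <- order(x$q_value)
  show <- utils::head(ord[x$tested[ord] & !x$degenerate[ord]], max_rows)
  if (length(show)) {
    df <- x[show, c("codon", "amino_acid", "mean_subset", "mean_background",
                    "relative_change", "t_stat", "p_value", "q_value")]
    df[-(1:2)] <- lapply(df[-(1:2)], signif, 4)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Summarise a codon comparison
#'
#' @param object A `codon_comparison`.
#' @param alpha Significance level on the BH q-value.
#' @param ... Unused.
#' @return A list with counts of tested/significant codons, the
#'   significant rows, and the largest shifts in each direction.
#' @export
summary.codon_comparison <- function(object, alpha = 0.05, ...) {
  sig <- object[!is.na(object$q_value) & object$q_value < alpha &
                  !object$degenerate, , drop = FALSE]
  sig <- sig[order(sig$q_value), , drop = FALSE]
  out <- list(
    n_codons = nrow(object),
    n_tested = sum(object$tested),
    n_degenerate = sum(object$degenerate),
    n_significant = nrow(sig),
    alpha = alpha,
    significant = sig,
    max_increase = if (any(sig$relative_change > 0, na.rm = TRUE))
      sig[which.max(sig$relative_change), "codon"] else NA_character_,
    max_decrease = if (any(sig$relative_change < 0, na.rm = TRUE))
      sig[which.min(sig$relative_change), "codon"] else NA_character_)
  class(out) <- "summary.codon_comparison"
  out
}

#' @export
print.summary.codon_comparison <- function(x, ...) {
  cat(x$n_tested, "of", x$n_codons, "sense codons tested (",
      x$n_degenerate, "degenerate );", x$n_significant,
      "significant at q <", x$alpha, "\n")
  if (x$n_significant) {
    cat("strongest increase:", x$max_increase,
        " strongest decrease:", x$max_decrease, "\n")
    df <- x$significant[, c("codon", "amino_acid", "relative_change",
                            "q_value")]
    df[-(1:2)] <- lapply(df[-(1:2)], signif, 4)
    print.data.frame(utils::head(df, 15L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.codon_comparison <- function(object, ...) {
  stats::setNames(object$relative_change, object$codon)
}

#' Plot relative codon-usage changes
#'
#' Barplot of per-codon relative selection-rate change, ordered by codon,
#' with codons significant at `alpha` (BH q-value) highlighted.
#'
#' @param x A `codon_comparison`.
#' @param alpha Significance level for highlighting.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.codon_comparison <- function(x, alpha = 0.05, ...) {
  keep <- x$tested & !x$degenerate & !is.na(x$relative_change)
  rel <- x$relative_change[keep]
  sig <- !is.na(x$q_value[keep]) & x$q_value[keep] < alpha
  cols <- ifelse(sig, ifelse(rel > 0, "firebrick", "steelblue"), "grey70")
  mids <- graphics::barplot(rel, names.arg = x$codon[keep], col = cols,
                            border = NA, las = 2, cex.names = 0.55,
                            ylab = "relative change in selection rate", ...)
  graphics::abline(h = 0)
  invisible(mids)
}

#' Write a codon comparison as TSV
#'
#' One row per sense codon with the `codon_comparison` columns; `NA`
#' encodes untested or undefined statistics.
#'
#' @param comparison A `codon_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  utils::write.table(as.data.frame(comparison), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
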