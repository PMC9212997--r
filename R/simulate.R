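#' Draw a codon-weight model from symmetric Dirichlet priors
#'
#' For each amino-acid family, a weight vector over its synonymous codons
#' is drawn from a symmetric Dirichlet with the given concentration, so
#' each family's weights sum to 1 and single-codon families have weight 1.
#' `concentration = 1` gives weights uniform on the simplex; large
#' concentrations approach the uniform codon choice, which
#' `concentration = Inf` yields exactly.
#'
#' @param concentration Positive Dirichlet concentration, or `Inf` for
#'   exactly uniform within-family weights.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param code A [genetic_code()].
#' @return An object of class `codon_weight_model`: a named numeric vector
#'   over the sense codons, with attributes `concentration` and `seed`.
#' @export
simulate_weight_model <- function(concentration = 1, seed = NULL,
                                  code = genetic_code()) {
  stopifnot(concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  w <- stats::setNames(numeric(length(code$sense_codons)), code$sense_codons)
  for (fam in code$families) {
    k <- length(fam)
    if (is.infinite(concentration)) {
      w[fam] <- 1 / k
    } else {
      g <- stats::rgamma(k, shape = concentration)
      if (sum(g) == 0) g <- rep(1, k)   # guard against underflow at tiny shape
      w[fam] <- g / sum(g)
    }
  }
  structure(w, class = "codon_weight_model",
            concentration = concentration, seed = seed)
}

#' @export
print.codon_weight_model <- function(x, ...) {
  cat("Codon weight model (Dirichlet concentration ",
      attr(x, "concentration"), ")\n", sep = "")
  bias <- attr(x, "bias")
  if (!is.null(bias))
    cat("biased: shift ", bias$shift, " on ",
        paste(bias$target_codons, collapse = ", "), "\n", sep = "")
  print(signif(unclass(x), 3))
  invisible(x)
}

#' Inject a multiplicative bias into designated codons
#'
#' Multiplies each target codon's weight by `shift` and renormalises every
#' affected family to sum 1; untargeted families are unchanged. With
#' `shift != 1` every targeted family differs from the base model, so the
#' target codons (and, through renormalisation, their family siblings)
#' carry a known usage shift for recovery tests.
#'
#' @param model A `codon_weight_model`.
#' @param target_codons Sense codons to bias.
#' @param shift Multiplicative factor, > 0.
#' @param code A [genetic_code()].
#' @return A `codon_weight_model` with a `bias` attribute recording
#'   `target_codons` and `shift`.
#' @examples
#' m <- simulate_weight_model(Inf)
#' apply_bias(m, "AAA", 3)[c("AAA", "AAG")]   # 0.75 0.25
#' @export
apply_bias <- function(model, target_codons, shift, code = genetic_code()) {
  if (shift <= 0) stop("shift must be > 0")
  target_codons <- unique(target_codons)
  bad <- setdiff(target_codons, names(model))
  if (length(bad))
    stop("target codons not in model: ", paste(bad, collapse = ", "))
  w <- unclass(model)
  w[target_codons] <- w[target_codons] * shift
  hit <- vapply(code$families, function(fam) any(target_codons %in% fam),
                logical(1))
  for (fam in code$families[hit]) w[fam] <- w[fam] / sum(w[fam])
  structure(w, class = "codon_weight_model",
            concentration = attr(model, "concentration"),
            seed = attr(model, "seed"),
            bias = list(target_codons = target_codons, shift = shift))
}

#' Uniform and mammalian-like amino-acid frequencies
#'
#' @param preset `"uniform"` (default; each of the 20 amino acids at 1/20)
#'   or `"mouse"`, a typical mammalian proteome composition.
#' @param code A [genetic_code()].
#' @return Named numeric vector over the amino acids, summing to 1.
#' @export
amino_acid_freqs <- function(preset = c("uniform", "mouse"),
                             code = genetic_code()) {
  preset <- match.arg(preset)
  aas <- names(code$families)
  if (preset == "uniform")
    return(stats::setNames(rep(1 / length(aas), length(aas)), aas))
  ## approximate mammalian proteome composition (percent, renormalised)
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.8, C = 2.2, Q = 4.7, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.2, F = 3.6,
         P = 6.1, S = 8.4, T = 5.4, W = 1.2, Y = 2.6, V = 6.0)
  f <- f[aas]
  f / sum(f)
}

#' Simulate a set of coding sequences with known codon-usage structure
#'
#' Each gene starts with `ATG`, followed by a number of codons drawn from
#' a negative-binomial length model (floored at 30 codons so per-gene
#' selection rates are estimable), each position drawing an amino acid
#' from `aa_freqs` and then a synonymous codon from the weight model, and
#' ends with a uniformly chosen stop codon. Internal stops are never
#' generated. Output is deterministic given the seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param model A `codon_weight_model`.
#' @param mean_codons Mean body length in codons (default 400, a typical
#'   mammalian CDS).
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param aa_freqs Named frequencies over amino acids; default uniform.
#' @param seed Integer seed.
#' @param transcripts `"single"` (one transcript per gene) or `"multi"`
#'   (some genes gain 1-2 additional 5'-truncated transcripts, to
#'   exercise representative selection).
#' @param gene_prefix Prefix for generated gene ids.
#' @param code A [genetic_code()].
#' @return A list with `cds` (data frame `gene_id`, `transcript_id`,
#'   `nucleotides`) and `truth` (list of class `simulation_truth`:
#'   `model`, `aa_freqs`, `gene_ids`, `lengths` in body codons, `seed`).
#' @export
simulate_cds_set <- function(n_genes, model, mean_codons = 400,
                             dispersion = 10, aa_freqs = NULL, seed = NULL,
                             transcripts = c("single", "multi"),
                             gene_prefix = "SIMG", code = genetic_code()) {
  stopifnot(n_genes >= 1)
  transcripts <- match.arg(transcripts)
  if (is.null(aa_freqs)) aa_freqs <- amino_acid_freqs("uniform", code)
  if (abs(sum(aa_freqs) - 1) > 1e-8)
    stop("amino-acid frequencies must sum to 1")
  if (!is.null(seed)) set.seed(seed)

  sense <- code$sense_codons
  ## marginal codon probability: P(aa) * P(codon | aa)
  p <- aa_freqs[code$amino_acid[sense]] * unclass(model)[sense]
  p <- p / sum(p)

  len <- pmax(30L, stats::rnbinom(n_genes, mu = mean_codons,
                                  size = dispersion))
  total <- sum(len)
  draws <- sample.int(length(sense), total, replace = TRUE, prob = p)
  gene_f <- factor(rep.int(seq_len(n_genes), len), levels = seq_len(n_genes))
  bodies <- vapply(split(sense[draws], gene_f), paste0, "", collapse = "")
  stops <- sample(code$stop_codons, n_genes, replace = TRUE)

  width <- max(4L, nchar(as.character(n_genes)))
  gene_ids <- sprintf("%s%0*d", gene_prefix, width, seq_len(n_genes))
  cds <- data.frame(gene_id = gene_ids,
                    transcript_id = sub("G", "T", gene_ids, fixed = TRUE),
                    nucleotides = unname(paste0("ATG", bodies, stops)),
                    stringsAsFactors = FALSE)

  if (transcripts == "multi") {
    extra_n <- sample(0:2, n_genes, replace = TRUE)
    extras <- lapply(which(extra_n > 0L), function(i) {
      k <- extra_n[i]
      keep <- pmax(10L, floor(len[i] * seq_len(k) / (k + 1)))
      data.frame(gene_id = gene_ids[i],
                 transcript_id = paste0(cds$transcript_id[i], ".", seq_len(k)),
                 nucleotides = paste0("ATG",
                                      substr(bodies[i], 1L, 3L * keep),
                                      stops[i]),
                 stringsAsFactors = FALSE)
    })
    cds <- rbind(cds, do.call(rbind, extras))
    cds <- cds[order(match(cds$gene_id, gene_ids), cds$transcript_id), ,
               drop = FALSE]
    rownames(cds) <- NULL
  }

  truth <- structure(list(model = model, aa_freqs = aa_freqs,
                          gene_ids = gene_ids, lengths = len, seed = seed),
                     class = "simulation_truth")
  list(cds = cds, truth = truth)
}

#' Simulate a differential-expression results table with planted structure
#'
#' Generates a DE table in which exactly `n_pass` records strictly satisfy
#' `padj < padj_max` and `|log2fc| > lfc_min` (passes split between up-
#' and down-regulation), the remaining records fail at least one
#' criterion, planted boundary rows sit exactly on each threshold (and are
#' therefore excluded by the strict filter), and a stated fraction of
#' records has missing `padj`.
#'
#' @param n_genes Number of records.
#' @param n_pass Number of records passing both thresholds (0 <= n_pass
#'   <= n_genes).
#' @param padj_max,lfc_min The thresholds the truth is planted around
#'   (defaults 0.05 and 0.7).
#' @param frac_missing Fraction of non-passing records given `padj = NA`.
#' @param seed Integer seed.
#' @param gene_prefix Prefix for generated gene ids.
#' @return A list with `records` (data frame `gene_id`, `log2fc`, `padj`)
#'   and `truth` (list: `pass_ids`, `up_ids`, `down_ids`, `boundary_ids`,
#'   `missing_ids`, thresholds, `seed`).
#' @export
simulate_de_table <- function(n_genes, n_pass, padj_max = 0.05,
                              lfc_min = 0.7, frac_missing = 0.02,
                              seed = NULL, gene_prefix = "DEG") {
  stopifnot(n_pass >= 0, n_pass <= n_genes)
  if (!is.null(seed)) set.seed(seed)
  width <- max(4L, nchar(as.character(n_genes)))
  ids <- sprintf("%s%0*d", gene_prefix, width, seq_len(n_genes))

  padj <- numeric(n_genes)
  lfc <- numeric(n_genes)
  pass <- seq_len(n_pass)
  fail <- setdiff(seq_len(n_genes), pass)

  ## passing rows: strictly inside both thresholds, both directions
  sgn <- sample(c(-1, 1), n_pass, replace = TRUE)
  padj[pass] <- stats::runif(n_pass, 0, padj_max * 0.98)
  lfc[pass] <- sgn * (lfc_min + 0.05 + stats::rexp(n_pass, rate = 1))

  ## failing rows: miss at least one criterion
  n_fail <- length(fail)
  if (n_fail) {
    kind <- sample(c("padj_only", "lfc_only", "both_fail"), n_fail,
                   replace = TRUE)
    big_lfc <- function(n) sample(c(-1, 1), n, TRUE) *
      (lfc_min + 0.05 + stats::rexp(n, 1))
    small_lfc <- function(n) stats::runif(n, -lfc_min * 0.98, lfc_min * 0.98)
    hi_padj <- function(n) stats::runif(n, padj_max, 1)
    lo_padj <- function(n) stats::runif(n, 0, padj_max * 0.98)
    i <- fail[kind == "padj_only"]   # significant fold change, padj too high
    padj[i] <- hi_padj(length(i)); lfc[i] <- big_lfc(length(i))
    i <- fail[kind == "lfc_only"]    # good padj, small fold change
    padj[i] <- lo_padj(length(i)); lfc[i] <- small_lfc(length(i))
    i <- fail[kind == "both_fail"]
    padj[i] <- hi_padj(length(i)); lfc[i] <- small_lfc(length(i))

    ## planted boundary rows: exactly on each threshold -> excluded by the
    ## strict filter
    boundary <- fail[seq_len(min(4L, n_fail))]
    if (length(boundary) >= 1L) { padj[boundary[1L]] <- padj_max
                                  lfc[boundary[1L]] <- 2 }
    if (length(boundary) >= 2L) { padj[boundary[2L]] <- padj_max / 2
                                  lfc[boundary[2L]] <- lfc_min }
    if (length(boundary) >= 3L) { padj[boundary[3L]] <- padj_max / 2
                                  lfc[boundary[3L]] <- -lfc_min }
    if (length(boundary) >= 4L) { padj[boundary[4L]] <- padj_max
                                  lfc[boundary[4L]] <- lfc_min }

    ## missing padj on a fraction of the remaining failing rows
    rest <- setdiff(fail, boundary)
    n_na <- min(length(rest), round(frac_missing * n_genes))
    missing <- if (n_na) sample(rest, n_na) else integer(0)
    padj[missing] <- NA_real_
    lfc[missing] <- big_lfc(length(missing))   # would pass but for NA padj
  } else {
    boundary <- missing <- integer(0)
  }

  ord <- sample.int(n_genes)   # shuffle so truth rows are not contiguous
  records <- data.frame(gene_id = ids[ord], log2fc = lfc[ord],
                        padj = padj[ord], stringsAsFactors = FALSE)
  truth <- list(pass_ids = ids[pass],
                up_ids = ids[pass][sgn > 0],
                down_ids = ids[pass][sgn < 0],
                boundary_ids = ids[boundary],
                missing_ids = ids[missing],
                padj_max = padj_max, lfc_min = lfc_min, seed = seed)
  list(records = records, truth = truth)
}

#' Write a DE table as TSV
#'
#' Uses the DESeq2-style column names `gene_id`, `log2FoldChange`,
#' `padj` so [read_de_table()] defaults round-trip.
#'
#' @param records Data frame with `gene_id`, `log2fc`, `padj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(records, path) {
  df <- data.frame(gene_id = records$gene_id,
                   log2FoldChange = records$log2fc,
                   padj = records$padj)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write gene sets as a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}
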