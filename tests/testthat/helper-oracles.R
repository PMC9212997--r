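## Independent brute-force oracles. These deliberately use naive
## character-by-character / O(m^2) algorithms so they share no code path
## with the package implementations they check.

STD_CODE <- genetic_code()

## triplet scan via an explicit character loop
oracle_count_codons <- function(nt) {
  chars <- strsplit(nt, "")[[1]]
  counts <- stats::setNames(rep(0L, 64), STD_CODE$codons)
  i <- 1L
  while (i + 2L <= length(chars)) {
    codon <- paste0(chars[i], chars[i + 1L], chars[i + 2L])
    counts[codon] <- counts[codon] + 1L
    i <- i + 3L
  }
  counts
}

## per-codon loop over family sums
oracle_selection_rates <- function(counts) {
  out <- stats::setNames(rep(NA_real_, 61), STD_CODE$sense_codons)
  for (codon in STD_CODE$sense_codons) {
    aa <- STD_CODE$table[[codon]]
    fam_total <- 0L
    for (other in STD_CODE$sense_codons)
      if (STD_CODE$table[[other]] == aa)
        fam_total <- fam_total + counts[[other]]
    if (fam_total > 0L) out[codon] <- counts[[codon]] / fam_total
  }
  out
}

oracle_usage_rates <- function(counts) {
  total <- 0L
  for (codon in STD_CODE$sense_codons) total <- total + counts[[codon]]
  if (total == 0L)
    return(stats::setNames(rep(NA_real_, 61), STD_CODE$sense_codons))
  stats::setNames(
    vapply(STD_CODE$sense_codons, function(c) counts[[c]] / total, 0),
    STD_CODE$sense_codons)
}

## O(m^2) step-up: q_i = min over j with p_j >= p_i of p_j * m / rank(p_j)
oracle_bh <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  for (i in which(ok)) {
    r_i <- sum(p[ok] <= p[i])   # rank of p_i among non-missing
    best <- Inf
    for (j in which(ok)) {
      r_j <- sum(p[ok] <= p[j])
      if (r_j >= r_i) best <- min(best, p[j] * m / r_j)
    }
    q[i] <- min(1, best)
  }
  q
}

## per-gene region assignment for Venn counts
oracle_overlap <- function(sets) {
  universe <- unique(unlist(sets))
  counts <- new.env()
  for (g in universe) {
    pat <- paste(vapply(sets, function(s) if (g %in% s) "+" else "-", ""),
                 collapse = "")
    counts[[pat]] <- (if (is.null(counts[[pat]])) 0L else counts[[pat]]) + 1L
  }
  as.list(counts)
}

## row-by-row scan of a DE table
oracle_filter_de <- function(records, padj_max = 0.05, lfc_min = 0.7,
                             direction = "both") {
  hits <- character(0)
  for (i in seq_len(nrow(records))) {
    padj <- records$padj[i]; lfc <- records$log2fc[i]
    if (is.na(padj) || padj >= padj_max) next
    ok <- switch(direction,
                 up = lfc > lfc_min,
                 down = lfc < -lfc_min,
                 both = abs(lfc) > lfc_min)
    if (isTRUE(ok)) hits <- c(hits, records$gene_id[i])
  }
  unique(hits)
}

## random CDS-like strings, built independently of the package simulator
random_cds_string <- function(n_codons, include_n = FALSE) {
  alphabet <- c("A", "C", "G", "T", if (include_n) "N")
  paste0(sample(alphabet, 3 * n_codons, replace = TRUE), collapse = "")
}

make_cds_df <- function(nucleotides, prefix = "G") {
  n <- length(nucleotides)
  data.frame(gene_id = paste0(prefix, seq_len(n)),
             transcript_id = paste0(prefix, "T", seq_len(n)),
             nucleotides = nucleotides, stringsAsFactors = FALSE)
}
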