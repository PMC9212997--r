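#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file. Recognised keys (defaults in
#' parentheses):
#' \describe{
#'   \item{cds_fasta}{path to the coding-sequence FASTA (required).}
#'   \item{output_dir}{directory for the output bundle (required).}
#'   \item{dialect}{`name` ("gencode"), `gene_field` (2),
#'     `transcript_field` (1).}
#'   \item{validation_mode}{"strict" or "lenient" ("lenient").}
#'   \item{representative_policy}{"longest" or "first" ("longest").}
#'   \item{genetic_code}{path to a 64-row codon/amino-acid TSV, or null
#'     for the standard code.}
#'   \item{de_tables}{list of `{name, path}` DE results tables (optional;
#'     column names via `de_columns`).}
#'   \item{membership}{`{path, term, name}` membership subset (optional).}
#'   \item{thresholds}{`padj_max` (0.05), `lfc_min` (0.7), `direction`
#'     ("both"), `min_n` (10).}
#'   \item{stats}{`var_equal` (true).}
#'   \item{background}{`mode`: "exhaustive" (all profiled genes, default)
#'     or "list" with `path` to a gene-list file.}
#'   \item{max_missing_frac}{warn when at least this fraction of a
#'     subset's genes is absent from the profile matrix (0.2).}
#'   \item{seed}{integer seed recorded in the manifest (1).}
#' }
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    dialect = list(name = "gencode", gene_field = 2L, transcript_field = 1L),
    validation_mode = "lenient",
    representative_policy = "longest",
    genetic_code = NULL,
    de_tables = list(),
    de_columns = list(gene_id = "gene_id", log2fc = "log2FoldChange",
                      padj = "padj"),
    membership = NULL,
    thresholds = list(padj_max = 0.05, lfc_min = 0.7, direction = "both",
                      min_n = 10L),
    stats = list(var_equal = TRUE),
    background = list(mode = "exhaustive"),
    max_missing_frac = 0.2,
    seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && !k %in% c("de_tables", "membership")) {
      miss <- setdiff(names(defaults[[k]]), names(config[[k]]))
      config[[k]][miss] <- defaults[[k]][miss]
    }
  }
  if (is.null(config$cds_fasta)) stop("config must set cds_fasta")
  if (is.null(config$output_dir)) stop("config must set output_dir")
  if (!file.exists(config$cds_fasta))
    stop("cds_fasta not found: ", config$cds_fasta)
  for (de in config$de_tables)
    if (!file.exists(de$path)) stop("DE table not found: ", de$path)
  if (!is.null(config$membership) && !file.exists(config$membership$path))
    stop("membership file not found: ", config$membership$path)
  with(config$thresholds,
       stopifnot(padj_max > 0, lfc_min > 0, min_n >= 2))
  structure(config, class = c("pipeline_config", "list"))
}

log_stage <- function(stage, t0, detail) {
  message(sprintf("[codonbias] %-14s %6.2fs  %s", stage,
                  as.numeric(Sys.time()) - t0, detail))
}

#' Run the codon-usage-bias pipeline end to end
#'
#' Executes read, validate, representative selection, profile assembly,
#' subset definition, per-codon comparison and output writing, producing
#' for each subset a comparison TSV, a pooled relative-change matrix TSV,
#' a Venn-region TSV when two or more DE tables are given, a rejection
#' report, and a JSON run manifest with input checksums and per-stage
#' record counts. Progress is logged to stderr.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with `profiles`, `subsets`, `comparisons`,
#'   `overlap` (or `NULL`), `manifest` and `output_files`.
#' @export
run_codon_bias <- function(config) {
  cfg <- read_pipeline_config(config)
  t_start <- as.numeric(Sys.time())
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  code <- genetic_code(cfg$genetic_code)
  out_files <- character(0)

  t0 <- as.numeric(Sys.time())
  dialect <- header_dialect(cfg$dialect$name, cfg$dialect$gene_field,
                            cfg$dialect$transcript_field)
  cds <- read_cds_fasta(cfg$cds_fasta, dialect)
  log_stage("read", t0, paste(nrow(cds), "records"))

  t0 <- as.numeric(Sys.time())
  val <- validate_cds(cds, cfg$validation_mode)
  rej_path <- file.path(cfg$output_dir, "rejected_sequences.tsv")
  write_rejection_report(val, rej_path)
  out_files <- c(out_files, rej_path)
  log_stage("validate", t0, paste(nrow(val$accepted), "accepted,",
                                  nrow(val$rejected), "rejected"))

  t0 <- as.numeric(Sys.time())
  rep_cds <- select_representative(val$accepted, cfg$representative_policy)
  log_stage("representative", t0, paste(nrow(rep_cds), "genes"))

  t0 <- as.numeric(Sys.time())
  profiles <- profile_matrix(rep_cds, code)
  log_stage("profiles", t0, paste(length(profiles$gene_id), "x",
                                  length(code$sense_codons), "matrix"))

  ## subsets from DE tables and/or membership list
  t0 <- as.numeric(Sys.time())
  th <- cfg$thresholds
  subsets <- list()
  for (de in cfg$de_tables) {
    rec <- read_de_table(de$path, cfg$de_columns)
    s <- filter_de(rec, th$padj_max, th$lfc_min, th$direction,
                   name = de$name)
    if (length(s$members) == 0L)
      stop("subset '", de$name, "' is empty after filtering at padj < ",
           th$padj_max, ", |log2FC| > ", th$lfc_min,
           " (direction ", th$direction, ")")
    subsets[[s$name]] <- s
  }
  if (!is.null(cfg$membership)) {
    mem <- cfg$membership
    s <- membership_subset(mem$path, mem$term,
                           name = if (is.null(mem$name)) mem$term else mem$name)
    if (length(s$members) == 0L)
      stop("membership subset '", s$name, "' is empty")
    subsets[[s$name]] <- s
  }
  if (length(subsets) == 0L)
    stop("config defines no subsets (need de_tables and/or membership)")
  log_stage("subsets", t0, paste(length(subsets), "subset(s):",
                                 paste(names(subsets), collapse = ", ")))

  background <- NULL
  if (identical(cfg$background$mode, "list")) {
    bg_genes <- readLines(cfg$background$path)
    background <- gene_subset("background_list",
                              bg_genes[nzchar(trimws(bg_genes))])
  }

  ## per-subset comparisons + pooled relative-change matrix
  t0 <- as.numeric(Sys.time())
  comparisons <- list()
  pooled_rows <- list()
  bg_for_pool <- if (is.null(background)) profiles$gene_id else
    background$members
  for (s in subsets) {
    missing_frac <- mean(!s$members %in% profiles$gene_id)
    if (missing_frac >= cfg$max_missing_frac)
      warning(sprintf(
        "subset '%s': %d of %d genes (%.0f%%) absent from the profile matrix",
        s$name, sum(!s$members %in% profiles$gene_id), length(s$members),
        100 * missing_frac))
    cmp <- compare_codon_usage(profiles, s, background = background,
                               min_n = th$min_n,
                               var_equal = isTRUE(cfg$stats$var_equal),
                               code = code)
    comparisons[[s$name]] <- cmp
    cmp_path <- file.path(cfg$output_dir,
                          paste0("comparison_", s$name, ".tsv"))
    write_comparison_tsv(cmp, cmp_path)
    out_files <- c(out_files, cmp_path)

    sub_pool <- pooled_selection_rates(profiles, s$members)
    bg_pool <- pooled_selection_rates(
      profiles, setdiff(bg_for_pool, s$members))
    pooled_rows[[s$name]] <- data.frame(
      subset = s$name, codon = names(sub_pool),
      amino_acid = unname(code$amino_acid[names(sub_pool)]),
      pooled_subset_rate = unname(sub_pool),
      pooled_background_rate = unname(bg_pool),
      relative_change = unname((sub_pool - bg_pool) / bg_pool),
      stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, c(pooled_rows, make.row.names = FALSE))
  pooled_path <- file.path(cfg$output_dir, "pooled_rates.tsv")
  utils::write.table(pooled, pooled_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  out_files <- c(out_files, pooled_path)
  log_stage("compare", t0, paste(length(comparisons), "comparison(s)"))

  ## multi-set overlap when >= 2 DE-derived subsets exist
  overlap <- NULL
  de_subsets <- subsets[vapply(subsets, function(s)
    startsWith(s$provenance, "de_"), logical(1))]
  if (length(de_subsets) >= 2L) {
    overlap <- overlap_counts(de_subsets[seq_len(min(4L, length(de_subsets)))])
    venn_path <- file.path(cfg$output_dir, "venn_regions.tsv")
    write_overlap_tsv(overlap, venn_path)
    out_files <- c(out_files, venn_path)
  }

  input_paths <- c(cfg$cds_fasta,
                   vapply(cfg$de_tables, `[[`, "", "path"),
                   if (!is.null(cfg$membership)) cfg$membership$path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("codonbias")),
    started = format(as.POSIXct(t_start, origin = "1970-01-01"),
                     "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    duration_s = round(as.numeric(Sys.time()) - t_start, 2),
    seed = cfg$seed,
    config = unclass(cfg),
    input_checksums = as.list(tools::md5sum(input_paths)),
    counts = list(parsed = nrow(cds),
                  validated = nrow(val$accepted),
                  rejected = nrow(val$rejected),
                  representative = nrow(rep_cds),
                  genes_in_matrix = length(profiles$gene_id),
                  subset_sizes = lapply(subsets, function(s)
                    length(s$members))))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  out_files <- c(out_files, manifest_path)
  log_stage("done", t_start, paste(length(out_files), "output files"))

  invisible(list(profiles = profiles, subsets = subsets,
                 comparisons = comparisons, overlap = overlap,
                 manifest = manifest, output_files = out_files))
}
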