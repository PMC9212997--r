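test_that("DE filtering applies strict thresholds in each direction", {
  rec <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(0.8, 0.7, -0.9, 2.0, 0.71, -0.71),
    padj = c(0.04, 0.04, 0.01, 0.05, NA, 0.049))
  up <- filter_de(rec, direction = "up")
  expect_identical(up$members, "g1")          # g2 on lfc boundary, g4 on padj
  down <- filter_de(rec, direction = "down")
  expect_setequal(down$members, c("g3", "g6"))
  both <- filter_de(rec, direction = "both")
  expect_setequal(both$members, c("g1", "g3", "g6"))
  expect_identical(both$provenance, "de_both")
})

test_that("DE filtering matches a brute-force row scan on random tables", {
  set.seed(601)
  for (i in 1:5) {
    rec <- data.frame(
      gene_id = paste0("g", 1:400),
      log2fc = stats::rnorm(400, sd = 1.2),
      padj = ifelse(stats::runif(400) < 0.05, NA, stats::runif(400)))
    for (dir in c("up", "down", "both")) {
      got <- filter_de(rec, 0.1, 0.5, dir)
      expect_setequal(got$members, oracle_filter_de(rec, 0.1, 0.5, dir))
    }
  }
})

test_that("conflicting duplicate DE records are refused, consistent ones tolerated", {
  rec <- data.frame(gene_id = c("g1", "g1"), log2fc = c(1, 2),
                    padj = c(0.01, 0.01))
  expect_error(filter_de(rec), "g1")
  same <- data.frame(gene_id = c("g1", "g1"), log2fc = c(1, 1),
                     padj = c(0.01, 0.01))
  expect_identical(filter_de(same)$members, "g1")
})

test_that("membership subsets parse GMT and two-column TSV, with term union", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:0001649\tosteoblast differentiation\tg1\tg2",
               "GO:0001649\tosteoblast differentiation\tg2\tg3",
               "GO:0000001\tother\tg9"), gmt)
  s <- membership_subset(gmt, "GO:0001649")
  expect_setequal(s$members, c("g1", "g2", "g3"))
  expect_identical(s$provenance, "membership_list")
  expect_error(membership_subset(gmt, "GO:MISSING"), "GO:0000001")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("termA\tg1", "termA\tg2", "termB\tg3"), tsv)
  expect_setequal(membership_subset(tsv, "termA")$members, c("g1", "g2"))
})

test_that("BH step-up matches hand computation and brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_adjust(0.2), 0.2)             # m = 1
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(602)
  p <- stats::runif(200)
  p[sample(200, 10)] <- NA
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-15)
  expect_identical(is.na(q), is.na(p))
  ## independent cross-check against the stock BH implementation
  expect_equal(q[!is.na(p)], stats::p.adjust(p[!is.na(p)], "BH"),
               tolerance = 1e-15)
  ## q monotone in p-rank
  ord <- order(p[!is.na(p)])
  expect_true(all(diff(q[!is.na(p)][ord]) >= -1e-15))
  ## ties share one q-value
  expect_equal(bh_adjust(c(0.02, 0.02, 0.5))[1:2], rep(0.03, 2))
})

test_that("identical groups give zero change and zero t everywhere", {
  model <- simulate_weight_model(1, seed = 61)
  sim <- simulate_cds_set(40, model, mean_codons = 120, seed = 62)
  prof <- profile_matrix(sim$cds)
  ## duplicate every gene so subset and background hold the same values
  twin <- sim$cds
  twin$gene_id <- paste0(twin$gene_id, "_twin")
  both <- profile_matrix(rbind(sim$cds, twin))
  cmp <- compare_codon_usage(both, sim$truth$gene_ids, min_n = 5)
  tested <- cmp$tested
  expect_true(all(cmp$relative_change[tested & !is.na(cmp$relative_change)] == 0))
  expect_true(all(cmp$t_stat[tested] == 0))
  expect_true(all(cmp$p_value[tested] == 1))
})

test_that("t statistics agree with stats::t.test on both variants", {
  model <- simulate_weight_model(1, seed = 63)
  a <- simulate_cds_set(25, model, mean_codons = 100, seed = 64,
                        gene_prefix = "GA")
  b <- simulate_cds_set(30, model, mean_codons = 100, seed = 65,
                        gene_prefix = "GB")
  prof <- profile_matrix(rbind(a$cds, b$cds))
  sel <- prof$selection
  rownames(sel) <- prof$gene_id
  for (veq in c(TRUE, FALSE)) {
    cmp <- compare_codon_usage(prof, a$truth$gene_ids, min_n = 5,
                               var_equal = veq)
    for (codon in c("CTG", "AAA", "GGC", "TTT")) {
      row <- cmp[cmp$codon == codon, ]
      if (!row$tested || row$degenerate) next
      ref <- stats::t.test(sel[a$truth$gene_ids, codon],
                           sel[b$truth$gene_ids, codon], var.equal = veq)
      expect_equal(row$t_stat, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(row$mean_subset - row$mean_background,
                   unname(diff(rev(ref$estimate))), tolerance = 1e-12)
    }
  }
})

test_that("degenerate single-codon families report t = 0, p = 1, q = 1", {
  model <- simulate_weight_model(1, seed = 66)
  a <- simulate_cds_set(30, model, mean_codons = 100, seed = 67,
                        gene_prefix = "GA")
  b <- simulate_cds_set(30, model, mean_codons = 100, seed = 68,
                        gene_prefix = "GB")
  prof <- profile_matrix(rbind(a$cds, b$cds))
  cmp <- compare_codon_usage(prof, a$truth$gene_ids, min_n = 5)
  met <- cmp[cmp$codon == "ATG", ]
  trp <- cmp[cmp$codon == "TGG", ]
  expect_true(met$degenerate && trp$degenerate)
  expect_identical(c(met$t_stat, trp$t_stat), c(0, 0))
  expect_identical(c(met$p_value, trp$p_value), c(1, 1))
})

test_that("codons below min_n are reported untested, not dropped", {
  ## tiny genes: many families unobserved per gene
  model <- simulate_weight_model(1, seed = 69)
  sim <- simulate_cds_set(24, model, mean_codons = 30, seed = 70)
  prof <- profile_matrix(sim$cds)
  cmp <- compare_codon_usage(prof, sim$truth$gene_ids[1:4], min_n = 500)
  expect_identical(nrow(cmp), 61L)
  expect_false(any(cmp$tested))
  expect_true(all(is.na(cmp$p_value)))
  expect_true(all(is.na(cmp$q_value)))
})

test_that("the background excludes subset genes and cannot be empty", {
  model <- simulate_weight_model(1, seed = 71)
  sim <- simulate_cds_set(20, model, mean_codons = 60, seed = 72)
  prof <- profile_matrix(sim$cds)
  expect_error(compare_codon_usage(prof, sim$truth$gene_ids), "disjoint")
  expect_error(compare_codon_usage(prof, c("X1", "X2")), "no genes")
})

test_that("an injected family shift is detected with the right sign", {
  base <- simulate_weight_model(1, seed = 73)
  biased <- apply_bias(base, "CTG", 4)
  bg <- simulate_cds_set(120, base, mean_codons = 150, seed = 74,
                         gene_prefix = "BGG")
  sub <- simulate_cds_set(120, biased, mean_codons = 150, seed = 75,
                          gene_prefix = "SUBG")
  prof <- profile_matrix(rbind(bg$cds, sub$cds))
  cmp <- compare_codon_usage(prof, sub$truth$gene_ids)
  ctg <- cmp[cmp$codon == "CTG", ]
  expect_gt(ctg$relative_change, 0)
  expect_lt(ctg$q_value, 0.05)
  ## family-sum conservation of the group means in each group
  leu <- genetic_code()$families[["L"]]
  leu_rows <- cmp[cmp$codon %in% leu, ]
  expect_lt(abs(sum(leu_rows$mean_subset) - 1), 1e-10)
  expect_lt(abs(sum(leu_rows$mean_background) - 1), 1e-10)
})

test_that("comparison methods expose the fit the usual way", {
  model <- simulate_weight_model(1, seed = 76)
  a <- simulate_cds_set(30, model, mean_codons = 80, seed = 77,
                        gene_prefix = "GA")
  b <- simulate_cds_set(30, model, mean_codons = 80, seed = 78,
                        gene_prefix = "GB")
  prof <- profile_matrix(rbind(a$cds, b$cds))
  cmp <- compare_codon_usage(prof, a$truth$gene_ids, min_n = 5)
  expect_s3_class(cmp, "codon_comparison")
  expect_output(print(cmp), "Student t-test")
  sm <- summary(cmp)
  expect_identical(sm$n_codons, 61L)
  expect_output(print(sm), "tested")
  expect_named(coef(cmp), cmp$codon)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(cmp))
})

test_that("overlap regions partition the union for 2-4 sets", {
  ov <- overlap_counts(list(A = c("g1", "g2"), B = c("g2", "g3")))
  counts <- stats::setNames(ov$regions$count, ov$regions$region)
  expect_identical(counts[c("+-", "-+", "++")],
                   c("+-" = 1L, "-+" = 1L, "++" = 1L))
  expect_identical(ov$intersection, "g2")

  ## four pairwise-disjoint sets
  dis <- overlap_counts(list(W = "a", X = c("b", "c"), Y = "d",
                             Z = c("e", "f", "g")))
  multi <- dis$regions$count[vapply(strsplit(dis$regions$region, ""),
                                    function(f) sum(f == "+") > 1, TRUE)]
  expect_true(all(multi == 0L))
  single <- dis$regions[dis$regions$region %in%
                          c("+---", "-+--", "--+-", "---+"), ]
  expect_identical(sort(single$count), c(1L, 1L, 2L, 3L))
  expect_length(dis$intersection, 0)

  ## four random sets vs brute-force per-gene assignment
  set.seed(603)
  sets <- lapply(1:4, function(i)
    sample(paste0("gene", 1:600), 300, replace = FALSE))
  names(sets) <- LETTERS[1:4]
  ov4 <- overlap_counts(sets)
  expect_identical(sum(ov4$regions$count), ov4$union_size)
  oracle <- oracle_overlap(sets)
  for (region in ov4$regions$region) {
    want <- if (is.null(oracle[[region]])) 0L else oracle[[region]]
    expect_identical(ov4$regions$count[ov4$regions$region == region], want)
  }

  expect_error(overlap_counts(list(A = "g1")), "2 to 4")
  expect_error(overlap_counts(list(A = "g1", A = "g2", B = "g3")),
               "duplicate")
})
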