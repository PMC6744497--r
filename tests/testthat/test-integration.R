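test_that("probe-to-gene mapping expands multi-gene probes and drops IGR", {
  ann <- small_annotation()
  map <- map_probes_to_genes(ann)
  expect_setequal(map$PTPRE, c("cg01", "cg05"))
  expect_true("cg02" %in% map$PIK3R1 && "cg02" %in% map$MLXIP)
  expect_false(any(c("cg03", "cg06") %in% unlist(map)))  # IGR unmapped
  empty <- validate_annotation(small_annotation()[0, ])
  expect_length(map_probes_to_genes(empty), 0L)
})

test_that("gene methylation summaries roll up significant probes with totals", {
  ann <- small_annotation()
  dm <- fake_diff_table(ann$probe_id,
                        p = c(0.001, 0.001, 0.5, 0.001, 0.001, 0.5, 0.5, 0.5),
                        effect = c(6, -7, 1, 8, 9, 1, 1, 1),
                        q = c(0.01, 0.01, 0.9, 0.01, 0.01, 0.9, 0.9, 0.9),
                        significant = c(TRUE, TRUE, FALSE, TRUE, TRUE,
                                        FALSE, FALSE, FALSE))
  s <- summarize_gene_methylation(dm, ann)
  # cg01 + cg05 on PTPRE; cg02 on PIK3R1 and MLXIP (two links); cg04 on ACACB
  expect_equal(s$genes$n_dmc[s$genes$gene_id == "PTPRE"], 2L)
  expect_equal(s$totals$n_links, 5L)          # 4 probes, one double-linked
  expect_equal(s$totals$n_unique_probes, 4L)
  expect_equal(s$genes$max_abs_delta_beta[s$genes$gene_id == "PTPRE"], 9)
  # universe restriction only affects the gene total
  s2 <- summarize_gene_methylation(dm, ann, gene_universe = c("PTPRE", "ACACB"))
  expect_equal(s2$totals$n_genes, 2L)
  expect_equal(s2$totals$n_links, 5L)
  # no significant probes: empty rollup
  dm$significant <- FALSE
  s3 <- summarize_gene_methylation(dm, ann)
  expect_equal(nrow(s3$genes), 0L)
  expect_equal(s3$totals$n_links, 0L)
})

conc_fixture <- function(expr_dir, deltas, features) {
  # one gene "G" with given probe deltas/features on a small manifest
  ann <- validate_annotation(data.frame(
    probe_id = sprintf("cg%02d", seq_along(deltas)),
    chromosome = "1", position = seq_along(deltas) * 10L,
    gene_symbols = "G", region_feature = features,
    island_relation = "OpenSea", snp_flag = FALSE, stringsAsFactors = FALSE))
  dm <- fake_diff_table(ann$probe_id, p = rep(0.001, length(deltas)),
                        effect = deltas, q = rep(0.01, length(deltas)),
                        significant = rep(TRUE, length(deltas)))
  de <- fake_diff_table("G", p = 0.001, effect = if (expr_dir == "up") 1 else -1)
  s <- summarize_gene_methylation(dm, ann)
  concordance(de, s, ann)
}

test_that("concordance classes follow the promoter/body direction rules", {
  # downregulated gene with promoter hypermethylation (PTPRE-like)
  r <- conc_fixture("down", c(6, 8), c("TSS200", "TSS1500"))
  expect_equal(r$class, "concordant_promoter")

  # upregulated gene: promoter hypo + body hyper, all consistent (PIK3R1-like)
  r <- conc_fixture("up", c(-6, 7), c("TSS200", "Body"))
  expect_equal(r$class, "concordant_promoter")  # tie broken to promoter
  r <- conc_fixture("up", c(-6, 7, 8), c("TSS200", "Body", "UTR3"))
  expect_equal(r$class, "concordant_body")      # body zone dominates

  # upregulated gene with promoter hypermethylation alone is discordant
  r <- conc_fixture("up", 6, "TSS200")
  expect_equal(r$class, "discordant")

  # one consistent and one inconsistent probe: mixed
  r <- conc_fixture("up", c(-6, 6), c("TSS200", "TSS1500"))
  expect_equal(r$class, "mixed")
})

test_that("genes without linked DMCs are unlinked; foreign genes error", {
  ann <- small_annotation()
  dm <- fake_diff_table(ann$probe_id, p = rep(0.9, 8), effect = rep(1, 8),
                        q = rep(0.9, 8), significant = rep(FALSE, 8))
  s <- summarize_gene_methylation(dm, ann)
  de <- fake_diff_table("PTPRE", p = 0.001, effect = -1)
  r <- concordance(de, s, ann)
  expect_equal(r$class, "unlinked")
  de_bad <- fake_diff_table("NOT_A_GENE", p = 0.001)
  expect_error(concordance(de_bad, s, ann), "absent from the annotation")
})

test_that("candidate filter applies the >=2-CpG and >5pp rules with ordering", {
  ann <- validate_annotation(data.frame(
    probe_id = sprintf("cg%02d", 1:7), chromosome = "1", position = 1:7 * 10L,
    gene_symbols = c("A", "A", "A", "B", "C", "C", "C"),
    region_feature = "Body", island_relation = "OpenSea", snp_flag = FALSE,
    stringsAsFactors = FALSE))
  dm <- fake_diff_table(ann$probe_id, p = rep(0.001, 7),
                        effect = c(6, -7, 1, 6, 4, -4, 3),
                        q = rep(0.01, 7), significant = rep(TRUE, 7))
  de <- fake_diff_table(c("A", "B", "C"), p = rep(0.001, 3), effect = c(1, 1, 1))
  s <- summarize_gene_methylation(dm, ann)
  conc <- concordance(de, s, ann)
  cand <- candidate_filter(s, conc)
  # A: deltas (6, -7, 1) passes; B: single CpG fails count; C: (4, -4, 3)
  # fails the >5pp magnitude rule
  expect_equal(cand$gene_id, "A")
  expect_equal(cand$n_dmc_above_threshold, 2L)

  # monotone shrinkage in both thresholds
  n_base <- nrow(candidate_filter(s, conc, min_cpgs = 1, min_abs_delta_beta_pp = 0))
  n_tight1 <- nrow(candidate_filter(s, conc, min_cpgs = 3, min_abs_delta_beta_pp = 0))
  n_tight2 <- nrow(candidate_filter(s, conc, min_cpgs = 1, min_abs_delta_beta_pp = 6.5))
  expect_lte(n_tight1, n_base)
  expect_lte(n_tight2, n_base)
})

test_that("concordance classes partition the significant DEG set on a cohort", {
  co <- small_cohort(seed = 71)
  qc <- filter_probes(co$beta, co$annotation, "paired")
  dm <- diff_methylation(qc$beta, co$sheet, paired_contrast(52))
  de <- diff_expression(co$expression, co$sheet, paired_contrast(52))
  s <- summarize_gene_methylation(dm, co$annotation)
  conc <- concordance(de, s, co$annotation)
  expect_equal(nrow(conc), sum(de$significant))
  expect_true(all(conc$class %in% c("concordant_promoter", "concordant_body",
                                    "discordant", "mixed", "unlinked")))
  expect_true(all((conc$class == "unlinked") == (conc$n_probes == 0L)))
})
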