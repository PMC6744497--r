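test_that("four-field chi-square matches hand computation and symmetries", {
  r <- chisq_2x2(two_by_two(30, 10, 10, 30))
  expect_equal(r$statistic, 20)  # expected counts all 20, sum of (10^2/20)
  expect_equal(r$p, 7.7e-6, tolerance = 1e-2)
  expect_true(all(r$expected == 20))

  r0 <- chisq_2x2(two_by_two(10, 10, 10, 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # invariant under transposition and simultaneous row/col swap
  tab <- two_by_two(12, 5, 30, 44)
  expect_equal(chisq_2x2(t(tab))$statistic, chisq_2x2(tab)$statistic)
  expect_equal(chisq_2x2(tab[2:1, 2:1])$statistic, chisq_2x2(tab)$statistic)

  expect_warning(rz <- chisq_2x2(two_by_two(0, 0, 5, 5)), "empty margin")
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p, 1)
  expect_warning(chisq_2x2(two_by_two(2, 1, 1, 3)), "below 5")
  # Yates correction reduces the statistic
  expect_lt(chisq_2x2(two_by_two(30, 10, 10, 30), yates = TRUE)$statistic, 20)
})

test_that("region enrichment detects constructed open-sea excess", {
  n <- 1000L
  ann <- validate_annotation(data.frame(
    probe_id = sprintf("cg%04d", 1:n), chromosome = "1", position = 1:n,
    gene_symbols = "G1", region_feature = "Body",
    island_relation = rep(c("OpenSea", "Island"), each = n / 2),
    snp_flag = FALSE, stringsAsFactors = FALSE))
  universe <- ann$probe_id
  # universe is 50% open sea; take a DMC set that is 80% open sea
  dmc <- c(ann$probe_id[1:80], ann$probe_id[(n / 2 + 1):(n / 2 + 20)])
  res <- region_enrichment(dmc, universe, ann, "island_relation")
  os <- res[res$category == "OpenSea", ]
  expect_equal(os$fold, 1.6)
  expect_lt(os$p, 0.01)
  # chi-square oracle on the same 2x2
  oracle <- chisq_2x2(two_by_two(80, 420, 20, 480))
  expect_equal(os$statistic, oracle$statistic)

  # saturation: dmc = universe gives folds 1 and p 1
  sat <- region_enrichment(universe, universe, ann, "island_relation")
  expect_true(all(sat$fold[sat$n_universe > 0] == 1))
  expect_true(all(sat$p[sat$n_universe > 0] == 1))

  # size-weighted folds average to 1 over the partition (empty categories
  # carry no weight and undefined fold)
  wavg <- sum(res$fold * res$n_universe / length(universe), na.rm = TRUE)
  expect_equal(wavg, 1, tolerance = 1e-12)
  expect_true(all(is.na(res$fold[res$n_universe == 0])))

  # empty dmc: undefined folds, missing p
  emp <- region_enrichment(character(), universe, ann, "island_relation")
  expect_true(all(is.na(emp$fold)))
  expect_true(all(is.na(emp$p)))
})

test_that("three-way genic collapse groups promoter, body and intergenic", {
  ann <- small_annotation()
  probes <- ann$probe_id
  res <- region_enrichment(probes[1], probes, ann, "gene_region_3way")
  expect_setequal(res$category, c("promoter", "body", "intergenic"))
  # TSS200/TSS1500/FirstExon are promoter; Body/UTR3 body; IGR intergenic
  expect_equal(res$n_universe[res$category == "promoter"], 3L)
  expect_equal(res$n_universe[res$category == "body"], 3L)
  expect_equal(res$n_universe[res$category == "intergenic"], 2L)
})

test_that("hypomethylated fraction counts negative delta-beta among significant", {
  tab <- fake_diff_table(sprintf("cg%02d", 1:12),
                         p = rep(0.001, 12),
                         effect = c(rep(-6, 7), rep(6, 3), 0, 4),
                         q = rep(0.001, 12),
                         significant = c(rep(TRUE, 10), FALSE, FALSE))
  expect_equal(hypo_fraction(tab), 0.7)
  tab$effect <- abs(tab$effect)
  expect_equal(hypo_fraction(tab), 0)
  # zero delta-beta counts as hypermethylated (tie rule)
  tab$effect[1] <- 0
  expect_equal(hypo_fraction(tab), 0)
  tab$significant <- FALSE
  expect_true(is.na(hypo_fraction(tab)))
})

test_that("reprogramming enrichment: fraction, saturation and chi-square consistency", {
  universe <- sprintf("g%03d", 1:100)
  r <- reprogramming_enrichment(universe[1:4], universe[1:3], universe)
  expect_equal(r$fraction, 0.75)

  sat <- reprogramming_enrichment(universe[1:4], universe, universe)
  expect_equal(sat$fraction, 1)
  expect_equal(sat$p, 1)  # empty margin: methylation column is saturated

  big_universe <- sprintf("g%05d", 1:5000)
  transient <- big_universe[1:1126]
  meth <- c(big_universe[1:849], big_universe[2000:3500])
  r <- reprogramming_enrichment(transient, meth, big_universe)
  expect_equal(round(100 * r$fraction), 75)
  oracle <- chisq_2x2(two_by_two(849, 277, 1501, 5000 - 849 - 277 - 1501))
  expect_equal(r$statistic, oracle$statistic)
  expect_equal(r$p, oracle$p)

  expect_true(is.na(reprogramming_enrichment(character(), meth, big_universe)$fraction))
})

test_that("Fisher over-representation equals the hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  r <- fisher_ora(universe[1:10], universe[1:10], universe)
  expect_equal(r$p, 1 / choose(100, 10), tolerance = 1e-9)
  expect_equal(r$overlap, 10L)
  expect_true(is.infinite(r$odds_ratio))

  # overlap at expectation is unremarkable
  r <- fisher_ora(universe[1:50], universe[seq(1, 100, 2)], universe)
  expect_gte(r$p, 0.4)

  # zero overlap with small sets: p near 1
  r <- fisher_ora(universe[1:5], universe[6:10], universe)
  expect_gt(r$p, 0.7)

  expect_error(fisher_ora("a", "a", character()), "empty universe")

  # large-count sanity: one-sided Fisher and chi-square/2 within an order
  r <- fisher_ora(universe[1:40], universe[c(1:30, 41:60)], universe)
  ch <- chisq_2x2(two_by_two(30, 10, 20, 40))
  expect_lt(abs(log10(r$p) - log10(ch$p / 2)), 1)
})

test_that("GMT parsing returns named member lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tPTPRE\tPIK3R1", "setB\tdesc\tACACB"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("PTPRE", "PIK3R1"))
  expect_equal(sets$setB, "ACACB")
})
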