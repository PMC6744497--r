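# Four-field chi-square and Fisher machinery: genomic-region enrichment,
# hypomethylation fractions, reprogramming enrichment, generic gene-set
# over-representation.

#' Build a 2x2 contingency table
#'
#' Rows are in-class / not-in-class, columns are in-set / not-in-set.
#'
#' @param a,b,c,d Non-negative integer counts, row-major.
#' @return 2x2 integer matrix.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("2x2 table must have a positive total")
  matrix(as.numeric(counts), nrow = 2L, byrow = TRUE,
         dimnames = list(c("in_class", "not_in_class"), c("in_set", "not_in_set")))
}

#' Four-field (2x2) chi-square test
#'
#' Pearson chi-square with 1 degree of freedom, optional Yates continuity
#' correction. A table with an empty row or column margin yields
#' `statistic = 0, p = 1` with a warning; a warning is also emitted when any
#' expected count falls below 5.
#'
#' @param tab 2x2 count matrix (see [two_by_two()]).
#' @param yates Apply continuity correction? Default `FALSE`.
#' @return List `(statistic, df, p, expected)`.
#' @export
chisq_2x2 <- function(tab, yates = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(tab < 0) || sum(tab) == 0) stop("invalid 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("2x2 table has an empty margin; returning statistic 0, p 1")
    return(list(statistic = 0, df = 1L, p = 1,
                expected = outer(rowSums(tab), colSums(tab)) / sum(tab)))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  if (any(res$expected < 5)) {
    warning("expected count below 5; chi-square approximation may be poor")
  }
  list(statistic = unname(res$statistic), df = 1L, p = res$p.value,
       expected = res$expected)
}

# Collapse manifest region features to promoter / body / intergenic.
region_3way <- function(region_feature) {
  ifelse(region_feature %in% PROMOTER_FEATURES, "promoter",
         ifelse(region_feature %in% BODY_FEATURES, "body", "intergenic"))
}

#' Genomic-region enrichment of differentially methylated CpGs
#'
#' For each category of the chosen partition (CpG-island relation, or the
#' three-way genic collapse promoter / gene body / intergenic), tests whether
#' membership in the category is associated with being a DMC by a four-field
#' chi-square over the tested universe. Fold is the DMC fraction in the
#' category divided by the universe fraction.
#'
#' @param dmc Character vector of significant probe ids (subset of
#'   `universe`).
#' @param universe Character vector of all tested probe ids.
#' @param ann Probe annotation covering the universe.
#' @param partition `"island_relation"` or `"gene_region_3way"`.
#' @return data.frame per category: `category, n_dmc, n_universe, fold,
#'   statistic, p`. With an empty `dmc`, folds and p-values are missing.
#' @export
region_enrichment <- function(dmc, universe, ann,
                              partition = c("island_relation", "gene_region_3way")) {
  partition <- match.arg(partition)
  if (!all(dmc %in% universe)) stop("dmc must be a subset of the universe")
  a <- ann[match(universe, ann$probe_id), , drop = FALSE]
  if (anyNA(a$probe_id)) stop("universe probes missing from annotation")
  cat_of <- switch(partition,
                   island_relation = a$island_relation,
                   gene_region_3way = region_3way(a$region_feature))
  categories <- switch(partition,
                       island_relation = ISLAND_RELATIONS,
                       gene_region_3way = c("promoter", "body", "intergenic"))
  is_dmc <- universe %in% dmc
  n_d <- length(dmc)
  n_u <- length(universe)
  rows <- lapply(categories, function(cc) {
    inc <- cat_of == cc
    n_cat <- sum(inc)
    n_dmc_in <- sum(inc & is_dmc)
    if (n_d == 0L || n_cat == 0L) {
      return(data.frame(category = cc, n_dmc = n_dmc_in, n_universe = n_cat,
                        fold = NA_real_, statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    fold <- (n_dmc_in / n_d) / (n_cat / n_u)
    tab <- two_by_two(n_dmc_in, n_cat - n_dmc_in,
                      n_d - n_dmc_in, (n_u - n_cat) - (n_d - n_dmc_in))
    ch <- suppressWarnings(chisq_2x2(tab))
    data.frame(category = cc, n_dmc = n_dmc_in, n_universe = n_cat,
               fold = fold, statistic = ch$statistic, p = ch$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of significant CpGs that are hypomethylated
#'
#' @param tab A methylation differential table ([diff_methylation()]).
#' @return Fraction of significant probes with negative delta-beta; a zero
#'   delta-beta counts as hypermethylated (tie convention). `NA` when no
#'   probe is significant.
#' @export
hypo_fraction <- function(tab) {
  sig <- tab[tab$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(NA_real_)
  mean(sig$effect < 0)
}

#' Reprogramming enrichment of transiently expressed genes
#'
#' Tests whether genes with transiently altered expression (significant at 2
#' weeks, back to baseline later) are over-represented among genes carrying
#' differentially methylated CpGs at 52 weeks, by a four-field chi-square
#' over the gene universe.
#'
#' @param transient_genes Character vector (subset of `universe`).
#' @param meth_genes_52w Character vector of genes with >= 1 DMC at 52 weeks.
#' @param universe Character vector of all analyzed genes.
#' @param yates Continuity correction for the chi-square (default `FALSE`).
#' @return List `(fraction, table, statistic, p)`; `fraction` is
#'   `|transient intersect methylated| / |transient|`.
#' @export
reprogramming_enrichment <- function(transient_genes, meth_genes_52w, universe,
                                     yates = FALSE) {
  if (length(transient_genes) == 0L) {
    return(list(fraction = NA_real_, table = NULL, statistic = NA_real_, p = NA_real_))
  }
  if (!all(transient_genes %in% universe)) {
    stop("transient genes must be a subset of the universe")
  }
  meth <- intersect(meth_genes_52w, universe)
  a <- length(intersect(transient_genes, meth))
  b <- length(transient_genes) - a
  c <- length(meth) - a
  d <- length(universe) - a - b - c
  tab <- two_by_two(a, b, c, d)
  ch <- suppressWarnings(chisq_2x2(tab, yates = yates))
  list(fraction = a / length(transient_genes), table = tab,
       statistic = ch$statistic, p = ch$p)
}

#' Gene-set over-representation (one-sided Fisher / hypergeometric)
#'
#' Upper-tail hypergeometric p-value for the overlap between a hit list and a
#' gene set within a universe, with the sample odds ratio of the 2x2 table.
#'
#' @param hits Character vector of selected genes (subset of `universe`).
#' @param gene_set Character vector defining the set (subset of `universe`).
#' @param universe Character vector of all genes.
#' @return List `(overlap, odds_ratio, p, table)`.
#' @export
fisher_ora <- function(hits, gene_set, universe) {
  if (length(universe) == 0L) stop("fisher_ora: empty universe")
  hits <- intersect(hits, universe)
  gene_set <- intersect(gene_set, universe)
  a <- length(intersect(hits, gene_set))
  b <- length(hits) - a
  c <- length(gene_set) - a
  d <- length(universe) - a - b - c
  p <- stats::phyper(a - 1L, length(gene_set), length(universe) - length(gene_set),
                     length(hits), lower.tail = FALSE)
  or <- (a * d) / (b * c)
  list(overlap = a, odds_ratio = or, p = p, table = two_by_two(a, b, c, d))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name, description,
#' member...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}
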