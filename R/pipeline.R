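# End-to-end orchestration: QC -> differential -> temporal classification ->
# enrichment -> integration -> reprogramming -> phenotype association, with a
# machine-readable run report.

#' Pipeline configuration
#'
#' Either a simulation configuration (`sim`) or a set of input paths
#' (`paths`: named list with `sample_sheet`, `expression`, `beta`,
#' `annotation`, `phenotypes`) must be provided.
#'
#' @param sim A [sim_config()], or `NULL` in real-data mode.
#' @param paths Named list of input file paths, or `NULL` in simulation mode.
#' @param alpha_expr Unadjusted-p threshold for expression calls.
#' @param alpha_q_meth FDR (BH q) threshold for methylation calls.
#' @param min_cpgs,min_abs_delta_beta_pp Candidate-filter thresholds.
#' @param promoter_zone,body_zone Region features of the two genic zones.
#' @param assoc_scheme Observation scheme for phenotype correlations.
#' @param assoc_phenotypes Phenotype columns to correlate.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            alpha_expr = 0.05, alpha_q_meth = 0.05,
                            min_cpgs = 2L, min_abs_delta_beta_pp = 5,
                            promoter_zone = PROMOTER_FEATURES,
                            body_zone = BODY_FEATURES,
                            assoc_scheme = "pooled_levels",
                            assoc_phenotypes = c("BMI", "M_value", "glucose",
                                                 "FFA", "HMW_adiponectin", "CSA")) {
  if (is.null(sim) && is.null(paths)) stop("provide either sim or paths")
  thresholds <- c(alpha_expr, alpha_q_meth)
  if (any(thresholds <= 0 | thresholds > 1)) stop("alpha thresholds must be in (0, 1]")
  if (min_cpgs < 1L || min_abs_delta_beta_pp < 0) stop("invalid candidate thresholds")
  structure(list(sim = sim, paths = paths, alpha_expr = alpha_expr,
                 alpha_q_meth = alpha_q_meth, min_cpgs = as.integer(min_cpgs),
                 min_abs_delta_beta_pp = min_abs_delta_beta_pp,
                 promoter_zone = promoter_zone, body_zone = body_zone,
                 assoc_scheme = assoc_scheme, assoc_phenotypes = assoc_phenotypes),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    for (f in c("sample_sheet", "expression", "beta", "annotation", "phenotypes")) {
      if (is.null(p[[f]]) || !file.exists(p[[f]])) {
        stop("pipeline input '", f, "' missing or not found: ",
             if (is.null(p[[f]])) "(no path given)" else p[[f]])
      }
    }
    list(sheet = read_sample_sheet(p$sample_sheet),
         expression = read_matrix(p$expression, "expression"),
         beta = read_matrix(p$beta, "beta"),
         annotation = read_annotation(p$annotation),
         phenotypes = read_phenotypes(p$phenotypes),
         truth = NULL)
  } else {
    generate_cohort(config$sim)
  }
}

#' Run the full integration pipeline
#'
#' Executes all stages in dependency order on simulated or supplied data:
#' probe QC (paired mode), differential expression at 2/12/24/52 weeks vs
#' baseline, differential methylation at 2 and 52 weeks, temporal gene
#' classification, hypomethylation fractions and genomic-region enrichment,
#' methylation-expression concordance and candidate filtering at 52 weeks,
#' reprogramming enrichment of transient genes, derived clinical indices,
#' and phenotype correlations. Finishes with an internal audit that
#' recomputes every reported count from the stage tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all stage tables are
#'   written as TSV/CSV and the report as `report.json`.
#' @return List with `report` (the machine-readable summary) and `stages`
#'   (all intermediate tables).
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dat <- load_pipeline_inputs(config)
  sheet <- dat$sheet

  qc <- filter_probes(dat$beta, dat$annotation, analysis_mode = "paired")

  tps <- c(2L, 12L, 24L, 52L)
  de <- lapply(tps, function(tp) {
    diff_expression(dat$expression, sheet, paired_contrast(tp),
                    alpha = config$alpha_expr)
  })
  names(de) <- as.character(tps)
  dm <- lapply(c(2L, 52L), function(tp) {
    diff_methylation(qc$beta, sheet, paired_contrast(tp),
                     alpha_q = config$alpha_q_meth)
  })
  names(dm) <- c("2", "52")

  classification <- classify_genes(de, alpha = config$alpha_expr)
  cls_counts <- temporal_counts(classification)

  dmc52 <- dm[["52"]]$feature[dm[["52"]]$significant]
  enr_island <- region_enrichment(dmc52, dm[["52"]]$feature, dat$annotation,
                                  "island_relation")
  enr_region <- region_enrichment(dmc52, dm[["52"]]$feature, dat$annotation,
                                  "gene_region_3way")

  deg52 <- de[["52"]]$feature[de[["52"]]$significant]
  summaries <- summarize_gene_methylation(dm[["52"]], dat$annotation,
                                          gene_universe = deg52)
  conc <- concordance(de[["52"]], summaries, dat$annotation,
                      promoter_zone = config$promoter_zone,
                      body_zone = config$body_zone)
  candidates <- candidate_filter(summaries, conc,
                                 min_cpgs = config$min_cpgs,
                                 min_abs_delta_beta_pp = config$min_abs_delta_beta_pp)

  transient <- classification$gene[classification$class == "transient_2w"]
  meth_genes <- unique(summaries$links$gene_id)
  repro <- reprogramming_enrichment(transient, meth_genes,
                                    universe = classification$gene)

  clinical <- derive_clinical(dat$phenotypes)
  assoc <- correlate_features(dat$expression, dat$phenotypes, sheet,
                              config$assoc_phenotypes,
                              scheme = config$assoc_scheme,
                              alpha = config$alpha_expr)
  assoc_meth <- correlate_features(qc$beta, dat$phenotypes, sheet,
                                   config$assoc_phenotypes,
                                   scheme = config$assoc_scheme,
                                   alpha = config$alpha_expr,
                                   ann = dat$annotation)

  report <- list(
    package_version = as.character(utils::packageVersion("metasurg")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    config = list(alpha_expr = config$alpha_expr,
                  alpha_q_meth = config$alpha_q_meth,
                  min_cpgs = config$min_cpgs,
                  min_abs_delta_beta_pp = config$min_abs_delta_beta_pp,
                  assoc_scheme = config$assoc_scheme),
    n_probes_tested = nrow(qc$beta),
    n_probes_removed = nrow(qc$log),
    deg_counts = lapply(de, diff_counts),
    temporal_class_counts = as.list(cls_counts),
    dmc_counts = lapply(dm, diff_counts),
    hypo_fraction = lapply(dm, hypo_fraction),
    region_enrichment = list(island_relation = enr_island,
                             gene_region_3way = enr_region),
    integration = list(n_cpg_gene_links = summaries$totals$n_links,
                       n_unique_dmc_probes_linked = summaries$totals$n_unique_probes,
                       n_deg_genes_with_dmc = summaries$totals$n_genes,
                       concordance_class_counts =
                         as.list(table(factor(conc$class,
                                              levels = c("concordant_promoter",
                                                         "concordant_body",
                                                         "discordant", "mixed",
                                                         "unlinked")))),
                       n_candidates = nrow(candidates)),
    reprogramming = list(fraction = repro$fraction,
                         statistic = repro$statistic, p = repro$p),
    phenotype_assoc = list(expression_counts = as.list(assoc$counts),
                           methylation_gene_counts = as.list(assoc_meth$gene_counts))
  )

  stages <- list(qc_log = qc$log, de = de, dm = dm,
                 classification = classification, enr_island = enr_island,
                 enr_region = enr_region, summaries = summaries,
                 concordance = conc, candidates = candidates,
                 reprogramming = repro, clinical = clinical,
                 assoc_expression = assoc, assoc_methylation = assoc_meth,
                 truth = dat$truth)

  audit_report(report, stages)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(qc$log, file.path(out_dir, "qc_removed_probes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (tp in names(de)) {
      utils::write.table(de[[tp]], file.path(out_dir, paste0("diff_expr_", tp, "w.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (tp in names(dm)) {
      utils::write.table(dm[[tp]], file.path(out_dir, paste0("diff_meth_", tp, "w.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(classification, file.path(out_dir, "temporal_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assoc$table, file.path(out_dir, "phenotype_assoc_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_phenotypes(clinical, file.path(out_dir, "clinical_derived.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  list(report = report, stages = stages)
}

# Recompute every reported count from the stage tables; abort on mismatch.
audit_report <- function(report, stages) {
  for (tp in names(stages$de)) {
    cnt <- diff_counts(stages$de[[tp]])
    stopifnot(identical(cnt, report$deg_counts[[tp]]))
  }
  for (tp in names(stages$dm)) {
    cnt <- diff_counts(stages$dm[[tp]])
    stopifnot(identical(cnt, report$dmc_counts[[tp]]))
  }
  stopifnot(report$integration$n_candidates == nrow(stages$candidates))
  cls <- table(stages$classification$class)
  for (cl in TEMPORAL_CLASSES) {
    stopifnot(report$temporal_class_counts[[cl]] ==
                (if (cl %in% names(cls)) cls[[cl]] else 0L))
  }
  invisible(TRUE)
}
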