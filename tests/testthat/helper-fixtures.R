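# Shared fixtures: small in-memory tables and a reduced synthetic cohort
# (kept small so unit tests run in seconds; acceptance tests use defaults).

small_sheet <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c("CON01", "CON02", "CON03",
                  paste0(rep(c("OB01", "OB02", "OB03", "OB04"), each = 2),
                         "_w", rep(c(0, 52), 4))),
    subject_id = c("CON01", "CON02", "CON03",
                   rep(c("OB01", "OB02", "OB03", "OB04"), each = 2)),
    group = c(rep("CON", 3), rep("OB", 8)),
    timepoint_weeks = c(rep(0L, 3), rep(c(0L, 52L), 4)),
    stringsAsFactors = FALSE))
}

small_annotation <- function() {
  validate_annotation(data.frame(
    probe_id = sprintf("cg%02d", 1:8),
    chromosome = c("1", "2", "X", "7", "chr3", "11", "Y", "5"),
    position = 1000L * (1:8),
    gene_symbols = c("PTPRE", "PIK3R1;MLXIP", "", "ACACB", "PTPRE", "", "IMMP2L", "HMGCS2"),
    region_feature = c("TSS200", "Body", "IGR", "UTR3", "Body", "IGR", "TSS1500", "FirstExon"),
    island_relation = c("Island", "OpenSea", "Shore", "Shelf", "OpenSea", "OpenSea",
                        "Island", "Shore"),
    snp_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

small_cohort <- function(seed = 101, ...) {
  generate_cohort(sim_config(n_con = 6L, n_ob = 10L, n_genes = 200L,
                             n_probes = 2000L, seed = seed, ...))
}

# Cohort at the study's omics sample size (n_ob = 16) for power-sensitive
# recovery checks; gene/probe counts reduced to keep tests fast.
power_cohort <- function(seed = 101, ...) {
  generate_cohort(sim_config(n_con = 6L, n_ob = 16L, n_genes = 400L,
                             n_probes = 4000L, seed = seed, ...))
}

# Convenience: differential tables at all four timepoints for a cohort.
all_timepoint_de <- function(cohort, alpha = 0.05) {
  de <- lapply(c(2L, 12L, 24L, 52L), function(tp) {
    diff_expression(cohort$expression, cohort$sheet, paired_contrast(tp),
                    alpha = alpha)
  })
  names(de) <- c("2", "12", "24", "52")
  de
}

# Build a differential table directly (for rule-level tests).
fake_diff_table <- function(feature, p, effect = NULL, q = NULL,
                            significant = NULL, alpha = 0.05) {
  if (is.null(effect)) effect <- rep(1, length(feature))
  if (is.null(q)) q <- rep(NA_real_, length(feature))
  if (is.null(significant)) significant <- !is.na(p) & p < alpha
  data.frame(feature = feature, effect = effect, t = NA_real_, df = NA_real_,
             p = p, q = q,
             direction = ifelse(effect < 0, "down", "up"),
             n = 16L, significant = significant, stringsAsFactors = FALSE)
}
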