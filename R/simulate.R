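# Synthetic longitudinal cohort with planted, recorded effects.
#
# The generator emulates the statistical structure of a paired five-timepoint
# metabolic-surgery cohort: log-scale expression with per-gene baselines and
# subject random intercepts; beta-valued methylation built on the logit scale
# with subject random effects and probe noise; planted effect genes of three
# temporal classes (transient at 2 weeks, constant, late at 52 weeks) whose
# 52-week methylation shifts follow the promoter/gene-body direction rules
# used by the integration stage; and clinical phenotype trajectories
# (post-surgical FFA spike at 2 weeks, late insulin-sensitivity improvement).


#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated under:
#' 16 obese (OB) subjects with omics at weeks 0/2/12/24/52, 14 controls (CON)
#' sampled once, 2,000 genes and 20,000 probes, 5% transient and 1% constant
#' expression effect genes, 5% of genes with late methylation-coupled
#' effects, unit expression shifts (on the paired-difference SD scale) and
#' 10-percentage-point planted beta shifts at 52 weeks.
#'
#' @param n_con,n_ob Number of control / obese subjects.
#' @param n_genes,n_probes Number of genes / methylation probes.
#' @param frac_transient,frac_constant,frac_late_meth_coupled Fractions of
#'   genes planted in each effect class (must sum to at most 1).
#' @param expr_effect_sd_units Planted expression shift, in units of the SD
#'   of a within-subject difference (`sqrt(2) * expr_noise_sd`), the noise
#'   scale relevant to the paired design.
#' @param delta_beta_pp Planted 52-week methylation shift, beta-scale
#'   percentage points; the shifted value is clipped to \[0.01, 0.99\] and
#'   planting is restricted to probes whose baseline leaves room for the full
#'   shift, so planted |delta-beta| always equals `delta_beta_pp`.
#' @param probe_noise_sd_logit,subject_re_sd_logit Logit-scale SDs of the
#'   per-measurement probe noise and the per-(subject, probe) random effect.
#' @param expr_noise_sd,expr_subject_re_sd Log-scale SDs of the expression
#'   residual and subject random intercept.
#' @param pheno_noise_scale Multiplier on the phenotype noise SDs (0 gives
#'   noise-free trajectories equal to the configured means).
#' @param frac_igr,frac_xy,frac_snp,frac_multigene Manifest composition:
#'   fractions of intergenic probes, sex-chromosome probes, SNP-flagged
#'   probes and two-gene probes.
#' @param probes_per_effect_gene Number of methylation probes planted per
#'   effect gene (at least 2).
#' @param seed Integer RNG seed; identical configurations give identical
#'   cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_con = 14L, n_ob = 16L,
                       n_genes = 2000L, n_probes = 20000L,
                       frac_transient = 0.05, frac_constant = 0.01,
                       frac_late_meth_coupled = 0.05,
                       expr_effect_sd_units = 1.0, delta_beta_pp = 10,
                       probe_noise_sd_logit = 0.3, subject_re_sd_logit = 0.2,
                       expr_noise_sd = 0.7, expr_subject_re_sd = 0.5,
                       pheno_noise_scale = 1.0,
                       frac_igr = 0.25, frac_xy = 0.05, frac_snp = 0.03,
                       frac_multigene = 0.02,
                       probes_per_effect_gene = 3L,
                       seed = 1L) {
  cfg <- list(n_con = as.integer(n_con), n_ob = as.integer(n_ob),
              n_genes = as.integer(n_genes), n_probes = as.integer(n_probes),
              frac_transient = frac_transient, frac_constant = frac_constant,
              frac_late_meth_coupled = frac_late_meth_coupled,
              expr_effect_sd_units = expr_effect_sd_units,
              delta_beta_pp = delta_beta_pp,
              probe_noise_sd_logit = probe_noise_sd_logit,
              subject_re_sd_logit = subject_re_sd_logit,
              expr_noise_sd = expr_noise_sd,
              expr_subject_re_sd = expr_subject_re_sd,
              pheno_noise_scale = pheno_noise_scale,
              frac_igr = frac_igr, frac_xy = frac_xy, frac_snp = frac_snp,
              frac_multigene = frac_multigene,
              probes_per_effect_gene = as.integer(probes_per_effect_gene),
              seed = as.integer(seed))
  fr <- cfg$frac_transient + cfg$frac_constant + cfg$frac_late_meth_coupled
  if (fr > 1) stop("effect fractions sum to ", fr, " (> 1)")
  if (any(c(cfg$frac_transient, cfg$frac_constant, cfg$frac_late_meth_coupled) < 0)) {
    stop("effect fractions must be non-negative")
  }
  if (cfg$n_ob < 2L) stop("n_ob must be at least 2")
  sds <- c(cfg$probe_noise_sd_logit, cfg$subject_re_sd_logit,
           cfg$expr_noise_sd, cfg$expr_subject_re_sd)
  if (any(sds <= 0)) stop("all noise SDs must be > 0")
  if (cfg$delta_beta_pp <= 0 || cfg$delta_beta_pp >= 49) {
    stop("delta_beta_pp must be in (0, 49) percentage points")
  }
  if (cfg$probes_per_effect_gene < 2L) stop("probes_per_effect_gene must be >= 2")
  if (cfg$pheno_noise_scale < 0) stop("pheno_noise_scale must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Reference phenotype trajectories of the simulated cohort
#'
#' Group means used by [generate_cohort()]: OB values per timepoint (weeks
#' 0/2/12/24/52) emulating a severely obese surgical cohort with a transient
#' free-fatty-acid spike at 2 weeks and late improvement of the clamp
#' M-value, CON values for lean controls, and the between-subject noise SDs
#' applied on top.
#'
#' @return List with data.frame `ob` (one row per timepoint), one-row
#'   data.frame `con`, and named numeric `sd`.
#' @export
reference_phenotype_trajectories <- function() {
  ob <- data.frame(
    timepoint_weeks = STUDY_TIMEPOINTS,
    body_weight = c(154, 143, 127, 115, 101),
    BMI = c(51.4, 47.6, 42.3, 38.5, 33.9),
    glucose = c(98, 93, 84, 83, 80),
    insulin = c(21, 22, 12, 10, 9),
    FFA = c(676, 1057, 699, 643, 527),
    HbA1c = c(5.8, 5.5, 5.3, 5.2, 5.2),
    HMW_adiponectin = c(1432, 2170, 2708, 3217, 4025),
    M_value = c(2.0, 2.0, 2.5, 3.5, 6.0),
    RQ_basal = c(0.80, 0.80, 0.80, 0.80, 0.80),
    RQ_clamp = c(0.87, 0.85, 0.88, 0.92, 0.96),
    state3 = c(22, 18, 21, 22, 22),
    state4 = c(8, 11, 8, 8, 8),
    state_u = c(26, 23.4, 25, 26, 26),
    CSA = c(150, 120, 140, 150, 150)
  )
  con <- data.frame(
    timepoint_weeks = 0L,
    body_weight = 75, BMI = 24.5, glucose = 79, insulin = 6, FFA = 492,
    HbA1c = 5.2, HMW_adiponectin = 3181, M_value = 6.5,
    RQ_basal = 0.80, RQ_clamp = 0.92,
    state3 = 25, state4 = 8, state_u = 32, CSA = 155
  )
  sd <- c(body_weight = 20, BMI = 6, glucose = 12, insulin = 6, FFA = 120,
          HbA1c = 0.4, HMW_adiponectin = 800, M_value = 1.0,
          RQ_basal = 0.03, RQ_clamp = 0.04,
          state3 = 4, state4 = 1.5, state_u = 5, CSA = 25)
  list(ob = ob, con = con, sd = sd)
}

logit <- function(p) log(p / (1 - p))

# Split an effect-class total into up/down counts (up gets the ceiling).
split_updown <- function(n) c(up = ceiling(n / 2), down = floor(n / 2))

#' Generate a complete synthetic study
#'
#' Produces a self-consistent set of study tables: sample sheet, phenotype
#' table, expression matrix, beta matrix, probe annotation, and the planted
#' ground truth. Effect genes are shifted on the expression side (transient:
#' week 2 only; constant: all post-surgery weeks; late-coupled: week 52 only)
#' and carry `probes_per_effect_gene` planted 52-week methylation shifts each,
#' with signs that satisfy the promoter/gene-body concordance rules (promoter
#' probes hypomethylated for upregulated genes, gene-body probes
#' hypermethylated, and mirrored for downregulated genes).
#'
#' @param config A [sim_config()].
#' @return List with elements `sheet`, `phenotypes`, `expression`, `beta`,
#'   `annotation`, `truth` (list: `gene_class` named character vector,
#'   `dmc_probes` data.frame of planted probes with signed `delta_beta_pp`),
#'   and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  ## --- design -------------------------------------------------------------
  con_subj <- sprintf("CON%02d", seq_len(config$n_con))
  ob_subj <- sprintf("OB%02d", seq_len(config$n_ob))
  sheet <- rbind(
    data.frame(sample_id = con_subj, subject_id = con_subj, group = "CON",
               timepoint_weeks = 0L, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(rep(ob_subj, each = 5L), "_w",
                                  rep(STUDY_TIMEPOINTS, times = config$n_ob)),
               subject_id = rep(ob_subj, each = 5L), group = "OB",
               timepoint_weeks = rep(STUDY_TIMEPOINTS, times = config$n_ob),
               stringsAsFactors = FALSE)
  )
  sheet$sex <- "unknown"
  sheet$sex[sheet$group == "CON"] <-
    rep(sample(c("M", "F"), config$n_con, replace = TRUE, prob = c(0.64, 0.36)),
        times = 1L)
  ob_sex <- sample(c("M", "F"), config$n_ob, replace = TRUE, prob = c(0.3, 0.7))
  sheet$sex[sheet$group == "OB"] <- rep(ob_sex, each = 5L)
  sheet <- validate_sample_sheet(sheet)
  n_samples <- nrow(sheet)

  ## --- probe annotation ---------------------------------------------------
  np <- config$n_probes
  probe_id <- sprintf("cg%08d", seq_len(np))
  n_xy <- round(config$frac_xy * np)
  chromosome <- sample(as.character(1:22), np, replace = TRUE)
  if (n_xy > 0L) {
    xy_idx <- sample.int(np, n_xy)
    chromosome[xy_idx] <- sample(c("X", "Y"), n_xy, replace = TRUE, prob = c(0.8, 0.2))
  }
  position <- sample.int(2e8L, np, replace = TRUE)
  snp_flag <- runif(np) < config$frac_snp
  igr <- runif(np) < config$frac_igr
  island_relation <- sample(ISLAND_RELATIONS, np, replace = TRUE,
                            prob = c(0.2, 0.2, 0.1, 0.5))
  region_feature <- rep("IGR", np)
  genic <- which(!igr)
  region_feature[genic] <- sample(setdiff(REGION_FEATURES, "IGR"), length(genic),
                                  replace = TRUE,
                                  prob = c(0.12, 0.12, 0.08, 0.05, 0.55, 0.08))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  gene_symbols <- rep("", np)
  # round-robin assignment of genic probes to genes
  gene_symbols[genic] <- gene_ids[((seq_along(genic) - 1L) %% config$n_genes) + 1L]
  multi <- genic[runif(length(genic)) < config$frac_multigene]
  if (length(multi) > 0L) {
    second <- gene_ids[(match(gene_symbols[multi], gene_ids) %% config$n_genes) + 1L]
    gene_symbols[multi] <- paste(gene_symbols[multi], second, sep = ";")
  }
  annotation <- validate_annotation(data.frame(
    probe_id = probe_id, chromosome = chromosome, position = position,
    gene_symbols = gene_symbols, region_feature = region_feature,
    island_relation = island_relation, snp_flag = snp_flag,
    stringsAsFactors = FALSE))

  ## --- probe baselines (logit scale, bimodal like array data) -------------
  mode <- sample.int(3L, np, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu_logit <- numeric(np)
  mu_logit[mode == 1L] <- stats::rnorm(sum(mode == 1L), -2.5, 0.7)  # lowly methylated
  mu_logit[mode == 2L] <- stats::rnorm(sum(mode == 2L), 2.5, 0.7)   # highly methylated
  mu_logit[mode == 3L] <- stats::rnorm(sum(mode == 3L), 0, 1.2)     # intermediate
  baseline_beta <- stats::plogis(mu_logit)

  ## --- effect genes and planted probes ------------------------------------
  n_tr <- floor(config$frac_transient * config$n_genes)
  n_co <- floor(config$frac_constant * config$n_genes)
  n_la <- floor(config$frac_late_meth_coupled * config$n_genes)
  class_pool <- c(rep("transient", n_tr), rep("constant", n_co), rep("late_coupled", n_la))
  sign_pool <- unlist(lapply(c(n_tr, n_co, n_la), function(n) {
    ud <- split_updown(n)
    c(rep(1, ud["up"]), rep(-1, ud["down"]))
  }), use.names = FALSE)

  delta <- config$delta_beta_pp / 100
  k <- config$probes_per_effect_gene
  # probes eligible for planting: autosomal, non-SNP, genic, with room for a
  # full beta shift in the planted direction
  first_gene <- vapply(split_gene_symbols(annotation$gene_symbols),
                       function(g) if (length(g) > 0L) g[1L] else "", "")
  eligible_base <- annotation$chromosome %in% as.character(1:22) &
    !annotation$snp_flag & nzchar(first_gene)
  zone <- ifelse(annotation$region_feature %in% PROMOTER_FEATURES, "promoter",
                 ifelse(annotation$region_feature %in% BODY_FEATURES, "body", "igr"))

  gene_class <- stats::setNames(rep("null", config$n_genes), gene_ids)
  dmc_rows <- vector("list", length(class_pool))
  if (length(class_pool) > 0L) {
    probe_gene <- split(seq_len(np)[eligible_base], first_gene[eligible_base])
    shuffled_genes <- sample(gene_ids)
    gi <- 1L
    for (e in seq_along(class_pool)) {
      s <- sign_pool[e]
      planted <- NULL
      while (gi <= length(shuffled_genes)) {
        g <- shuffled_genes[gi]
        gi <- gi + 1L
        idx <- probe_gene[[g]]
        if (is.null(idx)) next
        # planted shift sign per probe zone: promoter opposes expression,
        # body follows it
        psign <- ifelse(zone[idx] == "promoter", -s, s)
        room <- ifelse(psign > 0, baseline_beta[idx] <= 0.99 - delta,
                       baseline_beta[idx] >= 0.01 + delta)
        ok <- idx[room & zone[idx] != "igr"]
        if (length(ok) >= k) {
          pick <- if (length(ok) == k) ok else sample(ok, k)
          planted <- data.frame(
            probe_id = annotation$probe_id[pick],
            gene_id = g,
            zone = zone[pick],
            delta_beta_pp = 100 * delta * ifelse(zone[pick] == "promoter", -s, s),
            stringsAsFactors = FALSE)
          gene_class[g] <- paste0(class_pool[e], ifelse(s > 0, "_up", "_down"))
          break
        }
      }
      if (is.null(planted)) {
        stop("could not find ", k, " eligible probes for every effect gene; ",
             "increase n_probes or lower probes_per_effect_gene")
      }
      dmc_rows[[e]] <- planted
    }
  }
  dmc_probes <- if (length(dmc_rows) > 0L) do.call(rbind, dmc_rows) else
    data.frame(probe_id = character(), gene_id = character(), zone = character(),
               delta_beta_pp = numeric(), stringsAsFactors = FALSE)

  ## --- expression matrix --------------------------------------------------
  gene_base <- stats::rnorm(config$n_genes, 7, 1.5)
  subj_all <- unique(sheet$subject_id)
  expr_re <- stats::setNames(stats::rnorm(length(subj_all), 0, config$expr_subject_re_sd),
                             subj_all)
  expr <- matrix(stats::rnorm(config$n_genes * n_samples, 0, config$expr_noise_sd),
                 nrow = config$n_genes, ncol = n_samples,
                 dimnames = list(gene_ids, sheet$sample_id))
  expr <- expr + gene_base +
    matrix(expr_re[sheet$subject_id], nrow = config$n_genes,
           ncol = n_samples, byrow = TRUE)
  # effect size in units of the paired-design noise scale: the SD of a
  # within-subject difference of two measurements
  eff <- config$expr_effect_sd_units * sqrt(2) * config$expr_noise_sd
  is_ob <- sheet$group == "OB"
  tp <- sheet$timepoint_weeks
  for (cls in names(which(gene_class != "null"))) {
    cl <- gene_class[cls]
    s <- if (grepl("_up$", cl)) 1 else -1
    cols <- switch(sub("_(up|down)$", "", cl),
                   transient = is_ob & tp == 2L,
                   constant = is_ob & tp > 0L,
                   late_coupled = is_ob & tp == 52L)
    expr[cls, cols] <- expr[cls, cols] + s * eff
  }

  ## --- beta matrix ---------------------------------------------------------
  meth_re <- matrix(stats::rnorm(np * length(subj_all), 0, config$subject_re_sd_logit),
                    nrow = np, ncol = length(subj_all),
                    dimnames = list(probe_id, subj_all))
  noise <- matrix(stats::rnorm(np * n_samples, 0, config$probe_noise_sd_logit),
                  nrow = np, ncol = n_samples)
  beta <- stats::plogis(mu_logit + meth_re[, sheet$subject_id] + noise)
  dimnames(beta) <- list(probe_id, sheet$sample_id)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  if (nrow(dmc_probes) > 0L) {
    w52 <- which(is_ob & tp == 52L)
    pidx <- match(dmc_probes$probe_id, probe_id)
    beta[pidx, w52] <- beta[pidx, w52] + dmc_probes$delta_beta_pp / 100
    beta <- pmin(pmax(beta, 0.01), 0.99)
  }

  ## --- phenotypes ----------------------------------------------------------
  ref <- reference_phenotype_trajectories()
  pheno_names <- setdiff(names(ref$sd), NULL)
  scale <- config$pheno_noise_scale
  rows_con <- data.frame(subject_id = con_subj, timepoint_weeks = 0L,
                         stringsAsFactors = FALSE)
  rows_ob <- data.frame(subject_id = rep(ob_subj, each = 5L),
                        timepoint_weeks = rep(STUDY_TIMEPOINTS, times = config$n_ob),
                        stringsAsFactors = FALSE)
  pheno <- rbind(rows_con, rows_ob)
  height <- c(stats::setNames(stats::rnorm(config$n_con, 1.75, 0.07 * scale), con_subj),
              stats::setNames(stats::rnorm(config$n_ob, 1.73, 0.07 * scale), ob_subj))
  pheno$height <- round(height[pheno$subject_id], 3)
  for (ph in pheno_names) {
    sd_between <- 0.8 * ref$sd[[ph]] * scale
    sd_within <- 0.4 * ref$sd[[ph]] * scale
    re <- c(stats::setNames(stats::rnorm(config$n_con, 0, sd_between), con_subj),
            stats::setNames(stats::rnorm(config$n_ob, 0, sd_between), ob_subj))
    mu <- ifelse(pheno$subject_id %in% con_subj,
                 ref$con[[ph]],
                 ref$ob[[ph]][match(pheno$timepoint_weeks, ref$ob$timepoint_weeks)])
    v <- mu + re[pheno$subject_id] + stats::rnorm(nrow(pheno), 0, sd_within)
    if (ph %in% NONNEGATIVE_PHENOTYPES) v <- pmax(v, 0)
    if (ph %in% RQ_PHENOTYPES) v <- pmin(pmax(v, RQ_RANGE[1L]), RQ_RANGE[2L])
    pheno[[ph]] <- v
  }
  pheno <- validate_phenotypes(pheno)

  list(sheet = sheet, phenotypes = pheno, expression = expr, beta = beta,
       annotation = annotation,
       truth = list(gene_class = gene_class, dmc_probes = dmc_probes),
       config = config)
}

#' Generate a null cohort (no planted effects)
#'
#' Identical to [generate_cohort()] with all effect fractions forced to zero;
#' useful as a type-I-error / false-discovery harness.
#'
#' @param config A [sim_config()]; its effect fractions are ignored.
#' @return Same structure as [generate_cohort()]; `truth$gene_class` is all
#'   `"null"` and `truth$dmc_probes` is empty.
#' @export
null_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  config$frac_transient <- 0
  config$frac_constant <- 0
  config$frac_late_meth_coupled <- 0
  generate_cohort(config)
}

#' Write a generated cohort to a directory
#'
#' Serializes all study tables via the package's standard formats plus the
#' planted ground truth (`ground_truth.csv`, `dmc_probes.csv`) and a JSON
#' manifest echoing the configuration and seed.
#'
#' @param cohort Result of [generate_cohort()] or [null_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.csv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  write_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_annotation(cohort$annotation, file.path(dir, "annotation.csv"))
  utils::write.csv(data.frame(gene_id = names(cohort$truth$gene_class),
                              class = unname(cohort$truth$gene_class)),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth$dmc_probes, file.path(dir, "dmc_probes.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
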