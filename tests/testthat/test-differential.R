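test_that("Welch t matches frozen hand values and stats::t.test", {
  r <- welch_t(1:4, 11:14)
  expect_equal(r$df, 6)
  expect_lt(r$p, 1e-4)
  expect_equal(r$effect, 10)

  # oracle equivalence on a grid of small samples
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    r <- welch_t(x, y)
    o <- t.test(y, x)  # effect oriented as second - first group
    expect_equal(r$t, unname(o$statistic), tolerance = 1e-12)
    expect_equal(r$df, unname(o$parameter), tolerance = 1e-12)
    expect_equal(r$p, o$p.value, tolerance = 1e-12)
  }
})

test_that("Welch t degenerate conventions are total and documented", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r <- welch_t(c(0, 0), c(0, 0))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_warning(r <- welch_t(c(0, 0), c(1, 1)), "zero variance")
  expect_equal(r$p, 0)
})

test_that("Welch p agrees with an exhaustive permutation test on tiny samples", {
  # enumeration oracle: all 70 relabelings of 4+4 values, two-sided on |mean diff|
  perm_p <- function(x, y) {
    pool <- c(x, y)
    idx <- utils::combn(8, 4)
    obs <- abs(mean(y) - mean(x))
    stats <- apply(idx, 2, function(i) abs(mean(pool[-i]) - mean(pool[i])))
    mean(stats >= obs - 1e-12)
  }
  set.seed(9)
  for (i in 1:10) {
    x <- round(rnorm(4), 2)
    y <- round(rnorm(4, mean = runif(1, 0, 2)), 2)
    expect_lt(abs(welch_t(x, y)$p - perm_p(x, y)), 0.1)
  }
})

test_that("paired t matches frozen hand values and stats::t.test", {
  # differences 1,2,3,4: t = 2.5 / (1.29099/2) = 3.873, df = 3
  r <- paired_t(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$p, 0.0304663, tolerance = 1e-5)
  expect_equal(r$df, 3)

  set.seed(6)
  for (i in 1:20) {
    b <- rnorm(sample(4:10, 1)); a <- b + rnorm(length(b), 0.3)
    r <- paired_t(b, a)
    o <- t.test(a, b, paired = TRUE)
    expect_equal(r$t, unname(o$statistic), tolerance = 1e-12)
    expect_equal(r$p, o$p.value, tolerance = 1e-12)
  }

  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_warning(r <- paired_t(c(0, 0, 0, 0), c(1, 1, 1, 1)), "zero-variance")
  expect_equal(r$p, 0)
  # incomplete pairs dropped listwise (both surviving diffs are 1, so the
  # zero-variance convention also fires)
  expect_warning(r <- paired_t(c(1, 2, NA, 4), c(2, 3, 5, NA)), "zero-variance")
  expect_equal(r$n, 2)
})

test_that("Benjamini-Hochberg step-up matches hand application", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.2)), c(0.004, 0.02, 0.04, 0.2))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # missing entries excluded from the number of tests
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  # permutation invariance
  set.seed(2)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("differential tables satisfy their structural invariants", {
  co <- small_cohort(seed = 21)
  qc <- filter_probes(co$beta, co$annotation, "paired")
  dm <- diff_methylation(qc$beta, co$sheet, paired_contrast(52))
  expect_true(all(dm$q >= dm$p - 1e-12, na.rm = TRUE))
  expect_true(all(dm$p >= 0 & dm$p <= 1, na.rm = TRUE))
  expect_true(all(abs(dm$effect) <= 100, na.rm = TRUE))
  expect_true(all(dm$direction == ifelse(dm$effect < 0, "down", "up")))
  de <- diff_expression(co$expression, co$sheet, paired_contrast(2))
  expect_true(all(is.na(de$q)))  # expression significance is unadjusted
  expect_setequal(de$feature, rownames(co$expression))
})

test_that("delta-beta is the mean within-subject change in percentage points", {
  sheet <- small_sheet()
  ob <- sheet[sheet$group == "OB", ]
  before <- ob$sample_id[ob$timepoint_weeks == 0]
  after <- ob$sample_id[ob$timepoint_weeks == 52]
  beta <- matrix(NA_real_, 1, nrow(sheet),
                 dimnames = list("cgA", sheet$sample_id))
  beta[1, ] <- 0.3
  beta[1, before] <- c(0.40, 0.45, 0.50, 0.50)  # mean 0.4625
  beta[1, after] <- beta[1, before] + 0.05      # constant +5pp shift
  dm <- diff_methylation(beta, sheet, paired_contrast(52))
  expect_equal(dm$effect, 5)
  expect_equal(dm$direction, "up")
})

test_that("expression power and type-I behaviour on planted and null cohorts", {
  co <- power_cohort(seed = 31)
  de2 <- diff_expression(co$expression, co$sheet, paired_contrast(2))
  tr <- names(co$truth$gene_class)[grepl("^transient", co$truth$gene_class)]
  expect_gte(mean(de2$significant[match(tr, de2$feature)]), 0.8)

  nu <- null_cohort(sim_config(n_con = 6L, n_ob = 10L, n_genes = 500L,
                               n_probes = 500L, seed = 32))
  de_null <- diff_expression(nu$expression, nu$sheet, paired_contrast(2))
  frac <- mean(de_null$significant)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("unpaired contrast compares CON with OB baseline by Welch", {
  co <- small_cohort(seed = 33)
  de <- diff_expression(co$expression, co$sheet, unpaired_contrast())
  g <- rownames(co$expression)[1]
  con <- co$sheet$sample_id[co$sheet$group == "CON"]
  ob0 <- co$sheet$sample_id[co$sheet$group == "OB" & co$sheet$timepoint_weeks == 0]
  o <- t.test(co$expression[g, ob0], co$expression[g, con])
  expect_equal(de$p[de$feature == g], o$p.value, tolerance = 1e-12)
  expect_equal(de$effect[de$feature == g],
               mean(co$expression[g, ob0]) - mean(co$expression[g, con]))
})

test_that("paired testing is more powerful than unpaired on correlated data", {
  # subject random effects induce within-subject correlation; on planted
  # probes the paired test must dominate Welch on the same samples
  co <- small_cohort(seed = 35, subject_re_sd_logit = 0.4)
  sheet <- co$sheet
  ob <- sheet[sheet$group == "OB", ]
  before <- ob$sample_id[ob$timepoint_weeks == 0]
  after <- ob$sample_id[ob$timepoint_weeks == 52]
  planted <- co$truth$dmc_probes$probe_id
  b0 <- co$beta[planted, before, drop = FALSE]
  b52 <- co$beta[planted, after, drop = FALSE]
  p_paired <- vapply(seq_along(planted),
                     function(i) paired_t(b0[i, ], b52[i, ])$p, numeric(1))
  p_welch <- vapply(seq_along(planted),
                    function(i) welch_t(b0[i, ], b52[i, ])$p, numeric(1))
  # dominance on average (log scale) and in detections at a strict threshold
  expect_lt(mean(log(pmax(p_paired, 1e-300))),
            mean(log(pmax(p_welch, 1e-300))))
  expect_gte(sum(p_paired < 1e-3), sum(p_welch < 1e-3))
})
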