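# Per-feature differential statistics: Welch and paired t-tests with the
# study's effect-size and adjustment conventions (expression significance on
# unadjusted p; methylation significance on Benjamini-Hochberg q, effect
# reported as delta-beta in percentage points).

#' Contrast constructors
#'
#' `paired_contrast(tp)` compares OB samples at a follow-up timepoint with
#' the same subjects' baseline by a paired t-test; `unpaired_contrast()`
#' compares CON with OB baseline by Welch's t-test.
#'
#' @param timepoint_weeks Follow-up timepoint, one of 2, 12, 24, 52.
#' @return List of class `contrast` with fields `kind` and (for paired)
#'   `timepoint_weeks`.
#' @export
paired_contrast <- function(timepoint_weeks) {
  timepoint_weeks <- as.integer(timepoint_weeks)
  if (!timepoint_weeks %in% c(2L, 12L, 24L, 52L)) {
    stop("paired contrast timepoint must be one of 2, 12, 24, 52")
  }
  structure(list(kind = "paired_tp_vs_baseline", timepoint_weeks = timepoint_weeks),
            class = "contrast")
}

#' @rdname paired_contrast
#' @export
unpaired_contrast <- function() {
  structure(list(kind = "unpaired_CON_vs_OB0"), class = "contrast")
}

# Row-wise paired t statistics on aligned before/after matrices.
# Conventions for degenerate rows: zero-variance differences with zero mean
# give t = 0, p = 1; zero variance with nonzero mean give t = +-Inf, p = 0
# (with a warning); fewer than 2 complete pairs give missing statistics.
row_paired_t <- function(before, after) {
  stopifnot(all(dim(before) == dim(after)))
  d <- after - before
  n <- rowSums(is.finite(d))
  m <- rowSums(d, na.rm = TRUE) / n
  v <- rowSums((d - m)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[!is.finite(v)] <- NA_real_
  se <- sqrt(v / n)
  t <- m / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- !is.na(v) & v == 0 & n >= 2L
  t[zero_var & m == 0] <- 0
  p[zero_var & m == 0] <- 1
  inf <- zero_var & m != 0
  if (any(inf)) {
    warning(sum(inf), " feature(s) with zero-variance nonzero differences; p set to 0")
    t[inf] <- sign(m[inf]) * Inf
    p[inf] <- 0
  }
  small <- n < 2L
  t[small] <- NA_real_
  p[small] <- NA_real_
  df[small] <- NA_real_
  m[small] <- NA_real_
  list(effect = m, t = t, df = df, p = p, n = n)
}

# Row-wise Welch t statistics on two group matrices.
row_welch_t <- function(x, y) {
  nx <- rowSums(is.finite(x)); ny <- rowSums(is.finite(y))
  mx <- rowSums(x, na.rm = TRUE) / nx
  my <- rowSums(y, na.rm = TRUE) / ny
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1L, 1L)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1L, 1L)
  effect <- my - mx
  sq <- vx / nx + vy / ny
  t <- effect / sqrt(sq)
  df <- sq^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  both_zero <- !is.na(vx) & !is.na(vy) & vx == 0 & vy == 0 & nx >= 2L & ny >= 2L
  eq <- both_zero & effect == 0
  t[eq] <- 0; p[eq] <- 1; df[eq] <- nx[eq] + ny[eq] - 2
  ne <- both_zero & effect != 0
  if (any(ne)) {
    warning(sum(ne), " feature(s) with zero variance in both groups but ",
            "different means; p set to 0")
    t[ne] <- sign(effect[ne]) * Inf
    p[ne] <- 0
    df[ne] <- nx[ne] + ny[ne] - 2
  }
  small <- nx < 2L | ny < 2L
  t[small] <- NA_real_; p[small] <- NA_real_; df[small] <- NA_real_
  effect[small] <- NA_real_
  list(effect = effect, t = t, df = df, p = p, n = pmin(nx, ny))
}

#' Welch's two-sample t-test (two-tailed)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs follow documented conventions: if both groups have zero
#' variance and equal means, `t = 0, p = 1`; if both have zero variance and
#' different means, `p = 0` with a warning.
#'
#' @param x,y Numeric vectors (>= 2 non-missing values each).
#' @return List `(t, df, p, effect)` where `effect = mean(y) - mean(x)`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("welch_t: need >= 2 values per group")
  r <- row_welch_t(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(t = r$t, df = r$df, p = r$p, effect = r$effect)
}

#' Paired t-test on subject-aligned values (two-tailed)
#'
#' Pairs with a missing member are dropped listwise. All-zero differences
#' give `t = 0, p = 1`; zero-variance nonzero differences give `p = 0` with a
#' warning; fewer than 2 complete pairs give missing statistics.
#'
#' @param before,after Numeric vectors aligned by subject.
#' @return List `(t, df, p, effect, n)`; `effect` is the mean within-subject
#'   difference `after - before`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stop("paired_t: inputs must be aligned")
  r <- row_paired_t(matrix(before, nrow = 1L), matrix(after, nrow = 1L))
  list(t = r$t, df = r$df, p = r$p, effect = r$effect, n = r$n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing p-values are excluded from the number of tests and stay missing in
#' the output; original order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of BH-adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("bh_adjust: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Resolve a contrast to aligned column sets of a feature matrix.
contrast_columns <- function(mat, sheet, contrast) {
  stopifnot(inherits(contrast, "contrast"))
  sheet <- sheet[sheet$sample_id %in% colnames(mat), , drop = FALSE]
  if (contrast$kind == "paired_tp_vs_baseline") {
    ob <- sheet[sheet$group == "OB", , drop = FALSE]
    base <- ob[ob$timepoint_weeks == 0L, c("subject_id", "sample_id")]
    foll <- ob[ob$timepoint_weeks == contrast$timepoint_weeks,
               c("subject_id", "sample_id")]
    subj <- intersect(base$subject_id, foll$subject_id)
    if (length(subj) < 2L) stop("fewer than 2 complete pairs for contrast")
    list(paired = TRUE,
         before = base$sample_id[match(subj, base$subject_id)],
         after = foll$sample_id[match(subj, foll$subject_id)],
         n = length(subj))
  } else {
    con <- sheet$sample_id[sheet$group == "CON"]
    ob0 <- sheet$sample_id[sheet$group == "OB" & sheet$timepoint_weeks == 0L]
    if (length(con) < 2L || length(ob0) < 2L) stop("fewer than 2 samples per group")
    list(paired = FALSE, x = con, y = ob0, n = min(length(con), length(ob0)))
  }
}

build_diff_table <- function(features, r, scale = c("log", "beta"),
                             adjust = FALSE, alpha = 0.05) {
  scale <- match.arg(scale)
  effect <- if (scale == "beta") 100 * r$effect else r$effect
  q <- if (adjust) bh_adjust(r$p) else rep(NA_real_, length(r$p))
  crit <- if (adjust) q else r$p
  tab <- data.frame(
    feature = features,
    effect = effect,
    t = r$t, df = r$df, p = r$p, q = q,
    direction = ifelse(!is.na(effect) & effect < 0, "down", "up"),
    n = r$n,
    significant = !is.na(crit) & crit < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "alpha") <- alpha
  attr(tab, "adjusted") <- adjust
  tab
}

#' Differential expression for one contrast
#'
#' Per-gene paired t-test (follow-up vs baseline within OB subjects) or
#' Welch's t-test (CON vs OB baseline). Following the study convention for
#' expression arrays, significance is called on the unadjusted p-value
#' (`p < alpha`); BH q-values are not used for expression calls.
#'
#' @param expr Expression matrix (genes x samples, log scale).
#' @param sheet Validated sample sheet.
#' @param contrast A [paired_contrast()] or [unpaired_contrast()].
#' @param alpha Significance threshold on the unadjusted p (default 0.05).
#' @return Differential table: `feature, effect` (mean log difference),
#'   `t, df, p, q` (NA for expression), `direction, n, significant`.
#' @export
diff_expression <- function(expr, sheet, contrast, alpha = 0.05) {
  cc <- contrast_columns(expr, sheet, contrast)
  r <- if (cc$paired) {
    row_paired_t(expr[, cc$before, drop = FALSE], expr[, cc$after, drop = FALSE])
  } else {
    row_welch_t(expr[, cc$x, drop = FALSE], expr[, cc$y, drop = FALSE])
  }
  build_diff_table(rownames(expr), r, scale = "log", adjust = FALSE, alpha = alpha)
}

#' Differential methylation for one contrast
#'
#' Per-probe paired or Welch t-test on beta values, with the effect reported
#' as delta-beta in percentage points (paired: 100 x mean within-subject
#' difference; unpaired: 100 x group-mean difference). P-values are adjusted
#' across tested probes by Benjamini-Hochberg; significance is `q < alpha_q`.
#' Probes should already be QC-filtered ([filter_probes()]) with the matching
#' analysis mode.
#'
#' @param beta Beta matrix (probes x samples).
#' @param sheet Validated sample sheet.
#' @param contrast A [paired_contrast()] or [unpaired_contrast()].
#' @param alpha_q FDR threshold (default 0.05).
#' @return Differential table with `effect` = delta-beta (pp, negative =
#'   hypomethylation) and `significant` = `q < alpha_q`.
#' @export
diff_methylation <- function(beta, sheet, contrast, alpha_q = 0.05) {
  cc <- contrast_columns(beta, sheet, contrast)
  r <- if (cc$paired) {
    row_paired_t(beta[, cc$before, drop = FALSE], beta[, cc$after, drop = FALSE])
  } else {
    row_welch_t(beta[, cc$x, drop = FALSE], beta[, cc$y, drop = FALSE])
  }
  build_diff_table(rownames(beta), r, scale = "beta", adjust = TRUE, alpha = alpha_q)
}

#' Count significant features by direction
#'
#' @param tab A differential table.
#' @return Named list `(n_significant, n_up, n_down)`.
#' @export
diff_counts <- function(tab) {
  sig <- tab[tab$significant, , drop = FALSE]
  list(n_significant = nrow(sig),
       n_up = sum(sig$direction == "up"),
       n_down = sum(sig$direction == "down"))
}
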