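# Temporal classification of genes across the 2/12/24/52-week contrasts.

TEMPORAL_CLASSES <- c("transient_2w", "constant", "late_only", "never", "other")

#' Classify genes by their differential-expression time course
#'
#' Given the four paired differential tables (2, 12, 24 and 52 weeks vs
#' baseline) over a common gene universe, each gene is assigned exactly one
#' primary class:
#' \describe{
#'   \item{constant}{significant at 2 and at 52 weeks with the same direction}
#'   \item{transient_2w}{significant at 2 weeks but not at 52 weeks
#'     ("returned to baseline")}
#'   \item{late_only}{significant at 52 weeks and at no earlier timepoint}
#'   \item{never}{significant at no timepoint}
#'   \item{other}{any remaining pattern (e.g. direction reversal between 2
#'     and 52 weeks, or significance only at 12/24 weeks)}
#' }
#' The auxiliary flag `strict_transient_2w` marks transient genes significant
#' at none of 12, 24 or 52 weeks.
#'
#' @param tables Named list of differential tables with names `"2"`, `"12"`,
#'   `"24"`, `"52"` (see [diff_expression()]).
#' @param alpha Significance threshold on the unadjusted p (default 0.05).
#' @return data.frame with one row per gene: `gene`, `class`,
#'   `strict_transient_2w`, and per-timepoint `p_*` / `dir_*` columns.
#' @export
classify_genes <- function(tables, alpha = 0.05) {
  tps <- c("2", "12", "24", "52")
  if (!all(tps %in% names(tables))) {
    stop("classify_genes: need tables named ", paste(tps, collapse = ", "))
  }
  genes <- tables[["2"]]$feature
  for (tp in tps) {
    if (!setequal(tables[[tp]]$feature, genes)) {
      stop("classify_genes: gene universes differ between timepoints")
    }
  }
  sig <- vapply(tps, function(tp) {
    t <- tables[[tp]]
    s <- !is.na(t$p) & t$p < alpha
    s[match(genes, t$feature)]
  }, logical(length(genes)))
  dir <- vapply(tps, function(tp) {
    t <- tables[[tp]]
    t$direction[match(genes, t$feature)]
  }, character(length(genes)))
  if (length(genes) == 1L) {
    sig <- matrix(sig, nrow = 1L, dimnames = list(NULL, tps))
    dir <- matrix(dir, nrow = 1L, dimnames = list(NULL, tps))
  }
  cls <- rep("other", length(genes))
  cls[sig[, "2"] & sig[, "52"] & dir[, "2"] == dir[, "52"]] <- "constant"
  cls[sig[, "2"] & !sig[, "52"]] <- "transient_2w"
  cls[!sig[, "2"] & !sig[, "12"] & !sig[, "24"] & sig[, "52"]] <- "late_only"
  cls[rowSums(sig) == 0L] <- "never"
  strict <- cls == "transient_2w" & !sig[, "12"] & !sig[, "24"] & !sig[, "52"]
  out <- data.frame(gene = genes, class = cls, strict_transient_2w = strict,
                    stringsAsFactors = FALSE)
  for (tp in tps) {
    out[[paste0("p_", tp, "w")]] <- tables[[tp]]$p[match(genes, tables[[tp]]$feature)]
    out[[paste0("dir_", tp, "w")]] <- dir[, tp]
  }
  out
}

#' Count genes per temporal class
#'
#' @param classification Result of [classify_genes()].
#' @return Named integer vector over all classes, plus `strict_transient_2w`.
#' @export
temporal_counts <- function(classification) {
  counts <- vapply(TEMPORAL_CLASSES,
                   function(cl) sum(classification$class == cl), integer(1L))
  c(counts, strict_transient_2w = sum(classification$strict_transient_2w))
}
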