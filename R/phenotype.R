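# Pearson correlation of omics features with clinical phenotypes, and the
# per-phenotype significant-feature counting scheme.

#' Pearson correlation with t-based two-tailed p-value
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped. At least 3
#'   complete pairs and nonzero variance on both sides are required;
#'   otherwise all results are missing (with a warning for zero variance).
#' @return List `(r, r_squared, p, n)`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: inputs must be aligned")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson: zero variance; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  list(r = r, r_squared = r^2, p = p, n = n)
}

# Align pooled OB sample-level phenotype values to matrix columns.
pooled_design <- function(mat, phenotypes, sheet) {
  ob <- sheet[sheet$group == "OB" & sheet$sample_id %in% colnames(mat), ,
              drop = FALSE]
  key <- paste(phenotypes$subject_id, phenotypes$timepoint_weeks, sep = "@")
  idx <- match(paste(ob$subject_id, ob$timepoint_weeks, sep = "@"), key)
  list(samples = ob$sample_id, pheno_rows = idx)
}

#' Correlate features with clinical phenotypes
#'
#' Two observation schemes are supported. `pooled_levels` pools all OB
#' sample-timepoints: each observation pairs a feature value with the same
#' subject-timepoint's phenotype value (note that repeated measures per
#' subject violate independence; counts follow the raw-correlation
#' convention regardless). `delta_52w` correlates per-subject 52-week-minus-
#' baseline changes on both sides.
#'
#' @param mat Feature matrix (genes or probes x samples).
#' @param phenotypes Validated phenotype table.
#' @param sheet Validated sample sheet.
#' @param phenotype_names Character vector of phenotype columns to test.
#' @param scheme `"pooled_levels"` (default) or `"delta_52w"`.
#' @param alpha Significance threshold on the unadjusted p (default 0.05).
#' @param ann Optional probe annotation; when supplied, gene-level counts
#'   (genes with >= 1 significantly correlated CpG) are also returned.
#' @return List with `table` (data.frame `feature, phenotype, r, r_squared,
#'   p, n, significant`), `counts` (named integer vector per phenotype), and
#'   `gene_counts` (when `ann` given).
#' @export
correlate_features <- function(mat, phenotypes, sheet, phenotype_names,
                               scheme = c("pooled_levels", "delta_52w"),
                               alpha = 0.05, ann = NULL) {
  scheme <- match.arg(scheme)
  phenotypes <- validate_phenotypes(phenotypes)
  unknown <- setdiff(phenotype_names, names(phenotypes))
  if (length(unknown) > 0L) {
    stop("unknown phenotype column(s): ", paste(unknown, collapse = ", "))
  }
  if (scheme == "pooled_levels") {
    des <- pooled_design(mat, phenotypes, sheet)
    x_mat <- mat[, des$samples, drop = FALSE]
    pheno_of <- function(ph) phenotypes[[ph]][des$pheno_rows]
  } else {
    ob <- sheet[sheet$group == "OB" & sheet$sample_id %in% colnames(mat), ,
                drop = FALSE]
    s0 <- ob[ob$timepoint_weeks == 0L, c("subject_id", "sample_id")]
    s52 <- ob[ob$timepoint_weeks == 52L, c("subject_id", "sample_id")]
    subj <- intersect(s0$subject_id, s52$subject_id)
    x_mat <- mat[, s52$sample_id[match(subj, s52$subject_id)], drop = FALSE] -
      mat[, s0$sample_id[match(subj, s0$subject_id)], drop = FALSE]
    key <- paste(phenotypes$subject_id, phenotypes$timepoint_weeks, sep = "@")
    pheno_of <- function(ph) {
      phenotypes[[ph]][match(paste0(subj, "@52"), key)] -
        phenotypes[[ph]][match(paste0(subj, "@0"), key)]
    }
  }
  rows <- lapply(phenotype_names, function(ph) {
    y <- pheno_of(ph)
    res <- row_pearson(x_mat, y)
    data.frame(feature = rownames(mat), phenotype = ph,
               r = res$r, r_squared = res$r^2, p = res$p, n = res$n,
               significant = !is.na(res$p) & res$p < alpha,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  counts <- vapply(phenotype_names,
                   function(ph) sum(tab$significant[tab$phenotype == ph]),
                   integer(1L))
  out <- list(table = tab, counts = counts)
  if (!is.null(ann)) {
    p2g <- map_probes_to_genes(ann)
    gene_of <- split_gene_symbols(ann$gene_symbols[match(rownames(mat),
                                                         ann$probe_id)])
    out$gene_counts <- vapply(phenotype_names, function(ph) {
      sig_probes <- tab$feature[tab$phenotype == ph & tab$significant]
      length(unique(unlist(gene_of[match(sig_probes, rownames(mat))])))
    }, integer(1L))
  }
  out
}

# Vectorized Pearson correlation of matrix rows against one vector, with
# pairwise-complete handling and zero-variance rows returned as missing.
row_pearson <- function(mat, y) {
  n_feat <- nrow(mat)
  r <- rep(NA_real_, n_feat); p <- rep(NA_real_, n_feat)
  n <- integer(n_feat)
  ok_y <- is.finite(y)
  if (sum(ok_y) < 3L || (sum(ok_y) >= 1L && stats::sd(y[ok_y]) == 0)) {
    return(list(r = r, p = p, n = rep(sum(ok_y), n_feat)))
  }
  complete <- !is.na(mat) & matrix(ok_y, n_feat, length(y), byrow = TRUE)
  n <- rowSums(complete)
  ym <- matrix(y, n_feat, length(y), byrow = TRUE)
  ym[!complete] <- NA
  xm <- mat
  xm[!complete] <- NA
  mx <- rowMeans(xm, na.rm = TRUE)
  my <- rowMeans(ym, na.rm = TRUE)
  xc <- xm - mx
  yc <- ym - my
  sxy <- rowSums(xc * yc, na.rm = TRUE)
  sxx <- rowSums(xc^2, na.rm = TRUE)
  syy <- rowSums(yc^2, na.rm = TRUE)
  valid <- n >= 3L & sxx > 0 & syy > 0
  r[valid] <- sxy[valid] / sqrt(sxx[valid] * syy[valid])
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[valid] <- (2 * stats::pt(-abs(t), n - 2))[valid]
  list(r = r, p = p, n = n)
}
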