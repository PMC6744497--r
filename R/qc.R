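# Probe exclusion rules applied before any methylation statistics.

#' Filter methylation probes before differential analysis
#'
#' Applies the probe exclusion rules of a mixed-sex EPIC-style study:
#' probes annotated to chromosomes X and Y are always removed; SNP-flagged
#' probes are removed for unpaired (between-group) analyses but retained for
#' paired (within-subject) analyses, where a SNP shifts both members of a
#' pair equally; probes missing in more than `max_missing_frac` of samples
#' are removed.
#'
#' @param beta Beta matrix (probes x samples); every probe must be present in
#'   `ann`.
#' @param ann Probe annotation (see [read_annotation()]).
#' @param analysis_mode `"paired"` or `"unpaired"`; controls the SNP rule.
#' @param max_missing_frac Maximum tolerated fraction of missing values per
#'   probe (default 0.05).
#' @return List with `beta` (the filtered matrix) and `log`, a data.frame
#'   `(probe_id, reason)` with one row per removed probe; reasons are
#'   `"sex_chromosome"`, `"snp"` or `"missingness"` (first matching rule).
#' @export
filter_probes <- function(beta, ann, analysis_mode = c("paired", "unpaired"),
                          max_missing_frac = 0.05) {
  analysis_mode <- match.arg(analysis_mode)
  probes <- rownames(beta)
  unknown <- setdiff(probes, ann$probe_id)
  if (length(unknown) > 0L) {
    stop("probes absent from annotation: ",
         paste(utils::head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) sprintf(" (and %d more)", length(unknown) - 10L))
  }
  a <- ann[match(probes, ann$probe_id), , drop = FALSE]
  reason <- rep(NA_character_, length(probes))
  sexchr <- a$chromosome %in% c("X", "Y")
  reason[sexchr] <- "sex_chromosome"
  if (analysis_mode == "unpaired") {
    reason[is.na(reason) & a$snp_flag] <- "snp"
  }
  miss <- rowMeans(is.na(beta)) > max_missing_frac
  reason[is.na(reason) & miss] <- "missingness"
  keep <- is.na(reason)
  list(beta = beta[keep, , drop = FALSE],
       log = data.frame(probe_id = probes[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE))
}
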