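# Shared vocabularies for the study design and the EPIC-style manifest.

#' Controlled vocabularies used throughout the package
#'
#' Constants describing the study design (groups, biopsy timepoints) and the
#' probe manifest (genic region features, CpG-island relations). Exported so
#' that callers can validate their own inputs against the same vocabulary.
#'
#' @format Character (or integer) vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
STUDY_GROUPS <- c("CON", "OB")

#' @rdname vocabularies
#' @export
STUDY_TIMEPOINTS <- c(0L, 2L, 12L, 24L, 52L)

#' @rdname vocabularies
#' @export
REGION_FEATURES <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body", "UTR3", "IGR")

#' @rdname vocabularies
#' @export
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")

#' @rdname vocabularies
#' @export
PROMOTER_FEATURES <- c("TSS200", "TSS1500", "UTR5", "FirstExon")

#' @rdname vocabularies
#' @export
BODY_FEATURES <- c("Body", "UTR3")

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y")
SEX_LEVELS <- c("M", "F", "unknown")

#' Validate a sample sheet
#'
#' Checks the design invariants of a longitudinal surgery cohort: control
#' (CON) subjects are sampled once at week 0; obese (OB) subjects are sampled
#' at baseline and up to four follow-up timepoints; every OB subject with a
#' follow-up biopsy must also have a baseline biopsy so that paired contrasts
#' are defined.
#'
#' @param sheet data.frame with columns `sample_id`, `subject_id`, `group`,
#'   `timepoint_weeks` and optionally `sex`.
#' @return The validated sheet (invisibly coerced: `timepoint_weeks` integer,
#'   missing `sex` filled with `"unknown"`).
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "subject_id", "group", "timepoint_weeks")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"sex" %in% names(sheet)) sheet$sex <- "unknown"
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$subject_id <- as.character(sheet$subject_id)
  sheet$group <- as.character(sheet$group)
  sheet$sex <- as.character(sheet$sex)
  sheet$timepoint_weeks <- suppressWarnings(as.integer(sheet$timepoint_weeks))

  dup <- duplicated(sheet$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id: ", paste(unique(sheet$sample_id[dup]), collapse = ", "))
  }
  bad_group <- which(!sheet$group %in% STUDY_GROUPS)
  if (length(bad_group) > 0L) {
    stop("unknown group '", sheet$group[bad_group[1L]], "' in row ", bad_group[1L])
  }
  bad_tp <- which(is.na(sheet$timepoint_weeks) |
                    !sheet$timepoint_weeks %in% STUDY_TIMEPOINTS)
  if (length(bad_tp) > 0L) {
    stop("invalid timepoint_weeks in row ", bad_tp[1L],
         " (sample ", sheet$sample_id[bad_tp[1L]], "); allowed: ",
         paste(STUDY_TIMEPOINTS, collapse = ", "))
  }
  bad_sex <- which(!sheet$sex %in% SEX_LEVELS)
  if (length(bad_sex) > 0L) {
    stop("unknown sex '", sheet$sex[bad_sex[1L]], "' in row ", bad_sex[1L])
  }
  con_follow <- which(sheet$group == "CON" & sheet$timepoint_weeks != 0L)
  if (length(con_follow) > 0L) {
    stop("CON samples must have timepoint 0 (row ", con_follow[1L],
         ", sample ", sheet$sample_id[con_follow[1L]], ")")
  }
  key <- paste(sheet$subject_id, sheet$timepoint_weeks, sep = "@")
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, timepoint_weeks): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  ob <- sheet[sheet$group == "OB", , drop = FALSE]
  if (nrow(ob) > 0L) {
    has_follow <- tapply(ob$timepoint_weeks, ob$subject_id, function(t) any(t > 0L))
    has_base <- tapply(ob$timepoint_weeks, ob$subject_id, function(t) any(t == 0L))
    no_base <- names(has_follow)[has_follow & !has_base]
    if (length(no_base) > 0L) {
      stop("missing baseline (timepoint 0) sample for OB subject(s): ",
           paste(no_base, collapse = ", "))
    }
  }
  sheet
}

#' Read a sample sheet from CSV
#'
#' @param path Path to a CSV file with header `sample_id, subject_id, group,
#'   timepoint_weeks[, sex]`.
#' @return Validated data.frame; row order of the file is preserved.
#' @seealso [validate_sample_sheet()]
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet Validated sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(validate_sample_sheet(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a features-by-samples matrix from TSV
#'
#' The first column holds feature identifiers (genes or probes), the header
#' row holds sample identifiers. Empty cells and `NA` are read as missing,
#' never as zero. Methylation matrices (`kind = "beta"`) are range-checked:
#' every non-missing value must lie in \[0, 1\].
#'
#' @param path Path to a tab-separated file.
#' @param kind `"expression"` (log-scale intensities, any finite value) or
#'   `"beta"` (methylation fractions in \[0, 1\]).
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("expression", "beta")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("matrix file needs a feature column plus >=1 sample column: ", path)
  ids <- as.character(df[[1L]])
  dup <- duplicated(ids)
  if (any(dup)) {
    stop("duplicated feature id(s): ", paste(unique(ids[dup]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_matrix(m, kind)
}

#' @rdname read_matrix
#' @param m Numeric matrix with rownames/colnames.
#' @export
validate_matrix <- function(m, kind = c("expression", "beta")) {
  kind <- match.arg(kind)
  if (is.null(rownames(m))) stop("matrix must have feature rownames")
  if (anyDuplicated(rownames(m))) stop("duplicated feature id(s) in matrix")
  finite <- is.finite(m) | is.na(m)
  if (!all(finite)) stop("matrix contains non-finite, non-missing values")
  if (kind == "beta") {
    bad <- which(!is.na(m) & (m < 0 | m > 1))
    if (length(bad) > 0L) {
      i <- arrayInd(bad[1L], dim(m))
      stop("beta value out of [0, 1]: ", m[bad[1L]], " at probe ",
           rownames(m)[i[1L]], ", sample ", colnames(m)[i[2L]])
    }
  }
  m
}

#' @rdname read_matrix
#' @param digits Significant digits used for text serialization (default 6);
#'   write-read round-trips are exact at this precision.
#' @export
write_matrix <- function(m, path, digits = 6L) {
  out <- data.frame(feature = rownames(m), signif(m, digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an EPIC-style probe annotation manifest
#'
#' Expected CSV columns: `probe_id`, `chromosome` (1-22, X, Y; a leading
#' `"chr"` prefix is stripped), `position` (1-based), `gene_symbols`
#' (semicolon-separated, empty for intergenic probes), `region_feature`,
#' `island_relation`, `snp_flag`. A probe is intergenic (`IGR`) exactly when
#' its gene list is empty.
#'
#' @param path Path to the manifest CSV.
#' @return data.frame, one row per probe; `gene_symbols` keeps the serialized
#'   semicolon form (use [split_gene_symbols()] to expand).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(gene_symbols = "character"))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann Annotation data.frame.
#' @export
validate_annotation <- function(ann) {
  required <- c("probe_id", "chromosome", "position", "gene_symbols",
                "region_feature", "island_relation", "snp_flag")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ann$probe_id <- as.character(ann$probe_id)
  if (anyDuplicated(ann$probe_id)) stop("duplicated probe_id in annotation")
  ann$chromosome <- sub("^chr", "", as.character(ann$chromosome))
  bad <- which(!ann$chromosome %in% VALID_CHROMOSOMES)
  if (length(bad) > 0L) {
    stop("unknown chromosome '", ann$chromosome[bad[1L]], "' for probe ",
         ann$probe_id[bad[1L]])
  }
  ann$position <- as.integer(ann$position)
  if (any(is.na(ann$position) | ann$position <= 0L)) {
    stop("positions must be positive 1-based integers")
  }
  ann$gene_symbols <- ifelse(is.na(ann$gene_symbols), "", as.character(ann$gene_symbols))
  bad <- which(!ann$region_feature %in% REGION_FEATURES)
  if (length(bad) > 0L) {
    stop("unknown region_feature '", ann$region_feature[bad[1L]],
         "' for probe ", ann$probe_id[bad[1L]])
  }
  bad <- which(!ann$island_relation %in% ISLAND_RELATIONS)
  if (length(bad) > 0L) {
    stop("unknown island_relation '", ann$island_relation[bad[1L]],
         "' for probe ", ann$probe_id[bad[1L]])
  }
  ann$snp_flag <- as.logical(ann$snp_flag)
  if (anyNA(ann$snp_flag)) stop("snp_flag must be logical (TRUE/FALSE)")
  empty <- !nzchar(ann$gene_symbols)
  igr <- ann$region_feature == "IGR"
  bad <- which(empty != igr)
  if (length(bad) > 0L) {
    stop("IGR invariant violated for probe ", ann$probe_id[bad[1L]],
         ": region_feature must be IGR iff gene_symbols is empty")
  }
  ann
}

#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  utils::write.csv(validate_annotation(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand serialized gene symbols
#'
#' @param x Character vector of semicolon-separated gene symbols ("" = none).
#' @return List of character vectors (possibly empty).
#' @export
split_gene_symbols <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

# Phenotype columns that are physical concentrations / rates, hence >= 0.
NONNEGATIVE_PHENOTYPES <- c("body_weight", "BMI", "height", "glucose", "insulin",
                            "FFA", "HbA1c", "HMW_adiponectin", "CSA",
                            "state3", "state4", "state_u")
RQ_PHENOTYPES <- c("RQ_basal", "RQ_clamp")
RQ_RANGE <- c(0.6, 1.3)

#' Read a clinical phenotype table from CSV
#'
#' One row per (subject, timepoint); columns beyond `subject_id` and
#' `timepoint_weeks` are numeric phenotypes. Concentrations and rates must be
#' non-negative; respiratory quotients must lie in \[0.6, 1.3\] when present.
#'
#' @param path Path to a CSV file.
#' @return Validated data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  pheno <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(pheno)
}

#' @rdname read_phenotypes
#' @param pheno Phenotype data.frame.
#' @export
validate_phenotypes <- function(pheno) {
  required <- c("subject_id", "timepoint_weeks")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  pheno$subject_id <- as.character(pheno$subject_id)
  pheno$timepoint_weeks <- as.integer(pheno$timepoint_weeks)
  key <- paste(pheno$subject_id, pheno$timepoint_weeks, sep = "@")
  if (anyDuplicated(key)) stop("duplicate (subject_id, timepoint_weeks) in phenotype table")
  for (col in intersect(NONNEGATIVE_PHENOTYPES, names(pheno))) {
    v <- pheno[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative values in phenotype column ", col)
  }
  for (col in intersect(RQ_PHENOTYPES, names(pheno))) {
    v <- pheno[[col]]
    if (any(!is.na(v) & (v < RQ_RANGE[1L] | v > RQ_RANGE[2L]))) {
      stop("respiratory quotient out of [", RQ_RANGE[1L], ", ", RQ_RANGE[2L],
           "] in column ", col)
    }
  }
  pheno
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(validate_phenotypes(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
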