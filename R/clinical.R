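# Clamp, calorimetry and respirometry indices used in the clinical tables.

#' Adipose-tissue insulin-resistance index (Adipo-IR)
#'
#' Product of fasting free fatty acids and fasting insulin, kept in raw units
#' (umol/l x uU/ml) without molar conversion.
#'
#' @param ffa Fasting FFA, umol/l (>= 0).
#' @param insulin Fasting insulin, uU/ml (>= 0).
#' @return Numeric, umol*uU*l^-1*ml^-1.
#' @export
adipo_ir <- function(ffa, insulin) {
  if (any(is.na(ffa) | is.na(insulin))) stop("adipo_ir: missing input")
  if (any(ffa < 0) || any(insulin < 0)) stop("adipo_ir: inputs must be >= 0")
  ffa * insulin
}

#' Metabolic flexibility (delta-RQ)
#'
#' Respiratory quotient during the hyperinsulinemic clamp minus the basal
#' respiratory quotient.
#'
#' @param rq_clamp,rq_basal Respiratory quotients, each in \[0.6, 1.3\].
#' @return Numeric difference (unitless).
#' @export
delta_rq <- function(rq_clamp, rq_basal) {
  for (v in list(rq_clamp, rq_basal)) {
    if (any(is.na(v) | v < RQ_RANGE[1L] | v > RQ_RANGE[2L])) {
      stop("delta_rq: respiratory quotients must lie in [", RQ_RANGE[1L],
           ", ", RQ_RANGE[2L], "]")
    }
  }
  rq_clamp - rq_basal
}

#' Mitochondrial coupling ratios
#'
#' Respiratory control ratio `rcr = state3 / state4` (index of mitochondrial
#' coupling) and leak control ratio `lcr = state4 / state_u` (index of proton
#' leak), from high-resolution respirometry states in pmol O2 s^-1 mg^-1.
#'
#' @param state3 Maximal oxidative phosphorylation rate.
#' @param state4 Resting (leak) respiration rate.
#' @param state_u Maximal uncoupled respiration rate.
#' @return Unitless ratio.
#' @export
rcr <- function(state3, state4) {
  if (any(state4 <= 0)) stop("rcr: state4 must be > 0")
  if (any(state3 < 0)) stop("rcr: state3 must be >= 0")
  state3 / state4
}

#' @rdname rcr
#' @export
lcr <- function(state4, state_u) {
  if (any(state_u <= 0)) stop("lcr: state_u must be > 0")
  if (any(state4 < 0)) stop("lcr: state4 must be >= 0")
  state4 / state_u
}

#' Body surface area (Du Bois convention)
#'
#' @param weight_kg Body weight, kg.
#' @param height_cm Height, cm.
#' @return BSA in m^2. This is the standard Du Bois formula
#'   `0.007184 * W^0.425 * H^0.725`, provided as a convention for when only
#'   height and weight are recorded.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) stop("bsa_dubois: inputs must be > 0")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Clamp record constructor
#'
#' @param gir_series data.frame with columns `time` (min) and `gir`
#'   (glucose infusion rate, mg/min, >= 0).
#' @param steady_window Numeric length-2 `(start, end)` in minutes, within the
#'   series range.
#' @param bsa Body surface area, m^2.
#' @param weight Body weight, kg.
#' @return List of class `clamp_record`.
#' @export
clamp_record <- function(gir_series, steady_window, bsa = NA_real_, weight = NA_real_) {
  stopifnot(is.data.frame(gir_series), all(c("time", "gir") %in% names(gir_series)))
  if (any(gir_series$gir < 0)) stop("glucose infusion rates must be >= 0")
  if (length(steady_window) != 2L || steady_window[1L] >= steady_window[2L]) {
    stop("steady_window must be (start, end) with start < end")
  }
  rng <- range(gir_series$time)
  if (steady_window[1L] < rng[1L] || steady_window[2L] > rng[2L]) {
    stop("steady_window outside the recorded series range [",
         rng[1L], ", ", rng[2L], "]")
  }
  structure(list(gir_series = gir_series[order(gir_series$time), , drop = FALSE],
                 steady_window = as.numeric(steady_window),
                 bsa = bsa, weight = weight),
            class = "clamp_record")
}

#' Clamp M-value (whole-body insulin sensitivity)
#'
#' Time-weighted (trapezoidal) mean glucose infusion rate over the
#' steady-state window, divided by the chosen normalizer. No urinary-loss or
#' glucose-space correction is applied.
#'
#' @param record A [clamp_record()].
#' @param normalizer `"bsa"` (per m^2) or `"weight"` (per kg).
#' @return M-value in mg min^-1 per normalizer unit.
#' @export
m_value <- function(record, normalizer = c("bsa", "weight")) {
  stopifnot(inherits(record, "clamp_record"))
  normalizer <- match.arg(normalizer)
  w <- record$steady_window
  s <- record$gir_series
  inside <- s$time >= w[1L] & s$time <= w[2L]
  if (sum(inside) < 2L) stop("m_value: need >= 2 GIR points inside the steady window")
  t <- s$time[inside]
  g <- s$gir[inside]
  n <- length(t)
  mean_gir <- sum(diff(t) * (g[-1L] + g[-n]) / 2) / (t[n] - t[1L])
  denom <- switch(normalizer, bsa = record$bsa, weight = record$weight)
  if (is.na(denom) || denom <= 0) stop("m_value: normalizer '", normalizer, "' unavailable")
  mean_gir / denom
}

#' Percentage change from baseline
#'
#' @param baseline Baseline value (> 0).
#' @param value Follow-up value.
#' @return `100 * (value - baseline) / baseline`, in percent.
#' @export
percent_change <- function(baseline, value) {
  if (any(is.na(baseline)) || any(baseline <= 0)) {
    stop("percent_change: baseline must be > 0")
  }
  100 * (value - baseline) / baseline
}

#' Append derived clinical indices to a phenotype table
#'
#' Adds `adipo_ir`, `delta_rq`, `rcr`, `lcr` and `pct_weight_change`
#' (each subject's weight change relative to their week-0 value) where the
#' source columns are available.
#'
#' @param pheno Validated phenotype table (see [read_phenotypes()]).
#' @return The table with derived columns appended.
#' @export
derive_clinical <- function(pheno) {
  pheno <- validate_phenotypes(pheno)
  if (all(c("FFA", "insulin") %in% names(pheno))) {
    pheno$adipo_ir <- pheno$FFA * pheno$insulin
  }
  if (all(c("RQ_clamp", "RQ_basal") %in% names(pheno))) {
    pheno$delta_rq <- pheno$RQ_clamp - pheno$RQ_basal
  }
  if (all(c("state3", "state4") %in% names(pheno))) {
    pheno$rcr <- ifelse(pheno$state4 > 0, pheno$state3 / pheno$state4, NA_real_)
  }
  if (all(c("state4", "state_u") %in% names(pheno))) {
    pheno$lcr <- ifelse(pheno$state_u > 0, pheno$state4 / pheno$state_u, NA_real_)
  }
  if ("body_weight" %in% names(pheno)) {
    base <- pheno$body_weight[match(paste0(pheno$subject_id, "@0"),
                                    paste(pheno$subject_id, pheno$timepoint_weeks,
                                          sep = "@"))]
    pheno$pct_weight_change <- ifelse(!is.na(base) & base > 0,
                                      100 * (pheno$body_weight - base) / base,
                                      NA_real_)
  }
  pheno
}
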