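# Lung-protective ventilation indices and safety alerts.
#
# Three indices drive ARDS management here: the ventilatory ratio (ventilation
# efficiency), the P/F ratio (oxygenation), and tidal volume normalized to
# predicted body weight (LTVV). Alerts fire on strict violation of the safe
# thresholds: LTVV > 8 mL/kg, P/F < 300 mmHg, FiO2 >= 0.4.

VR_DENOM_SCALE <- 100 # denominator scale constant of the ventilatory ratio
VR_DENOM_PCO2 <- 37.5 # reference PCO2 (mmHg) in the ventilatory-ratio denominator

#' Predicted body weight (ARDSNet/Devine)
#'
#' `male: 50 + 0.91 * (height - 152.4)`; `female: 45.5 + 0.91 * (height -
#' 152.4)` (kg, height in cm). Heights below the 152.4 cm anchor return the
#' base weight floor (50 / 45.5 kg), the convention used in low
#' tidal volume practice.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param height_cm Height in cm, within 120-230.
#' @return Predicted body weight in kg.
#' @examples
#' pbw("male", 170) # 66.016
#' @export
pbw <- function(sex, height_cm) {
  if (anyNA(sex) || !all(sex %in% c("male", "female"))) {
    stop_icufusion("sex must be 'male' or 'female'", "icufusion_domain_error")
  }
  if (anyNA(height_cm) || any(height_cm < 120 | height_cm > 230)) {
    stop_icufusion("height must be within 120-230 cm",
      "icufusion_domain_error")
  }
  base <- ifelse(sex == "male", 50, 45.5)
  pmax(base, base + 0.91 * (height_cm - 152.4))
}

#' Ventilatory ratio
#'
#' Default (`method = "printed"`) computes
#' `(Ve * PCO2 * Vt) / (100 * 37.5 * PBW)` with `Ve` in L/min, `PCO2` in
#' mmHg, `Vt` in mL and `PBW` in kg. `method = "standard"` computes the
#' conventional ventilatory ratio
#' `(Ve_mL_min * PCO2) / (100 * PBW * 37.5)` with minute volume converted to
#' mL/min, i.e. `(Ve * 1000 * PCO2) / (100 * PBW * 37.5)`, which does not use
#' Vt. Both are exposed because device documentation of this index varies in
#' its typesetting of the numerator.
#'
#' @param Ve Exhaled minute volume, L/min.
#' @param PCO2 Arterial CO2 partial pressure, mmHg.
#' @param Vt Tidal volume, mL (ignored under `method = "standard"`).
#' @param PBW Predicted body weight, kg.
#' @param method `"printed"` (default) or `"standard"`.
#' @return Dimensionless ventilatory ratio.
#' @examples
#' ventilatory_ratio(10, 40, 450, 60) # 0.8
#' @export
ventilatory_ratio <- function(Ve, PCO2, Vt, PBW, method = c("printed", "standard")) {
  method <- match.arg(method)
  vals <- c(Ve, PCO2, PBW, if (method == "printed") Vt)
  if (anyNA(vals) || any(vals <= 0)) {
    stop_icufusion("ventilatory ratio inputs must be positive",
      "icufusion_domain_error")
  }
  if (method == "printed") {
    (Ve * PCO2 * Vt) / (VR_DENOM_SCALE * VR_DENOM_PCO2 * PBW)
  } else {
    (Ve * 1000 * PCO2) / (VR_DENOM_SCALE * PBW * VR_DENOM_PCO2)
  }
}

#' P/F ratio (oxygenation index)
#'
#' `PO2 / FiO2` in mmHg, with FiO2 as a fraction in (0, 1].
#'
#' @param PO2 Arterial oxygen partial pressure, mmHg.
#' @param FiO2 Inspired oxygen fraction in (0, 1].
#' @return P/F ratio in mmHg.
#' @examples
#' pf_ratio(164, 1.0) # 164
#' @export
pf_ratio <- function(PO2, FiO2) {
  if (anyNA(c(PO2, FiO2)) || any(PO2 <= 0)) {
    stop_icufusion("PO2 must be positive", "icufusion_domain_error")
  }
  if (any(FiO2 <= 0) || any(FiO2 > 1)) {
    stop_icufusion("FiO2 must be a fraction in (0, 1]",
      "icufusion_domain_error")
  }
  PO2 / FiO2
}

#' Tidal volume per predicted body weight (LTVV index)
#'
#' `Vt / PBW` in mL/kg; values above 8 mL/kg are outside the
#' lung-protective zone.
#'
#' @param Vt Tidal volume, mL.
#' @param PBW Predicted body weight, kg.
#' @return mL/kg.
#' @examples
#' ltvv(480, 60) # 8
#' @export
ltvv <- function(Vt, PBW) {
  if (anyNA(c(Vt, PBW)) || any(Vt <= 0) || any(PBW <= 0)) {
    stop_icufusion("Vt and PBW must be positive", "icufusion_domain_error")
  }
  Vt / PBW
}

#' Default alert thresholds and vital-sign normal ranges
#'
#' Ventilation thresholds follow the safety rules: LTVV is safe up to and
#' including 8 mL/kg, P/F is safe at or above 300 mmHg, FiO2 is safe strictly
#' below 0.4. Vital-sign normal ranges are configurable conventions, not
#' fixed clinical constants.
#'
#' @return A named list of thresholds.
#' @export
default_thresholds <- function() {
  list(
    ltvv_max = 8, pf_min = 300, fio2_max = 0.4,
    vitals = list(
      HR = c(60, 100), RR = c(12, 20), SpO2 = c(94, 100), SBP = c(90, 140)
    )
  )
}

#' Evaluate safety alerts on a fused patient state
#'
#' One alert per violated rule; alerts fire on strict violation (LTVV > 8,
#' P/F < 300, FiO2 >= 0.4), so boundary values are safe for LTVV and P/F.
#' Vital signs outside their configured normal range raise
#' `VITAL_OUT_OF_RANGE` alerts. Vitals are optional; ventilation fields
#' (`Vt`, `PBW`, `PO2`, `FiO2`) are required.
#'
#' @param state A named list or one-row tibble with ventilation fields `Vt`,
#'   `PBW`, `PO2`, `FiO2` (optionally precomputed `ltvv`, `pf_ratio`),
#'   optional vitals (`HR`, `RR`, `SpO2`, `SBP`), and optional `patient_id`,
#'   `timestamp`.
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return A tibble of alerts with columns `kind`, `observed`, `threshold`,
#'   `direction`, `patient_id`, `timestamp`; zero rows iff all rules are
#'   satisfied.
#' @export
evaluate_alerts <- function(state, thresholds = default_thresholds()) {
  state <- as.list(state)
  ltvv_val <- state$ltvv %||%
    (if (!is.null(state$Vt) && !is.null(state$PBW)) ltvv(state$Vt, state$PBW))
  pf_val <- state$pf_ratio %||%
    (if (!is.null(state$PO2) && !is.null(state$FiO2)) {
      pf_ratio(state$PO2, state$FiO2)
    })
  missing <- c(
    if (is.null(ltvv_val)) "Vt/PBW (for LTVV)",
    if (is.null(pf_val)) "PO2/FiO2 (for P/F)",
    if (is.null(state$FiO2)) "FiO2"
  )
  if (length(missing) > 0) {
    stop_icufusion(
      paste0("incomplete state; missing: ", toString(missing)),
      "icufusion_incomplete_state", missing = missing
    )
  }
  pid <- state$patient_id %||% NA_character_
  ts <- state$timestamp %||% as.POSIXct(NA)
  alert <- function(kind, observed, threshold, direction) {
    tibble::tibble(
      kind = kind, observed = observed, threshold = threshold,
      direction = direction, patient_id = pid, timestamp = ts
    )
  }
  out <- list()
  if (ltvv_val > thresholds$ltvv_max) {
    out <- c(out, list(alert("LTVV_HIGH", ltvv_val, thresholds$ltvv_max, ">")))
  }
  if (pf_val < thresholds$pf_min) {
    out <- c(out, list(alert("PF_LOW", pf_val, thresholds$pf_min, "<")))
  }
  if (state$FiO2 >= thresholds$fio2_max) {
    out <- c(out, list(alert("FIO2_HIGH", state$FiO2, thresholds$fio2_max, ">=")))
  }
  for (v in names(thresholds$vitals)) {
    x <- state[[v]]
    if (is.null(x) || is.na(x)) next
    rng <- thresholds$vitals[[v]]
    if (x < rng[1] || x > rng[2]) {
      out <- c(out, list(alert(
        "VITAL_OUT_OF_RANGE", x,
        if (x < rng[1]) rng[1] else rng[2],
        if (x < rng[1]) "<" else ">"
      )))
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      kind = character(), observed = numeric(), threshold = numeric(),
      direction = character(), patient_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC")
    ))
  }
  dplyr::bind_rows(out)
}

#' Derived ventilation indices for a fused state
#'
#' @param state A named list or one-row tibble with `Ve`, `PCO2`, `Vt`,
#'   `PBW`, `PO2`, `FiO2`.
#' @param vr_method Passed to [ventilatory_ratio()].
#' @return A one-row tibble with `ventilatory_ratio`, `pf_ratio`, `ltvv`,
#'   `timestamp`.
#' @export
compute_indices <- function(state, vr_method = "printed") {
  state <- as.list(state)
  tibble::tibble(
    ventilatory_ratio = ventilatory_ratio(
      state$Ve, state$PCO2, state$Vt, state$PBW,
      method = vr_method
    ),
    pf_ratio = pf_ratio(state$PO2, state$FiO2),
    ltvv = ltvv(state$Vt, state$PBW),
    timestamp = state$timestamp %||% as.POSIXct(NA)
  )
}

#' Fuse observations and a patient profile into a patient state
#'
#' Data-level fusion: per parameter, the latest observation value within the
#' lookback window before `at_time` wins; predicted body weight is computed
#' from the profile. Provenance (source observation row) is retained per
#' field in `attr(state, "provenance")`. Fusing an already-fused state again
#' (same observations, same window) is idempotent.
#'
#' @param obs Observation tibble (sorted or not; sorted internally by time).
#' @param profile One-row tibble or list with `patient_id`, `sex`,
#'   `height_cm`.
#' @param window_h Lookback window in hours (> 0).
#' @param at_time Fusion time; defaults to the latest observation time.
#' @param required Canonical parameter names that must be present within the
#'   window; missing ones raise an incomplete-state error listing them.
#' @param registry Code registry for LOINC -> canonical name mapping.
#' @return A one-row tibble (patient state) with one column per fused
#'   parameter plus `patient_id`, `sex`, `height_cm`, `PBW`, `timestamp`.
#' @export
fuse_patient_state <- function(obs, profile, window_h = 6, at_time = NULL,
                               required = c("Vt", "Ve", "FiO2", "PCO2", "PO2"),
                               registry = code_registry()) {
  stopifnot(window_h > 0)
  profile <- as.list(profile)
  flat <- obs_flatten(obs, registry = registry)
  flat <- flat[flat$subject == profile$patient_id & !is.na(flat$name), ]
  at_time <- at_time %||% max(flat$effective_time)
  flat <- flat[flat$effective_time <= at_time &
    flat$effective_time > at_time - window_h * 3600, ]
  latest <- flat |>
    dplyr::arrange(.data$effective_time, .data$obs_id) |>
    dplyr::group_by(.data$name) |>
    dplyr::slice(dplyr::n()) |>
    dplyr::ungroup()
  missing <- setdiff(required, latest$name)
  if (length(missing) > 0) {
    stop_icufusion(
      paste0(
        "no observation within ", window_h, " h window for: ",
        toString(missing)
      ),
      "icufusion_incomplete_state", missing = missing
    )
  }
  state <- tibble::as_tibble(
    stats::setNames(as.list(latest$value), latest$name)
  )
  state$patient_id <- profile$patient_id
  state$sex <- profile$sex
  state$height_cm <- profile$height_cm
  state$PBW <- pbw(profile$sex, profile$height_cm)
  state$timestamp <- at_time
  attr(state, "provenance") <- latest[, c("name", "obs_id", "effective_time", "code")]
  state
}
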