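# Synthetic generators: cohorts, multi-dialect device-message streams at the
# modeled category mix, ARDS-labeled feature tables with a planted
# oxygenation signal, and the fixed worked-case trajectory.
#
# All generators are deterministic under a fixed seed and every corpus they
# produce is consumable by the downstream pipeline without parse errors.

STREAM_RATES_MBPS <- c(
  patient_monitor = 29.7, ventilator = 26.1, hemodynamics_monitor = 2.32,
  infusion_pump = 0.344, hematology_analyzer = 7.2
)

STREAM_DIALECTS <- c(
  patient_monitor = "hl7v2", ventilator = "proprietary",
  hemodynamics_monitor = "proprietary", infusion_pump = "json",
  hematology_analyzer = "proprietary"
)

#' Generate a synthetic patient cohort
#'
#' Heights are normal per sex (defaults: male 170 cm, female 158 cm, sd 7),
#' resampled into the 120-230 cm validity range; ward zones are drawn from a
#' configurable mix.
#'
#' @param n Number of patients (>= 1).
#' @param sex_ratio Probability of male sex.
#' @param height_mean Named vector `c(male =, female =)` of mean heights, cm.
#' @param height_sd Height standard deviation, cm.
#' @param zone_probs Named ward-zone probabilities.
#' @param seed RNG seed.
#' @return A profile tibble: `patient_id`, `sex`, `height_cm`, `bed`,
#'   `ward_zone`.
#' @export
generate_cohort <- function(n, sex_ratio = 0.5,
                            height_mean = c(male = 170, female = 158),
                            height_sd = 7,
                            zone_probs = c(
                              negative_pressure = 0.1,
                              contact_isolation = 0.2, regular = 0.7
                            ),
                            seed = 1L) {
  if (n < 1) stop_icufusion("n must be >= 1", "icufusion_validation_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sex <- ifelse(stats::rbinom(n, 1, sex_ratio) == 1, "male", "female")
  height <- stats::rnorm(n, height_mean[sex], height_sd)
  out_of_range <- which(height < 120 | height > 230)
  while (length(out_of_range) > 0) {
    height[out_of_range] <- stats::rnorm(
      length(out_of_range), height_mean[sex[out_of_range]], height_sd
    )
    out_of_range <- which(height < 120 | height > 230)
  }
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = sex,
    height_cm = round(height, 1),
    bed = sprintf("BED%02d", seq_len(n)),
    ward_zone = sample(names(zone_probs), n, replace = TRUE, prob = zone_probs)
  )
}

rnum <- function(n, lo, hi, digits = 1) round(stats::runif(n, lo, hi), digits)

stream_payload <- function(category, t) {
  # returns list(payload, truth = tibble(name, value))
  if (category == "patient_monitor") {
    v <- c(
      HR = rnum(1, 55, 130, 0), SPO2 = rnum(1, 85, 100, 0),
      RR = rnum(1, 10, 35, 0), SBP = rnum(1, 85, 180, 0),
      DBP = rnum(1, 45, 110, 0)
    )
    obx <- sprintf(
      "OBX|%d|NM|%s||%s|%s", seq_along(v), names(v),
      vapply(v, as.character, ""),
      c("{beats}/min", "%", "{breaths}/min", "mm[Hg]", "mm[Hg]")
    )
    msh <- paste0(
      "MSH|^~\\&|MON|ICU|||", format(t, "%Y%m%d%H%M%S", tz = "UTC"),
      "||ORU^R01|MSG|P|2.3"
    )
    payload <- paste(c(msh, obx), collapse = "\r")
    truth <- tibble::tibble(
      name = c("HR", "SpO2", "RR", "SBP", "DBP"), value = unname(v)
    )
  } else if (category == "ventilator") {
    v <- c(VT = rnum(1, 250, 650, 0), VE = rnum(1, 4, 15, 1), FIO2 = rnum(1, 0.21, 1, 2))
    payload <- paste0(names(v), ":", vapply(v, as.character, ""), collapse = "|")
    truth <- tibble::tibble(name = c("Vt", "Ve", "FiO2"), value = unname(v))
  } else if (category == "hemodynamics_monitor") {
    v <- c(SAO2 = rnum(1, 80, 100, 0), CO = rnum(1, 2.5, 9, 1), SV = rnum(1, 40, 120, 0))
    payload <- paste0(names(v), ":", vapply(v, as.character, ""), collapse = "|")
    truth <- tibble::tibble(name = c("SaO2", "CO", "SV"), value = unname(v))
  } else if (category == "infusion_pump") {
    v <- c(rate = rnum(1, 5, 250, 1), volume = rnum(1, 10, 2000, 0))
    payload <- as.character(jsonlite::toJSON(as.list(v), auto_unbox = TRUE, digits = NA))
    truth <- tibble::tibble(name = c("INF_RATE", "INF_DOSE"), value = unname(v))
  } else if (category == "hematology_analyzer") {
    v <- c(
      WBC = rnum(1, 3, 25, 1), RBC = rnum(1, 3, 6.5, 2),
      HGB = rnum(1, 7, 18, 1), HCT = rnum(1, 20, 55, 0),
      PLT = rnum(1, 50, 600, 0), PCO2 = rnum(1, 25, 90, 0),
      PO2 = rnum(1, 40, 500, 0)
    )
    payload <- paste0(names(v), "=", vapply(v, as.character, ""), collapse = ";")
    truth <- tibble::tibble(
      name = c("WBC", "RBC", "HGB", "HCT", "PLT", "PCO2", "PO2"),
      value = unname(v)
    )
  } else {
    stop_icufusion(paste0("unknown device category '", category, "'"),
      "icufusion_validation_error")
  }
  list(payload = payload, truth = truth)
}

#' Generate a multi-dialect device-message corpus
#'
#' Emits messages for the five device categories with per-category byte
#' budgets proportional to the modeled data rates (29.7 : 26.1 : 2.32 :
#' 0.344 : 7.2), scaled down to a desk-size corpus (the scale factor is
#' recorded in the manifest). Dialects follow the device assignment: patient
#' monitors emit HL7 v2, infusion pumps JSON, and ventilators, hemodynamics
#' monitors and hematology analyzers proprietary delimited records. Every
#' message parses against the shipped device-feature registry; the emitted
#' ground-truth values are attached as `attr(corpus, "truth")`.
#'
#' @param cohort Profile tibble from [generate_cohort()].
#' @param duration_s Emission horizon in seconds (timestamps are uniform over
#'   it).
#' @param total_bytes Approximate total payload bytes across categories.
#' @param rates_mbps Named per-category data rates used for the byte ratios.
#' @param seed RNG seed.
#' @return A raw-message tibble with attributes `truth` (tibble `msg_id`,
#'   `name`, `value`) and `manifest`.
#' @export
generate_streams <- function(cohort, duration_s = 60, total_bytes = 4e5,
                             rates_mbps = STREAM_RATES_MBPS, seed = 1L) {
  if (nrow(cohort) == 0L) {
    stop_icufusion("cohort must be non-empty", "icufusion_validation_error")
  }
  unknown <- setdiff(names(rates_mbps), names(STREAM_DIALECTS))
  if (length(unknown) > 0) {
    stop_icufusion(paste0("unknown categories: ", toString(unknown)),
      "icufusion_validation_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t0 <- as.POSIXct("2024-04-14 21:00:00", tz = "UTC")
  budgets <- total_bytes * rates_mbps / sum(rates_mbps)
  msgs <- list()
  truths <- list()
  for (cat in names(rates_mbps)) {
    got <- 0
    while (got < budgets[[cat]]) {
      t <- t0 + floor(stats::runif(1, 0, duration_s)) # whole-second device clocks
      pl <- stream_payload(cat, t)
      got <- got + nchar(pl$payload, type = "bytes")
      p <- cohort[sample.int(nrow(cohort), 1), ]
      msgs[[length(msgs) + 1L]] <- tibble::tibble(
        category = cat, dialect = STREAM_DIALECTS[[cat]],
        payload = pl$payload, received_time = t,
        source_device_id = sprintf("%s-%02d", toupper(substr(cat, 1, 3)),
          sample.int(20, 1)),
        patient_id = p$patient_id, location = p$bed
      )
      truths[[length(truths) + 1L]] <- pl$truth
    }
  }
  combined <- dplyr::bind_rows(msgs)
  ord <- order(combined$received_time)
  out <- combined[ord, ]
  truth <- purrr::imap(truths[ord], function(tt, i) {
    dplyr::mutate(tt, msg_id = i, .before = 1)
  }) |> dplyr::bind_rows()
  bytes <- tapply(nchar(out$payload, type = "bytes"), out$category, sum)
  attr(out, "truth") <- truth
  attr(out, "manifest") <- list(
    seed = seed, duration_s = duration_s, total_bytes = total_bytes,
    scale_note = "byte budgets scaled from Mbps ratios to a desk-size corpus",
    rates_mbps = as.list(rates_mbps),
    bytes_per_category = as.list(bytes)
  )
  out
}

#' Generate an ARDS-labeled ventilation dataset with a planted signal
#'
#' Labels are drawn first at the requested prevalence; the latent P/F ratio
#' is then normal within class, separated by `effect_size` mmHg (ARDS mean
#' 180, non-ARDS mean `180 + effect_size`, common sd `noise_sd`). With equal
#' within-class variances this is exactly a logistic label model in latent
#' P/F with coefficient `-effect_size / noise_sd^2`, and the Bayes-optimal
#' AUC is `pnorm(effect_size / (noise_sd * sqrt(2)))`; both are recorded in
#' the manifest. FiO2 is uniform on (0.30, 1.00) and PO2 is reconstructed as
#' `P/F * FiO2`, so the signal reaches the classifiers only through the
#' feature pair. PCO2 and Ve carry a mild secondary class shift (ventilation
#' inefficiency); Vt, height and sex are uninformative.
#'
#' @param n Sample count.
#' @param prevalence ARDS prevalence in (0, 1).
#' @param effect_size Between-class separation of latent P/F, mmHg (>= 0).
#' @param noise_sd Within-class P/F standard deviation, mmHg.
#' @param seed RNG seed.
#' @return A feature tibble with columns `FiO2`, `PCO2`, `PO2`, `Ve`, `Vt`,
#'   `height`, `sex`, `ards`, and a `manifest` attribute carrying the
#'   generating parameters.
#' @export
generate_ards_dataset <- function(n, prevalence = 0.3, effect_size = 120,
                                  noise_sd = 40, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop_icufusion("prevalence must lie in (0, 1)",
      "icufusion_validation_error")
  }
  if (effect_size < 0) {
    stop_icufusion("effect size must be >= 0", "icufusion_validation_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  label <- stats::rbinom(n, 1, prevalence)
  mu_ards <- 180
  pf <- pmax(40, (mu_ards + (1 - label) * effect_size) + stats::rnorm(n, 0, noise_sd))
  fio2 <- round(stats::runif(n, 0.30, 1.00), 2)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
  height <- pmin(230, pmax(120, stats::rnorm(n, ifelse(sex == "male", 170, 158), 7)))
  out <- tibble::tibble(
    FiO2 = fio2,
    PCO2 = pmin(150, pmax(15, round(stats::rnorm(n, 45 + 5 * label, 7), 1))),
    PO2 = pf * fio2,
    Ve = pmin(30, pmax(3, round(stats::rnorm(n, 9 + 1.5 * label, 2), 1))),
    Vt = pmin(800, pmax(200, round(stats::rnorm(n, 450, 60)))),
    height = round(height, 1),
    sex = sex,
    ards = label
  )
  attr(out, "label") <- "ards"
  attr(out, "manifest") <- list(
    seed = seed, n = n, prevalence = prevalence,
    effect_size = effect_size, noise_sd = noise_sd, mu_ards = mu_ards,
    beta_pf = -effect_size / noise_sd^2,
    bayes_auc = stats::pnorm(effect_size / (noise_sd * sqrt(2)))
  )
  out
}

worked_case_obs <- function(subject, t, bed, vt, ve, fio2, po2, pco2,
                            hr, rr, spo2, sbp, dbp, registry) {
  comp <- function(name, value) {
    e <- lookup_code(name, registry)
    obs_component(e$loinc, value, display = e$display, unit = e$unit)
  }
  list(
    make_observation(
      "ventilator", subject, t, "ventilator", bed,
      dplyr::bind_rows(comp("Vt", vt), comp("Ve", ve), comp("FiO2", fio2))
    ),
    make_observation(
      "laboratory", subject, t, "hematology_analyzer", bed,
      dplyr::bind_rows(comp("PO2", po2), comp("PCO2", pco2))
    ),
    make_observation(
      "vital-signs", subject, t, "patient_monitor", bed,
      dplyr::bind_rows(
        comp("HR", hr), comp("RR", rr), comp("SpO2", spo2),
        comp("SBP", sbp), comp("DBP", dbp)
      )
    )
  )
}

#' The fixed ARDS worked-case trajectory
#'
#' A seedless, hard-coded two-timepoint trajectory for one ventilated
#' patient. At the first timestamp (14 April, 21:20 UTC) the derived indices
#' are LTVV 10.0 mL/kg, P/F 164 mmHg and FiO2 1.0 — all three ventilation
#' alerts fire. Six hours later, after intervention, LTVV is 6.1, P/F 320
#' and FiO2 0.35 — no alerts. The generator inputs (Vt 600 then 366 mL, PBW
#' 60 kg via a 163.4 cm male profile, PO2 164 then 112 mmHg) are constructed
#' to reproduce those derived values.
#'
#' @return A list with `profile` (one-row tibble), `observations`
#'   (observation tibble over both timepoints) and `times` (the two POSIXct
#'   timestamps).
#' @export
generate_worked_case <- function() {
  registry <- code_registry()
  height <- 152.4 + 10 / 0.91 # PBW = 60 kg exactly under the male formula
  profile <- tibble::tibble(
    patient_id = "P-ARDS-01", sex = "male", height_cm = height,
    bed = "BED07", ward_zone = "negative_pressure"
  )
  t0 <- as.POSIXct("2024-04-14 21:20:00", tz = "UTC")
  t1 <- as.POSIXct("2024-04-15 03:30:00", tz = "UTC")
  obs <- c(
    worked_case_obs("P-ARDS-01", t0, "BED07",
      vt = 600, ve = 10.1, fio2 = 1.0, po2 = 164, pco2 = 55,
      hr = 96, rr = 18, spo2 = 94, sbp = 118, dbp = 76,
      registry = registry
    ),
    worked_case_obs("P-ARDS-01", t1, "BED07",
      vt = 366, ve = 8.4, fio2 = 0.35, po2 = 112, pco2 = 42,
      hr = 88, rr = 16, spo2 = 96, sbp = 122, dbp = 78,
      registry = registry
    )
  )
  list(
    profile = profile,
    observations = dplyr::bind_rows(obs),
    times = c(t0, t1)
  )
}
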