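# Shared fixtures, all built in code at test time.

hr_component <- function(value = 88) {
  obs_component("8867-4", value, display = "Heart rate", unit = "{beats}/min")
}

simple_observation <- function(subject = "P001", value = 88,
                               time = "2024-04-14T21:20:00Z") {
  make_observation(
    "vital-signs", subject, time, "patient_monitor", "BED07",
    hr_component(value)
  )
}

hemo_registry <- function() {
  empty <- df_registry(system.file("extdata", "device_features.json",
    package = "icufusion"
  ))
  empty
}

hemo_message <- function(payload = "SAO2:97|CO:4.8",
                         patient_id = "P001") {
  list(
    category = "hemodynamics_monitor", dialect = "proprietary",
    payload = payload,
    received_time = as.POSIXct("2024-04-14 21:20:00", tz = "UTC"),
    source_device_id = "HEM-01", patient_id = patient_id, location = "BED07"
  )
}

small_corpus <- function(n_patients = 8, total_bytes = 2e4, seed = 42) {
  cohort <- generate_cohort(n_patients, seed = seed)
  generate_streams(cohort, total_bytes = total_bytes, seed = seed + 1)
}

# drop generator/parse bookkeeping attributes before whole-table comparison
plain_df <- function(x) {
  x <- as.data.frame(x)
  for (a in c("truth", "manifest", "flags", "residue", "label", "n_dropped")) {
    attr(x, a) <- NULL
  }
  x
}
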