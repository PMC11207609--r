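test_that("feature registration validates, replaces, and audits", {
  reg <- df_registry()
  # shipped registry resolves every canonical name it declares
  codes <- code_registry()
  expect_true(all(reg$name %in% codes$name))

  n0 <- nrow(reg)
  reg2 <- register_feature(reg,
    category = "hemodynamics_monitor", name = "SaO2", dialect = "proprietary",
    locator = "SAT", range = c(0, 100), delimiter = "|", kv_delim = ":"
  )
  expect_identical(nrow(reg2), n0) # replaced, not appended
  audit <- attr(reg2, "audit")
  expect_identical(audit$action, "replace")
  expect_match(audit$detail, "SAO2 -> SAT")

  expect_error(
    register_feature(reg, "x", "y", "proprietary", "L",
      range = c(100, 0), delimiter = "|", kv_delim = ":"
    ),
    class = "icufusion_validation_error"
  )
  expect_error(
    register_feature(reg, "x", "y", "proprietary", "L"), # no delimiter
    class = "icufusion_validation_error"
  )
})

test_that("parser compilation is pure and covers exactly the registered features", {
  reg <- df_registry()
  rules <- compile_parser(reg, "hemodynamics_monitor", "proprietary")
  expect_identical(nrow(rules$rules), 3L) # SaO2, CO, SV
  expect_identical(rules$delimiter, "|")
  # recompilation without registry change is byte-identical
  expect_identical(
    serialize(compile_parser(reg, "hemodynamics_monitor", "proprietary"), NULL),
    serialize(rules, NULL)
  )
  expect_error(compile_parser(reg, "mri_scanner", "json"),
    class = "icufusion_empty_category"
  )
})

test_that("proprietary payloads parse with flag-and-forward range policy", {
  rules <- compile_parser(df_registry(), "hemodynamics_monitor", "proprietary")
  out <- parse_message(hemo_message("SAO2:97|CO:4.8"), rules)
  expect_identical(out$name, c("SaO2", "CO"))
  expect_identical(unlist(out$value), c(97, 4.8))
  expect_true(all(out$in_range))
  # out-of-range value is extracted and flagged, never dropped
  out2 <- parse_message(hemo_message("SAO2:250"), rules)
  expect_identical(unlist(out2$value), 250)
  expect_false(out2$in_range)
  # unmatched tokens end up in the residue
  out3 <- parse_message(hemo_message("SAO2:97|XYZ:1"), rules)
  expect_identical(attr(out3, "residue"), "XYZ")
  # dialect mismatch and undecodable payloads are explicit errors
  msg <- hemo_message()
  msg$dialect <- "json"
  expect_error(parse_message(msg, rules), class = "icufusion_dialect_mismatch")
  expect_error(parse_message(hemo_message("garbage-no-delims"), rules),
    class = "icufusion_parse_error"
  )
  expect_error(parse_message(hemo_message("SAO2:not_a_number"), rules),
    class = "icufusion_parse_error"
  )
})

test_that("HL7 v2 OBX segments carry vitals into parsed values", {
  rules <- compile_parser(df_registry(), "patient_monitor", "hl7v2")
  payload <- paste(
    "MSH|^~\\&|MON|ICU|||20240414212000||ORU^R01|MSG|P|2.3",
    "OBX|1|NM|HR||88|{beats}/min",
    "OBX|2|NM|SPO2||97|%",
    sep = "\r"
  )
  msg <- list(
    category = "patient_monitor", dialect = "hl7v2", payload = payload,
    received_time = as.POSIXct("2024-04-14 21:20:00", tz = "UTC"),
    patient_id = "P001", location = "BED01"
  )
  out <- parse_message(msg, rules)
  expect_identical(out$name, c("HR", "SpO2"))
  expect_identical(unlist(out$value), c(88, 97))
})

test_that("translation lifts parsed values into coded observation components", {
  dfm <- df_registry()
  rules <- compile_parser(dfm, "hemodynamics_monitor", "proprietary")
  obs <- translate(hemo_message("SAO2:97|CO:4.8"), rules)
  cmp <- obs$components[[1]]
  expect_identical(cmp$code[1], "2708-6")
  expect_identical(cmp$value[[1]], 97)
  expect_identical(obs$subject, "P001")
  expect_identical(obs$device_type, "hemodynamics_monitor")

  # infusion pump JSON dialect
  jrules <- compile_parser(dfm, "infusion_pump", "json")
  jmsg <- list(
    category = "infusion_pump", dialect = "json",
    payload = "{\"rate\": 5, \"unit\": \"mL/h\"}",
    received_time = as.POSIXct("2024-04-14 21:20:00", tz = "UTC"),
    patient_id = "P002", location = "BED02"
  )
  jobs <- translate(jmsg, jrules)
  expect_identical(jobs$components[[1]]$value[[1]], 5)
  expect_identical(jobs$components[[1]]$code[1], "33747-0")

  # zero extractable features
  expect_error(
    translate(hemo_message("XYZ:1|ABC:2"), rules),
    class = "icufusion_empty_translation"
  )
  # missing patient id proceeds as UNKNOWN with a warning
  expect_warning(
    unk <- translate(hemo_message(patient_id = NA_character_), rules),
    "UNKNOWN"
  )
  expect_identical(unk$subject, "UNKNOWN")
})

test_that("translation conserves every emitted value over a generated corpus", {
  corpus <- small_corpus()
  truth <- attr(corpus, "truth")
  obs <- translate_corpus(corpus)
  expect_identical(nrow(obs), nrow(corpus))
  # completeness: component count equals emitted value count, no silent loss
  expect_identical(sum(vapply(obs$components, nrow, 0L)), nrow(truth))
  # value conservation: per message, parsed component values match emissions
  flat <- obs_flatten(obs)
  by_msg <- split(flat$value, flat$obs_id)
  truth_by_msg <- split(truth$value, truth$msg_id)
  expect_identical(length(by_msg), length(truth_by_msg))
  for (i in seq_along(by_msg)) {
    expect_identical(unname(by_msg[[i]]), unname(truth_by_msg[[i]]))
  }
  # determinism: translating twice gives identical records
  expect_identical(
    as.data.frame(translate_corpus(corpus)), as.data.frame(obs)
  )
})
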