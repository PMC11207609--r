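test_that("code lookup returns the registered LOINC/UCUM pair deterministically", {
  reg <- code_registry()
  hr <- lookup_code("HR", reg)
  expect_identical(hr$loinc, "8867-4")
  expect_identical(hr$unit, "{beats}/min")
  expect_identical(lookup_code("SaO2", reg)$loinc, "2708-6")
  expect_identical(lookup_code("HR", reg), lookup_code("HR", reg))
  expect_error(lookup_code("NOT_A_PARAM", reg),
    class = "icufusion_unknown_parameter"
  )
})

test_that("registry invariants hold: LOINC patterns valid, no duplicate codes", {
  reg <- code_registry()
  expect_true(all(grepl("^[0-9]{1,7}-[0-9]$", reg$loinc)))
  expect_identical(anyDuplicated(reg$loinc), 0L)
  expect_identical(anyDuplicated(reg$name), 0L)
})

test_that("observation constructor validates its invariants", {
  obs <- simple_observation()
  expect_identical(obs$subject, "P001")
  expect_identical(obs$components[[1]]$value[[1]], 88)
  # empty components
  expect_error(
    make_observation(
      "vital-signs", "P001", "2024-04-14T21:20:00Z", "m", "b",
      hr_component()[0, ]
    ),
    class = "icufusion_validation_error"
  )
  # duplicate component code
  expect_error(
    make_observation(
      "vital-signs", "P001", "2024-04-14T21:20:00Z", "m", "b",
      dplyr::bind_rows(hr_component(88), hr_component(90))
    ),
    class = "icufusion_validation_error"
  )
  # malformed timestamp (no timezone)
  expect_error(
    make_observation(
      "vital-signs", "P001", "2024-04-14 21:20:00", "m", "b", hr_component()
    ),
    class = "icufusion_validation_error"
  )
  # empty subject
  expect_error(
    make_observation(
      "vital-signs", "", "2024-04-14T21:20:00Z", "m", "b", hr_component()
    ),
    class = "icufusion_validation_error"
  )
})

test_that("components preserve insertion order and enforce numeric units", {
  cmp <- dplyr::bind_rows(
    obs_component("8867-4", 88, unit = "{beats}/min"),
    obs_component("9279-1", 18, unit = "{breaths}/min"),
    obs_component("59408-5", 97, unit = "%")
  )
  obs <- make_observation(
    "vital-signs", "P001", "2024-04-14T21:20:00Z", "m", "b", cmp
  )
  expect_identical(obs$components[[1]]$code, c("8867-4", "9279-1", "59408-5"))
  expect_error(obs_component("8867-4", 88), # numeric without unit
    class = "icufusion_validation_error"
  )
  expect_error(obs_component("8867-4", Inf, unit = "x"),
    class = "icufusion_validation_error"
  )
  expect_error(obs_component("not-a-loinc!", 1, unit = "x"),
    class = "icufusion_validation_error"
  )
})

test_that("every declared FHIR value kind round-trips through NDJSON", {
  cmp <- dplyr::bind_rows(
    obs_component("8867-4", 88.25, unit = "{beats}/min"), # decimal
    obs_component("6690-2", 12L, unit = "10*3/uL"), # integer
    obs_component("777-3", "clumped"), # string
    obs_component("4544-3", TRUE), # boolean
    obs_component("8480-6", list(low = 90, high = 140), unit = "mm[Hg]") # range
  )
  expect_identical(cmp$type, c("decimal", "integer", "string", "boolean", "range"))
  obs <- make_observation(
    "laboratory", "P009", "2024-04-14T21:20:05Z", "analyzer", "LAB", cmp
  )
  path <- withr::local_tempfile()
  write_obs_ndjson(obs, path)
  back <- read_obs_ndjson(path)
  expect_identical(
    purrr::map(back$components[[1]]$value, identity),
    purrr::map(cmp$value, identity)
  )
  expect_identical(back$components[[1]]$type, cmp$type)
})

test_that("NDJSON round-trip is the identity on arbitrary generated record sets", {
  wc <- generate_worked_case()
  corpus <- small_corpus()
  obs <- dplyr::bind_rows(wc$observations, translate_corpus(corpus))
  path <- withr::local_tempfile()
  write_obs_ndjson(obs, path)
  expect_identical(length(readLines(path)), nrow(obs))
  back <- read_obs_ndjson(path)
  expect_equal(plain_df(back), plain_df(obs), tolerance = 0)

  # empty set round-trips to an empty set
  empty_path <- withr::local_tempfile()
  writeLines(character(), empty_path)
  expect_identical(nrow(read_obs_ndjson(empty_path)), 0L)

  # truncated line reports its line number
  lines <- readLines(path)
  lines[2] <- substr(lines[2], 1, 25)
  bad <- withr::local_tempfile()
  writeLines(lines, bad)
  err <- expect_error(read_obs_ndjson(bad), class = "icufusion_parse_error")
  expect_match(conditionMessage(err), "line 2")
})
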