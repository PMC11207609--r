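test_that("predicted body weight matches the sex-specific closed form", {
  expect_identical(pbw("male", 152.4), 50)
  expect_identical(pbw("female", 152.4), 45.5)
  expect_equal(pbw("male", 170), 66.016)
  expect_equal(pbw("female", 165), 45.5 + 0.91 * (165 - 152.4))
  # below the anchor the base weight is the floor
  expect_identical(pbw("male", 140), 50)
  expect_error(pbw("other", 170), class = "icufusion_domain_error")
  expect_error(pbw("male", 90), class = "icufusion_domain_error")
})

test_that("ventilatory ratio implements both numerator conventions", {
  expect_equal(ventilatory_ratio(10, 40, 450, 60), 0.8)
  # doubling PBW halves the result (homogeneity)
  expect_equal(
    ventilatory_ratio(10, 40, 450, 120),
    ventilatory_ratio(10, 40, 450, 60) / 2
  )
  # the standard convention converts Ve to mL/min and drops Vt
  expect_equal(
    ventilatory_ratio(7.5, 40, 450, 60, method = "standard"),
    (7.5 * 1000 * 40) / (100 * 60 * 37.5)
  )
  expect_error(ventilatory_ratio(10, 40, 450, 0),
    class = "icufusion_domain_error"
  )
})

test_that("P/F ratio and LTVV are the printed quotients with domain guards", {
  expect_identical(pf_ratio(164, 1.0), 164)
  expect_identical(pf_ratio(150, 0.5), 300)
  expect_error(pf_ratio(100, 0), class = "icufusion_domain_error")
  expect_error(pf_ratio(100, 1.2), class = "icufusion_domain_error")

  expect_identical(ltvv(480, 60), 8)
  expect_identical(ltvv(600, 60), 10)
  expect_identical(ltvv(366, 60), 6.1)
  expect_error(ltvv(480, 0), class = "icufusion_domain_error")

  # scale invariances
  expect_equal(ltvv(2 * 480, 2 * 60), ltvv(480, 60))
  expect_equal(pf_ratio(3 * 100, 0.5), 3 * pf_ratio(100, 0.5))
})

test_that("alerts fire iff their inequality is strictly violated, over a grid", {
  th <- default_thresholds()
  grid <- expand.grid(
    ltvv = c(6, 7.99, 8, 8.01, 12),
    pf = c(150, 299.9, 300, 300.1, 450),
    fio2 = c(0.21, 0.39, 0.4, 0.41, 1.0)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    state <- list(
      ltvv = g$ltvv, pf_ratio = g$pf, FiO2 = g$fio2,
      Vt = g$ltvv * 60, PBW = 60, PO2 = g$pf * g$fio2
    )
    alerts <- evaluate_alerts(state, th)
    expect_identical("LTVV_HIGH" %in% alerts$kind, g$ltvv > 8)
    expect_identical("PF_LOW" %in% alerts$kind, g$pf < 300)
    expect_identical("FIO2_HIGH" %in% alerts$kind, g$fio2 >= 0.4)
  }
})

test_that("vital signs outside configured normal ranges raise alerts", {
  base <- list(Vt = 420, PBW = 60, PO2 = 180, FiO2 = 0.3)
  ok <- evaluate_alerts(c(base, list(HR = 80, RR = 16, SpO2 = 97, SBP = 120)))
  expect_identical(nrow(ok), 0L)
  bad <- evaluate_alerts(c(base, list(HR = 140, RR = 16, SpO2 = 88, SBP = 120)))
  expect_identical(sum(bad$kind == "VITAL_OUT_OF_RANGE"), 2L)
  expect_error(evaluate_alerts(list(HR = 80)),
    class = "icufusion_incomplete_state"
  )
})

test_that("patient-state fusion keeps the latest value per parameter with provenance", {
  reg <- code_registry()
  profile <- list(patient_id = "P001", sex = "male", height_cm = 170)
  t0 <- "2024-04-14T21:00:00Z"
  t1 <- "2024-04-14T22:00:00Z"
  mk <- function(time, hr) {
    make_observation(
      "vital-signs", "P001", time, "patient_monitor", "BED01",
      dplyr::bind_rows(
        obs_component("8867-4", hr, unit = "{beats}/min"),
        obs_component("76222-4", 450, unit = "mL"),
        obs_component("20139-2", 9.1, unit = "L/min"),
        obs_component("19994-3", 0.4, unit = "1"),
        obs_component("2019-8", 42, unit = "mm[Hg]"),
        obs_component("2703-1", 95, unit = "mm[Hg]")
      )
    )
  }
  obs <- dplyr::bind_rows(mk(t0, 70), mk(t1, 90))
  st <- fuse_patient_state(obs, profile, window_h = 6)
  expect_identical(st$HR, 90) # last write wins
  expect_equal(st$PBW, 66.016)
  prov <- attr(st, "provenance")
  expect_identical(prov$obs_id[prov$name == "HR"], 2L)

  # fusion is idempotent: fusing the same observations at the same time again
  st2 <- fuse_patient_state(obs, profile, window_h = 6, at_time = st$timestamp)
  expect_equal(as.data.frame(st2), as.data.frame(st))

  # stale observations outside the window are an incomplete-state error
  err <- expect_error(
    fuse_patient_state(obs, profile,
      window_h = 0.5,
      at_time = parse_iso8601("2024-04-15T09:00:00Z")
    ),
    class = "icufusion_incomplete_state"
  )
  expect_match(conditionMessage(err), "Vt")
})

test_that("the worked trajectory yields the printed indices and alert counts", {
  wc <- generate_worked_case()
  st0 <- fuse_patient_state(wc$observations, wc$profile,
    window_h = 6, at_time = wc$times[1]
  )
  idx0 <- compute_indices(st0)
  expect_equal(idx0$ltvv, 10.0)
  expect_equal(idx0$pf_ratio, 164)
  expect_equal(st0$FiO2, 1.0)
  a0 <- evaluate_alerts(st0)
  expect_setequal(a0$kind, c("LTVV_HIGH", "PF_LOW", "FIO2_HIGH"))
  expect_identical(nrow(a0), 3L)

  st1 <- fuse_patient_state(wc$observations, wc$profile,
    window_h = 6, at_time = wc$times[2]
  )
  expect_equal(compute_indices(st1)$ltvv, 6.1)
  expect_identical(nrow(evaluate_alerts(st1)), 0L)

  # the trajectory is fixed: two calls agree exactly
  expect_identical(
    as.data.frame(generate_worked_case()$observations),
    as.data.frame(wc$observations)
  )
})
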