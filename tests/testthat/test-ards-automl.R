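test_that("the default stage graph validates with eight output features", {
  g <- ards_stage_graph()
  expect_identical(nrow(g$nodes), 8L)
  expect_setequal(
    g$nodes$output,
    c("PBW", "FiO2", "PCO2", "PO2", "Ve", "Vt", "ards", "ventilatory_ratio")
  )
  expect_identical(g$label, "ards")
})

test_that("graph validation reports cycles, dangling inputs and missing labels", {
  expect_error(
    stage_graph(
      stage_node("x", "expression", "x", 1L, expr = "x + 1"),
      stage0 = "a", label = "x"
    ),
    class = "icufusion_graph_cycle"
  )
  expect_error(
    stage_graph(
      stage_node("y", "expression", "ghost", 1L, expr = "ghost * 2"),
      stage0 = "a", label = "y"
    ),
    class = "icufusion_graph_dangling"
  )
  expect_error(
    stage_graph(
      stage_node("y", "bypass", "a", 1L),
      stage0 = c("a", "lab"), label = "lab"
    ),
    class = "icufusion_graph_label"
  )
})

test_that("extraction matches direct clinical-index calls and drops incomplete rows", {
  dat <- generate_ards_dataset(200, seed = 21)
  ft <- extract_features(ards_stage_graph(), dat)
  expect_identical(attr(ft, "n_dropped"), 0L)
  expect_identical(ft$PBW, pbw(dat$sex, dat$height))
  expect_identical(
    ft$ventilatory_ratio,
    ventilatory_ratio(dat$Ve, dat$PCO2, dat$Vt, ft$PBW)
  )
  expect_identical(ft$FiO2, dat$FiO2) # bypass is the identity
  # referential transparency
  expect_identical(
    as.data.frame(extract_features(ards_stage_graph(), dat)),
    as.data.frame(ft)
  )
  # a row with a missing sensor feature is dropped and counted
  dat2 <- dat
  dat2$PCO2[5] <- NA
  ft2 <- extract_features(ards_stage_graph(), dat2)
  expect_identical(attr(ft2, "n_dropped"), 1L)
  expect_identical(nrow(ft2), nrow(dat) - 1L)
})

test_that("expression nodes evaluate restricted arithmetic and reject the rest", {
  g <- stage_graph(
    dplyr::bind_rows(
      stage_node("pf", "expression", c("PO2", "FiO2"), 1L, expr = "PO2 / FiO2"),
      stage_node("lab", "bypass", "lab", 1L)
    ),
    stage0 = c("PO2", "FiO2", "lab"), label = "lab"
  )
  dat <- tibble::tibble(PO2 = c(80, 164), FiO2 = c(0.5, 1), lab = c(0, 1))
  ft <- extract_features(g, dat)
  expect_identical(ft$pf, c(160, 164))
  bad <- stage_graph(
    dplyr::bind_rows(
      stage_node("z", "expression", "PO2", 1L, expr = "system(PO2)"),
      stage_node("lab", "bypass", "lab", 1L)
    ),
    stage0 = c("PO2", "lab"), label = "lab"
  )
  expect_error(extract_features(bad, dat), class = "icufusion_graph_error")
})

test_that("majority voting returns the modal label with a positive tie-break", {
  expect_identical(majority_vote(cbind(1, 0, 1)), 1L)
  expect_identical(majority_vote(cbind(0, 0, 1)), 0L)
  expect_warning(tie <- majority_vote(cbind(1, 0)), "tie")
  expect_identical(tie, 1L)
  for (x in c(0L, 1L)) {
    expect_identical(
      suppressWarnings(majority_vote(matrix(x, 3, 5))), rep(x, 3)
    )
  }
  expect_error(majority_vote(matrix(integer(), 0, 0)),
    class = "icufusion_validation_error"
  )
})

test_that("ensemble training reports per-member and fused metrics deterministically", {
  dat <- generate_ards_dataset(1000, seed = 31)
  ft <- extract_features(ards_stage_graph(), dat)
  fit <- train_ensemble(ft, seed = 31)
  expect_identical(fit$split$n_valid, 200L) # 0.8 split on n = 1000
  expect_identical(nrow(fit$member_metrics), 3L)
  expect_identical(nrow(fit$ensemble_metrics), 1L)
  expect_true(all(c("auc", "f1", "precision", "accuracy") %in% names(tidy(fit))))
  # deterministic under a fixed seed
  fit2 <- train_ensemble(ft, seed = 31)
  expect_identical(fit2$member_metrics, fit$member_metrics)
  expect_identical(fit2$ensemble_metrics, fit$ensemble_metrics)
  # prediction returns fused labels for every row
  pred <- predict(fit, ft[1:10, ])
  expect_identical(nrow(pred), 10L)
  expect_true(all(pred$label %in% c(0L, 1L)))
  # single-class tables are rejected
  ft1 <- ft[ft$ards == 1, ]
  expect_error(train_ensemble(ft1, seed = 1), class = "icufusion_single_class")
})

test_that("model selection is a deterministic argmax with declaration-order ties", {
  fit <- list(
    member_metrics = tibble::tibble(
      member = c("svm", "xgb", "mlp"),
      auc = c(0.81, 0.88, 0.84), f1 = c(0.7, 0.7, 0.7)
    ),
    spec = list(metric = "auc")
  )
  class(fit) <- "ards_ensemble"
  expect_identical(select_best(fit, "auc"), "xgb")
  expect_identical(select_best(fit, "f1"), "svm") # tie -> first declared
  expect_error(select_best(fit, "brier"), class = "icufusion_validation_error")
})
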