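# Multi-algorithm ensemble for ARDS classification.
#
# Three member families (support vector machine, gradient-boosted trees,
# multilayer perceptron) are fit on a train split and scored on a held-out
# validation split; predictions are fused by majority voting (default) or
# probability averaging. The best single member by a chosen metric can be
# selected afterwards.

ENSEMBLE_MEMBERS <- c("svm", "xgb", "mlp")
ENSEMBLE_METRICS <- c("auc", "f1", "precision", "accuracy")

#' Specify an ensemble
#'
#' @param members Classifier kinds among `"svm"`, `"xgb"`, `"mlp"`.
#' @param train_fraction Train split fraction in (0, 1).
#' @param fusion `"majority_vote"` (hard votes; even-count ties break toward
#'   the positive class with a warning) or `"averaging"` (mean member
#'   probability).
#' @param metric Selection metric: `"auc"`, `"f1"`, `"precision"` or
#'   `"accuracy"`.
#' @param hyperparameters Named list of per-member hyperparameter overrides,
#'   e.g. `list(xgb = list(nrounds = 50))`. Member defaults are the fitting
#'   libraries' defaults, recorded in the run manifest.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(members = c("svm", "xgb", "mlp"),
                          train_fraction = 0.8,
                          fusion = c("majority_vote", "averaging"),
                          metric = "auc",
                          hyperparameters = list()) {
  fusion <- match.arg(fusion)
  if (length(members) < 1L || !all(members %in% ENSEMBLE_MEMBERS)) {
    stop_icufusion(
      paste0("members must be among: ", toString(ENSEMBLE_MEMBERS)),
      "icufusion_validation_error"
    )
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_icufusion("train_fraction must be in (0, 1)",
      "icufusion_validation_error")
  }
  if (!metric %in% ENSEMBLE_METRICS) {
    stop_icufusion(paste0("unknown metric '", metric, "'"),
      "icufusion_validation_error")
  }
  structure(
    list(
      members = members, train_fraction = train_fraction,
      fusion = fusion, metric = metric, hyperparameters = hyperparameters
    ),
    class = "ensemble_spec"
  )
}

#' Fuse binary member predictions by majority vote
#'
#' Returns the modal label per row. With an even member count, exact ties
#' break toward the positive class (clinically conservative for a disease
#' label) and a warning is raised once.
#'
#' @param votes A matrix or data frame of 0/1 member predictions, one column
#'   per member, or a vector for a single row.
#' @return Integer vector of fused 0/1 labels.
#' @examples
#' majority_vote(cbind(c(1, 0), c(0, 0), c(1, 1))) # 1, 0
#' @export
majority_vote <- function(votes) {
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  votes <- as.matrix(votes)
  if (ncol(votes) == 0L || nrow(votes) == 0L) {
    stop_icufusion("empty prediction set", "icufusion_validation_error")
  }
  frac <- rowMeans(votes)
  ties <- abs(frac - 0.5) < 1e-12
  if (any(ties)) {
    rlang::warn(paste0(
      sum(ties), " tied vote(s) broken toward the positive class"
    ))
  }
  as.integer(frac >= 0.5)
}

encode_features <- function(table, label) {
  x <- table[, setdiff(names(table), label), drop = FALSE]
  for (nm in names(x)) {
    if (is.character(x[[nm]]) || is.factor(x[[nm]])) {
      x[[nm]] <- as.numeric(factor(x[[nm]], levels = sort(unique(as.character(x[[nm]])))))
    }
  }
  as.matrix(x)
}

fit_member <- function(kind, x, y, hp, seed) {
  set.seed(seed)
  if (kind == "svm") {
    args <- utils::modifyList(
      list(
        x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
        kernel = "radial"
      ),
      hp %||% list()
    )
    fit <- do.call(e1071::svm, args)
    scaler <- NULL
  } else if (kind == "xgb") {
    params <- utils::modifyList(
      list(
        objective = "binary:logistic", max_depth = 4, eta = 0.1,
        nthread = 1, seed = seed
      ),
      hp$params %||% list()
    )
    fit <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$nrounds %||% 100, verbose = 0
    )
    scaler <- NULL
  } else if (kind == "mlp") {
    scaler <- list(center = colMeans(x), scale = apply(x, 2, stats::sd))
    scaler$scale[scaler$scale == 0] <- 1
    xs <- scale(x, scaler$center, scaler$scale)
    args <- utils::modifyList(
      list(
        x = xs, y = y, size = 8, decay = 0.01, maxit = 300,
        trace = FALSE, entropy = TRUE
      ),
      hp %||% list()
    )
    fit <- do.call(nnet::nnet, args)
  } else {
    stop_icufusion(paste0("unknown member kind '", kind, "'"),
      "icufusion_validation_error")
  }
  list(kind = kind, fit = fit, scaler = scaler)
}

predict_member <- function(member, x) {
  if (member$kind == "svm") {
    p <- stats::predict(member$fit, x, probability = TRUE)
    as.numeric(attr(p, "probabilities")[, "1"])
  } else if (member$kind == "xgb") {
    as.numeric(stats::predict(member$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  } else {
    xs <- scale(x, member$scaler$center, member$scaler$scale)
    as.numeric(stats::predict(member$fit, xs))
  }
}

metric_row <- function(prob, truth, pred = as.integer(prob >= 0.5)) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  auc <- as.numeric(pROC::auc(pROC::roc(truth, prob,
    quiet = TRUE, direction = "<", levels = c(0, 1)
  )))
  tibble::tibble(
    auc = auc, f1 = f1, precision = precision,
    accuracy = mean(pred == truth)
  )
}

#' Train the ARDS classification ensemble
#'
#' Splits the feature table into train/validation by the configured ratio,
#' fits each member, scores members and the fused rule on the validation
#' split, and returns a fitted bundle. Deterministic under a fixed seed.
#'
#' @param table Feature table with a binary label column (both classes
#'   present); e.g. the output of [extract_features()] or
#'   [generate_ards_dataset()].
#' @param spec An [ensemble_spec()].
#' @param seed RNG seed controlling the split and member fits.
#' @param label Label column name; defaults to `attr(table, "label")` or
#'   `"ards"`.
#' @return An `ards_ensemble` object with elements `members`,
#'   `member_metrics`, `ensemble_metrics`, `spec`, `seed`, `split`,
#'   `manifest`.
#' @export
train_ensemble <- function(table, spec = ensemble_spec(), seed = 1L,
                           label = NULL) {
  label <- label %||% attr(table, "label") %||% "ards"
  if (!label %in% names(table)) {
    stop_icufusion(paste0("label column '", label, "' not in table"),
      "icufusion_validation_error")
  }
  y <- as.integer(table[[label]])
  if (length(unique(y)) < 2L) {
    stop_icufusion("label has a single class; cannot train",
      "icufusion_single_class")
  }
  x <- encode_features(table, label)
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_train <- as.integer(floor(spec$train_fraction * n))
  idx <- sample.int(n, n_train)
  x_tr <- x[idx, , drop = FALSE]
  y_tr <- y[idx]
  x_va <- x[-idx, , drop = FALSE]
  y_va <- y[-idx]
  members <- purrr::imap(
    stats::setNames(spec$members, spec$members),
    function(kind, nm) {
      fit_member(kind, x_tr, y_tr,
        hp = spec$hyperparameters[[kind]],
        seed = seed + match(kind, spec$members)
      )
    }
  )
  probs <- purrr::map(members, predict_member, x = x_va)
  member_metrics <- purrr::imap(probs, function(p, nm) {
    dplyr::mutate(metric_row(p, y_va), member = nm, .before = 1)
  }) |> dplyr::bind_rows()
  vote_mat <- vapply(probs, function(p) as.integer(p >= 0.5), integer(length(y_va)))
  # hard votes decide the fused label; the averaged probability provides the
  # continuous ranking score that AUC needs (vote fractions are too coarse)
  fused_score <- rowMeans(do.call(cbind, probs))
  fused_label <- if (spec$fusion == "majority_vote") {
    suppressWarnings(majority_vote(vote_mat))
  } else {
    as.integer(fused_score >= 0.5)
  }
  ensemble_metrics <- dplyr::mutate(
    metric_row(fused_score, y_va, pred = fused_label),
    member = paste0("ensemble_", spec$fusion), .before = 1
  )
  structure(
    list(
      members = members, member_metrics = member_metrics,
      ensemble_metrics = ensemble_metrics, spec = spec, seed = seed,
      label = label,
      split = list(n = n, n_train = n_train, n_valid = n - n_train),
      manifest = list(
        seed = seed, members = spec$members,
        train_fraction = spec$train_fraction, fusion = spec$fusion,
        metric = spec$metric,
        hyperparameters = spec$hyperparameters,
        n = n, n_train = n_train, n_valid = n - n_train
      )
    ),
    class = "ards_ensemble"
  )
}

#' @export
print.ards_ensemble <- function(x, ...) {
  cat(
    "<ards_ensemble>", toString(x$spec$members), "| fusion:", x$spec$fusion,
    sprintf(
      "| n = %d (train %d / valid %d)\n",
      x$split$n, x$split$n_train, x$split$n_valid
    )
  )
  print(dplyr::bind_rows(x$member_metrics, x$ensemble_metrics))
  invisible(x)
}

#' @describeIn train_ensemble Per-member validation metrics, one row per
#'   member plus one for the fused rule.
#' @param x An `ards_ensemble`.
#' @param ... Unused.
#' @method tidy ards_ensemble
#' @export
tidy.ards_ensemble <- function(x, ...) {
  dplyr::bind_rows(x$member_metrics, x$ensemble_metrics)
}

#' @describeIn train_ensemble One-row summary of the fitted ensemble.
#' @method glance ards_ensemble
#' @export
glance.ards_ensemble <- function(x, ...) {
  tibble::tibble(
    n = x$split$n, n_train = x$split$n_train, n_valid = x$split$n_valid,
    n_members = length(x$members), fusion = x$spec$fusion,
    ensemble_auc = x$ensemble_metrics$auc,
    best_member = select_best(x, x$spec$metric),
    seed = x$seed
  )
}

#' Predict with a fitted ensemble
#'
#' @param object An `ards_ensemble`.
#' @param newdata Feature table (label column, if present, is ignored).
#' @param ... Unused.
#' @return A tibble with per-member probabilities, the fused score, and the
#'   fused 0/1 label.
#' @export
predict.ards_ensemble <- function(object, newdata, ...) {
  x <- encode_features(
    newdata[, setdiff(names(newdata), object$label), drop = FALSE],
    label = ""
  )
  probs <- purrr::map(object$members, predict_member, x = x)
  vote_mat <- vapply(probs, function(p) as.integer(p >= 0.5), integer(nrow(x)))
  if (is.null(dim(vote_mat))) vote_mat <- matrix(vote_mat, nrow = nrow(x))
  fused <- if (object$spec$fusion == "majority_vote") {
    suppressWarnings(majority_vote(vote_mat))
  } else {
    as.integer(rowMeans(do.call(cbind, probs)) >= 0.5)
  }
  out <- tibble::as_tibble(stats::setNames(probs, paste0("prob_", names(probs))))
  out$score <- if (object$spec$fusion == "majority_vote") {
    rowMeans(vote_mat)
  } else {
    rowMeans(do.call(cbind, probs))
  }
  out$label <- fused
  out
}

#' Select the best ensemble member by a metric
#'
#' Deterministic argmax over the validation metrics; ties break by member
#' declaration order.
#'
#' @param fit An `ards_ensemble`.
#' @param metric Metric name present in the member metrics.
#' @return The winning member id (e.g. `"xgb"`).
#' @export
select_best <- function(fit, metric = fit$spec$metric) {
  mm <- fit$member_metrics
  if (!metric %in% names(mm)) {
    stop_icufusion(paste0("metric '", metric, "' not computed"),
      "icufusion_validation_error")
  }
  mm$member[which.max(mm[[metric]])]
}

#' Write the run manifest of a fitted ensemble as JSON
#'
#' @param fit An `ards_ensemble`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(fit, path) {
  manifest <- fit$manifest
  manifest$member_metrics <- fit$member_metrics
  manifest$ensemble_metrics <- fit$ensemble_metrics
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
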