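# Staged feature-extraction graphs.
#
# Features are computed in stages: Stage 0 holds raw sensor features; later
# stages hold derived features. A node is a built-in function (predicted body
# weight, ventilatory ratio), a bypass (identity copy), or a restricted
# arithmetic expression. Nodes may consume only features available at earlier
# stages or same-stage predecessors already computed, which makes every valid
# graph acyclic with a fixed deterministic evaluation order.

STAGE_NODE_KINDS <- c(
  "builtin_pbw", "builtin_ventilatory_ratio", "bypass", "expression"
)

#' Declare a stage-graph node
#'
#' @param output Output feature name.
#' @param kind One of `"builtin_pbw"` (inputs: sex, height), `
#'   "builtin_ventilatory_ratio"` (inputs: Ve, PCO2, Vt, PBW), `"bypass"`
#'   (one input, copied unchanged) or `"expression"`.
#' @param inputs Character vector of consumed feature names.
#' @param stage Stage index (>= 1); stage 0 is the raw input table.
#' @param expr For `kind = "expression"`: an arithmetic expression string
#'   over feature names (operators `+ - * /`, parentheses, numeric
#'   literals only).
#' @return A one-row node tibble.
#' @export
stage_node <- function(output, kind, inputs, stage, expr = NA_character_) {
  if (!kind %in% STAGE_NODE_KINDS) {
    stop_icufusion(paste0("unknown node kind '", kind, "'"),
      "icufusion_graph_error")
  }
  tibble::tibble(
    output = output, kind = kind, inputs = list(inputs),
    stage = as.integer(stage), expr = expr
  )
}

#' Assemble and validate a stage graph
#'
#' @param nodes Node tibble built from [stage_node()] rows.
#' @param stage0 Character vector of raw (Stage 0) feature names.
#' @param label Name of the binary label feature; must appear among the
#'   graph's output features (typically via a bypass node).
#' @return A validated `stage_graph` object.
#' @export
stage_graph <- function(nodes, stage0, label) {
  graph <- structure(
    list(nodes = nodes, stage0 = stage0, label = label),
    class = "stage_graph"
  )
  validate_graph(graph)
}

#' Validate a stage graph
#'
#' Checks that every node input resolves to a Stage-0 feature or an
#' already-computed output (self-consumption is reported as a cycle), that
#' node kinds and built-in signatures are well-formed, and that exactly one
#' label column is flagged and produced.
#'
#' @param graph A `stage_graph` (or a list with `nodes`, `stage0`, `label`).
#' @return The validated `stage_graph`, with nodes sorted into evaluation
#'   order.
#' @export
validate_graph <- function(graph) {
  nodes <- graph$nodes
  if (nrow(nodes) == 0L) {
    stop_icufusion("graph has no nodes", "icufusion_graph_error")
  }
  nodes <- nodes[order(nodes$stage), ]
  if (anyDuplicated(nodes$output) > 0) {
    stop_icufusion("duplicate output feature names", "icufusion_graph_error")
  }
  available <- graph$stage0
  for (i in seq_len(nrow(nodes))) {
    ins <- nodes$inputs[[i]]
    out <- nodes$output[i]
    dangling <- setdiff(ins, available)
    # a bypass may shadow an already-available name (identity copy); a node
    # whose unavailable input is its own output is a genuine cycle
    if (out %in% dangling) {
      stop_icufusion(
        paste0("cycle: node '", out, "' consumes its own output"),
        "icufusion_graph_cycle"
      )
    }
    if (length(dangling) > 0) {
      stop_icufusion(
        paste0(
          "node '", out, "' consumes unresolved feature(s): ",
          toString(dangling)
        ),
        "icufusion_graph_dangling"
      )
    }
    kind <- nodes$kind[i]
    if (kind == "builtin_pbw" && !setequal(ins, c("sex", "height"))) {
      stop_icufusion("builtin_pbw requires inputs {sex, height}",
        "icufusion_graph_error")
    }
    if (kind == "builtin_ventilatory_ratio" &&
      !setequal(ins, c("Ve", "PCO2", "Vt", "PBW"))) {
      stop_icufusion(
        "builtin_ventilatory_ratio requires inputs {Ve, PCO2, Vt, PBW}",
        "icufusion_graph_error"
      )
    }
    if (kind == "bypass" && length(ins) != 1L) {
      stop_icufusion("bypass nodes take exactly one input",
        "icufusion_graph_error")
    }
    if (kind == "expression" && (is.na(nodes$expr[i]) || !nzchar(nodes$expr[i]))) {
      stop_icufusion("expression nodes require an expr",
        "icufusion_graph_error")
    }
    available <- c(available, out)
  }
  if (length(graph$label) != 1L || !graph$label %in% nodes$output) {
    stop_icufusion("exactly one label column must be flagged and produced",
      "icufusion_graph_label"
    )
  }
  graph$nodes <- nodes
  graph
}

#' @export
print.stage_graph <- function(x, ...) {
  cat(
    "<stage_graph>", nrow(x$nodes), "nodes over stages",
    paste(sort(unique(x$nodes$stage)), collapse = ","),
    "| label:", x$label, "\n"
  )
  invisible(x)
}

#' The default ARDS feature-extraction graph
#'
#' Stage 1 computes predicted body weight from height and sex and bypasses
#' the six sensor features (FiO2, PCO2, PO2, Ve, Vt and the ARDS label);
#' Stage 2 computes the ventilatory ratio from PBW, PCO2, Ve and Vt. Eight
#' output features in total.
#'
#' @return A validated `stage_graph`.
#' @export
ards_stage_graph <- function() {
  bypass <- purrr::map(
    c("FiO2", "PCO2", "PO2", "Ve", "Vt", "ards"),
    function(f) stage_node(f, "bypass", f, stage = 1L)
  )
  nodes <- dplyr::bind_rows(
    stage_node("PBW", "builtin_pbw", c("sex", "height"), stage = 1L),
    bypass,
    stage_node(
      "ventilatory_ratio", "builtin_ventilatory_ratio",
      c("Ve", "PCO2", "Vt", "PBW"), stage = 2L
    )
  )
  stage_graph(nodes,
    stage0 = c("FiO2", "PCO2", "PO2", "Ve", "Vt", "height", "sex", "ards"),
    label = "ards"
  )
}

# Restricted arithmetic evaluator: only + - * / ( ), numeric literals and
# known feature names may appear. Anything else is rejected before eval.
safe_arith_eval <- function(expr_string, data, allowed) {
  expr <- tryCatch(
    str2lang(expr_string),
    error = function(e) {
      stop_icufusion(paste0("unparseable expression: ", expr_string),
        "icufusion_graph_error")
    }
  )
  check <- function(e) {
    if (is.numeric(e)) {
      return(invisible(TRUE))
    }
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% allowed) {
        stop_icufusion(
          paste0("expression references unknown feature '", nm, "'"),
          "icufusion_graph_dangling"
        )
      }
      return(invisible(TRUE))
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% c("+", "-", "*", "/", "(")) {
        stop_icufusion(
          paste0("operator '", op, "' not allowed in feature expressions"),
          "icufusion_graph_error"
        )
      }
      for (a in as.list(e)[-1]) check(a)
      return(invisible(TRUE))
    }
    stop_icufusion("unsupported expression element", "icufusion_graph_error")
  }
  check(expr)
  eval(expr, envir = data, enclos = baseenv())
}

#' Evaluate a stage graph over a record table
#'
#' Built-in nodes call the clinical-index functions directly (identical
#' results to calling [pbw()] / [ventilatory_ratio()] by hand); bypass nodes
#' copy values unchanged. Rows with missing values in any consumed Stage-0
#' feature are dropped before evaluation and counted in
#' `attr(result, "n_dropped")`.
#'
#' @param graph A validated `stage_graph`.
#' @param records Tibble providing the Stage-0 features as columns.
#' @return A feature table whose columns are the graph's output features, in
#'   node evaluation order.
#' @export
extract_features <- function(graph, records) {
  graph <- validate_graph(graph)
  used0 <- intersect(
    unique(unlist(graph$nodes$inputs)), graph$stage0
  )
  missing_cols <- setdiff(used0, names(records))
  if (length(missing_cols) > 0) {
    stop_icufusion(
      paste0("records lack Stage-0 feature(s): ", toString(missing_cols)),
      "icufusion_graph_dangling"
    )
  }
  keep <- stats::complete.cases(records[, used0, drop = FALSE])
  dropped <- sum(!keep)
  data <- records[keep, , drop = FALSE]
  for (i in seq_len(nrow(graph$nodes))) {
    node <- graph$nodes[i, ]
    data[[node$output]] <- switch(node$kind,
      bypass = data[[node$inputs[[1]]]],
      builtin_pbw = pbw(data$sex, data$height),
      builtin_ventilatory_ratio = ventilatory_ratio(
        data$Ve, data$PCO2, data$Vt, data$PBW
      ),
      expression = safe_arith_eval(node$expr, data, allowed = names(data))
    )
  }
  out <- tibble::as_tibble(data[, graph$nodes$output, drop = FALSE])
  attr(out, "n_dropped") <- dropped
  attr(out, "label") <- graph$label
  out
}
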