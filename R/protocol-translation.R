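# Device-feature management and message translation.
#
# Each mappable datum of a device's output format is a "device feature" (DF):
# category + name + dialect-specific locator + value type + optional range.
# A deterministic table-driven parser is compiled from the registered DFs of
# one (category, dialect); raw messages are tokenized against it and the
# extracted values are lifted into FHIR-style observation records.

DIALECTS <- c("hl7v2", "json", "proprietary")

empty_df_registry <- function() {
  reg <- tibble::tibble(
    category = character(), name = character(), dialect = character(),
    locator = character(), value_type = character(),
    range_low = numeric(), range_high = numeric(),
    delimiter = character(), kv_delim = character()
  )
  attr(reg, "audit") <- tibble::tibble(
    action = character(), category = character(), name = character(),
    detail = character()
  )
  reg
}

#' Load the device-feature registry
#'
#' @param path Path to a DF registry JSON file; defaults to the shipped asset
#'   covering five device categories (patient monitors via HL7 v2, infusion
#'   pumps via JSON, ventilators / hemodynamics monitors / hematology
#'   analyzers via proprietary delimited records).
#' @return A DF registry tibble (see [register_feature()] for the columns).
#' @export
df_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "device_features.json",
    package = "icufusion", mustWork = TRUE
  )
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reg <- empty_df_registry()
  for (f in raw$features) {
    reg <- register_feature(
      reg,
      category = f$category, name = f$name, dialect = f$dialect,
      locator = f$locator, value_type = f$value_type %||% "decimal",
      range = if (!is.null(f$range)) unlist(f$range),
      delimiter = f$delimiter %||% NA_character_,
      kv_delim = f$kv_delim %||% NA_character_
    )
  }
  reg
}

#' Register (or replace) a device feature
#'
#' Re-registering an existing `(category, name)` pair replaces the entry and
#' appends a replacement record to the registry's audit log (available as
#' `attr(registry, "audit")`).
#'
#' @param registry A DF registry tibble, e.g. from [df_registry()] or
#'   `register_feature()` chained from an empty registry.
#' @param category Device category, e.g. `"hemodynamics_monitor"`.
#' @param name Canonical feature name; must resolve in [code_registry()] for
#'   translation to succeed.
#' @param dialect One of `"hl7v2"`, `"json"`, `"proprietary"`.
#' @param locator Dialect-specific locator: OBX-3 identifier (hl7v2), key
#'   path with `/` separators (json), or token label (proprietary).
#' @param value_type `"decimal"`, `"integer"` or `"string"`.
#' @param range Optional numeric `c(low, high)` with `low < high`.
#' @param delimiter,kv_delim Field and key-value delimiters; required for the
#'   proprietary dialect.
#' @return The updated registry tibble.
#' @export
register_feature <- function(registry, category, name, dialect, locator,
                             value_type = "decimal", range = NULL,
                             delimiter = NA_character_,
                             kv_delim = NA_character_) {
  if (!dialect %in% DIALECTS) {
    stop_icufusion(paste0("unknown dialect '", dialect, "'"),
      "icufusion_validation_error")
  }
  if (!is.null(range)) {
    if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
      stop_icufusion("value range must satisfy low < high",
        "icufusion_validation_error")
    }
  }
  if (dialect == "proprietary" &&
    (is.na(delimiter) || !nzchar(delimiter) ||
      is.na(kv_delim) || !nzchar(kv_delim))) {
    stop_icufusion("proprietary features require delimiter and kv_delim",
      "icufusion_validation_error")
  }
  audit <- attr(registry, "audit")
  dup <- registry$category == category & registry$name == name
  if (any(dup)) {
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      action = "replace", category = category, name = name,
      detail = paste0("locator ", registry$locator[dup][1], " -> ", locator)
    ))
    registry <- registry[!dup, ]
  }
  out <- dplyr::bind_rows(registry, tibble::tibble(
    category = category, name = name, dialect = dialect, locator = locator,
    value_type = value_type,
    range_low = if (is.null(range)) NA_real_ else range[1],
    range_high = if (is.null(range)) NA_real_ else range[2],
    delimiter = delimiter, kv_delim = kv_delim
  ))
  attr(out, "audit") <- audit
  out
}

#' Compile parsing rules for one device category and dialect
#'
#' Compilation is pure: the same registry content yields byte-identical
#' rules. The rules are stamped with a content hash of the contributing
#' registry rows (`compiled_from`) rather than wall-clock time, so recompiles
#' are reproducible.
#'
#' @param registry A DF registry tibble.
#' @param category Device category to compile.
#' @param dialect Message dialect to compile.
#' @return A `parser_rules` object.
#' @export
compile_parser <- function(registry, category, dialect) {
  sel <- registry[registry$category == category & registry$dialect == dialect, ]
  if (nrow(sel) == 0L) {
    stop_icufusion(
      paste0("no device features registered for (", category, ", ", dialect, ")"),
      "icufusion_empty_category"
    )
  }
  rules <- tibble::tibble(
    locator = sel$locator, name = sel$name, value_type = sel$value_type,
    range_low = sel$range_low, range_high = sel$range_high
  )
  if (anyDuplicated(rules$locator) > 0) {
    stop_icufusion("ambiguous rules: one locator maps to several names",
      "icufusion_validation_error")
  }
  delims <- unique(stats::na.omit(sel$delimiter))
  kvs <- unique(stats::na.omit(sel$kv_delim))
  if (dialect == "proprietary" && (length(delims) != 1L || length(kvs) != 1L)) {
    stop_icufusion("proprietary category must declare a single delimiter pair",
      "icufusion_validation_error")
  }
  structure(
    list(
      category = category, dialect = dialect, rules = rules,
      delimiter = if (length(delims)) delims else NA_character_,
      kv_delim = if (length(kvs)) kvs else NA_character_,
      compiled_from = rlang::hash(rules)
    ),
    class = "parser_rules"
  )
}

#' @export
print.parser_rules <- function(x, ...) {
  cat(
    "<parser_rules> category:", x$category, " dialect:", x$dialect,
    " rules:", nrow(x$rules), "\n"
  )
  invisible(x)
}

typed_value <- function(raw, value_type, where) {
  out <- switch(value_type,
    decimal = suppressWarnings(as.numeric(raw)),
    integer = suppressWarnings(as.integer(raw)),
    string = as.character(raw),
    stop_icufusion(paste0("unknown value type '", value_type, "'"),
      "icufusion_validation_error")
  )
  if (value_type != "string" && is.na(out)) {
    stop_icufusion(
      paste0("undecodable ", value_type, " value '", raw, "' at ", where),
      "icufusion_parse_error"
    )
  }
  out
}

parse_hl7v2_payload <- function(payload, rules) {
  segs <- strsplit(payload, "\r\n|\r|\n")[[1]]
  segs <- segs[nzchar(segs)]
  hits <- list()
  residue <- character()
  for (seg in segs) {
    f <- strsplit(seg, "|", fixed = TRUE)[[1]]
    if (f[1] != "OBX") next
    # OBX-n sits at f[n + 1]; OBX-3 = identifier, OBX-5 = value, OBX-6 = unit
    obx3 <- if (length(f) >= 4) f[4] else ""
    code <- strsplit(obx3, "^", fixed = TRUE)[[1]][1]
    val <- if (length(f) >= 6) f[6] else ""
    unit <- if (length(f) >= 7) f[7] else NA_character_
    rule <- rules$rules[rules$rules$locator == code, ]
    if (nrow(rule) == 1L) {
      hits[[length(hits) + 1L]] <- list(
        name = rule$name,
        value = typed_value(val, rule$value_type, paste0("OBX ", code)),
        unit = unit, locator = code,
        range = c(rule$range_low, rule$range_high)
      )
    } else {
      residue <- c(residue, code)
    }
  }
  list(hits = hits, residue = residue)
}

json_path_get <- function(obj, path) {
  for (k in strsplit(path, "/", fixed = TRUE)[[1]]) {
    if (!is.list(obj) || is.null(obj[[k]])) {
      return(NULL)
    }
    obj <- obj[[k]]
  }
  obj
}

parse_json_payload <- function(payload, rules) {
  obj <- tryCatch(
    jsonlite::fromJSON(payload, simplifyVector = FALSE),
    error = function(e) {
      stop_icufusion(paste0("undecodable JSON payload: ", conditionMessage(e)),
        "icufusion_parse_error")
    }
  )
  hits <- list()
  for (i in seq_len(nrow(rules$rules))) {
    rule <- rules$rules[i, ]
    v <- json_path_get(obj, rule$locator)
    if (is.null(v)) next
    hits[[length(hits) + 1L]] <- list(
      name = rule$name,
      value = typed_value(v, rule$value_type, rule$locator),
      unit = NA_character_, locator = rule$locator,
      range = c(rule$range_low, rule$range_high)
    )
  }
  consumed <- vapply(
    rules$rules$locator,
    function(p) strsplit(p, "/", fixed = TRUE)[[1]][1], ""
  )
  residue <- setdiff(names(obj), consumed)
  list(hits = hits, residue = residue)
}

parse_proprietary_payload <- function(payload, rules) {
  tokens <- strsplit(payload, rules$delimiter, fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  hits <- list()
  residue <- character()
  for (tok in tokens) {
    pos <- regexpr(rules$kv_delim, tok, fixed = TRUE)
    if (pos < 0) {
      stop_icufusion(
        paste0("undecodable token '", tok, "' (no '", rules$kv_delim, "')"),
        "icufusion_parse_error"
      )
    }
    label <- substr(tok, 1L, pos - 1L)
    raw <- substr(tok, pos + attr(pos, "match.length"), nchar(tok))
    rule <- rules$rules[rules$rules$locator == label, ]
    if (nrow(rule) == 1L) {
      hits[[length(hits) + 1L]] <- list(
        name = rule$name,
        value = typed_value(raw, rule$value_type, label),
        unit = NA_character_, locator = label,
        range = c(rule$range_low, rule$range_high)
      )
    } else {
      residue <- c(residue, label)
    }
  }
  list(hits = hits, residue = residue)
}

#' Parse one raw device message against compiled rules
#'
#' Extracted values are type-checked and range-checked; out-of-range values
#' are flagged (`in_range = FALSE`) but never dropped — clinical extremes are
#' signal, not noise. Payload tokens matching no rule are reported as residue
#' in `attr(result, "residue")`.
#'
#' @param msg A raw message: a list or one-row tibble with at least
#'   `dialect` and `payload`.
#' @param rules A `parser_rules` object for the matching dialect.
#' @return A tibble with columns `name`, `value` (list-column of typed
#'   values), `unit`, `locator`, `in_range`.
#' @export
parse_message <- function(msg, rules) {
  stopifnot(inherits(rules, "parser_rules"))
  msg <- as.list(msg)
  if (is.null(msg$payload) || !nzchar(msg$payload)) {
    stop_icufusion("payload must be non-empty", "icufusion_validation_error")
  }
  if (!identical(msg$dialect, rules$dialect)) {
    stop_icufusion(
      paste0(
        "dialect mismatch: message is '", msg$dialect,
        "', rules are '", rules$dialect, "'"
      ),
      "icufusion_dialect_mismatch"
    )
  }
  parsed <- switch(rules$dialect,
    hl7v2 = parse_hl7v2_payload(msg$payload, rules),
    json = parse_json_payload(msg$payload, rules),
    proprietary = parse_proprietary_payload(msg$payload, rules)
  )
  hits <- parsed$hits
  out <- tibble::tibble(
    name = purrr::map_chr(hits, "name"),
    value = purrr::map(hits, "value"),
    unit = purrr::map_chr(hits, "unit"),
    locator = purrr::map_chr(hits, "locator"),
    in_range = purrr::map_lgl(hits, function(h) {
      v <- h$value
      if (!is.numeric(v) || anyNA(h$range)) {
        return(TRUE)
      }
      v >= h$range[1] && v <= h$range[2]
    })
  )
  attr(out, "residue") <- parsed$residue
  out
}

obs_category_for <- function(device_category) {
  switch(device_category,
    patient_monitor = "vital-signs",
    ventilator = "ventilator",
    hemodynamics_monitor = "hemodynamics",
    infusion_pump = "infusion",
    hematology_analyzer = "laboratory",
    his = "medical-record",
    device_category
  )
}

#' Translate a raw device message into an observation record
#'
#' Parsed values become observation components carrying LOINC codes and UCUM
#' units from the code registry; numeric values pass through bit-identically.
#' The effective time is the device-reported time when present, otherwise the
#' gateway receive time. A missing patient identifier yields
#' `subject = "UNKNOWN"` with a warning. FiO2 values above 1 are interpreted
#' as percentages and normalized to the fraction convention.
#'
#' @param msg Raw message (list or one-row tibble) with `category`, `dialect`,
#'   `payload`, `received_time`, and optionally `device_time`, `patient_id`,
#'   `source_device_id`, `location`.
#' @param rules A `parser_rules` object.
#' @param registry Code registry tibble.
#' @return A one-row observation tibble; the parse flags (out-of-range,
#'   residue) are attached as attributes `flags` and `residue`.
#' @export
translate <- function(msg, rules, registry = code_registry()) {
  msg <- as.list(msg)
  parsed <- parse_message(msg, rules)
  if (nrow(parsed) == 0L) {
    stop_icufusion("no extractable features in payload",
      "icufusion_empty_translation")
  }
  subject <- msg$patient_id
  if (is.null(subject) || is.na(subject) || !nzchar(subject)) {
    rlang::warn("message has no patient identifier; using subject 'UNKNOWN'")
    subject <- "UNKNOWN"
  }
  eff <- msg$device_time
  if (is.null(eff) || (length(eff) == 1L && is.na(eff))) eff <- msg$received_time
  components <- purrr::map(seq_len(nrow(parsed)), function(i) {
    name <- parsed$name[i]
    entry <- lookup_code(name, registry)
    v <- parsed$value[[i]]
    if (identical(name, "FiO2") && is.numeric(v) && v > 1) v <- v / 100
    obs_component(entry$loinc, v, display = entry$display, unit = entry$unit)
  }) |> dplyr::bind_rows()
  out <- make_observation(
    code = obs_category_for(msg$category),
    subject = subject,
    effective_time = eff,
    device_type = msg$category %||% "unknown",
    device_location = msg$location %||% "unknown",
    components = components
  )
  attr(out, "flags") <- parsed[!parsed$in_range, c("name", "locator")]
  attr(out, "residue") <- attr(parsed, "residue")
  out
}

#' Translate a corpus of raw messages
#'
#' Compiles one parser per `(category, dialect)` present in the corpus and
#' translates every message, preserving corpus order. Value conservation
#' holds: every emitted feature value appears as exactly one component.
#'
#' @param messages Raw-message tibble with columns `category`, `dialect`,
#'   `payload`, `received_time`, `patient_id`, `source_device_id`, `location`
#'   (and optionally `device_time`).
#' @param dfm DF registry tibble.
#' @param registry Code registry tibble.
#' @return An observation tibble with one record per message.
#' @export
translate_corpus <- function(messages, dfm = df_registry(),
                             registry = code_registry()) {
  keys <- unique(messages[, c("category", "dialect")])
  parsers <- purrr::pmap(keys, function(category, dialect) {
    compile_parser(dfm, category, dialect)
  })
  names(parsers) <- paste(keys$category, keys$dialect, sep = "\r")
  recs <- purrr::map(seq_len(nrow(messages)), function(i) {
    msg <- as.list(messages[i, ])
    if (!is.null(msg$received_time) && inherits(msg$received_time, "POSIXct")) {
      msg$received_time <- msg$received_time
    }
    translate(msg, parsers[[paste(msg$category, msg$dialect, sep = "\r")]],
      registry = registry
    )
  })
  out <- dplyr::bind_rows(recs)
  # per-record parse flags are meaningless after binding
  attr(out, "flags") <- NULL
  attr(out, "residue") <- NULL
  out
}

#' Write raw device messages as NDJSON
#'
#' @param messages Raw-message tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raw_ndjson <- function(messages, path) {
  lines <- purrr::map_chr(seq_len(nrow(messages)), function(i) {
    m <- as.list(messages[i, ])
    m$received_time <- format_iso8601(m$received_time)
    jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read raw device messages from NDJSON
#'
#' @param path Path to an NDJSON file written by [write_raw_ndjson()].
#' @return A raw-message tibble.
#' @export
read_raw_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  purrr::imap(lines, function(line, i) {
    m <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        stop_icufusion(paste0("malformed NDJSON at line ", i),
          "icufusion_parse_error", line = i)
      }
    )
    tibble::tibble(
      category = m$category, dialect = m$dialect, payload = m$payload,
      received_time = parse_iso8601(m$received_time),
      source_device_id = m$source_device_id %||% NA_character_,
      patient_id = m$patient_id %||% NA_character_,
      location = m$location %||% NA_character_
    )
  }) |> dplyr::bind_rows()
}
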