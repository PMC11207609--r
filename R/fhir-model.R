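#' Load the LOINC/UCUM code registry
#'
#' The registry maps canonical physiological parameter names (e.g. `"HR"`,
#' `"SaO2"`, `"Vt"`) to their LOINC code, UCUM unit, display name and FHIR
#' value type. A versioned JSON asset covering vital signs, ventilator,
#' blood-gas, hemodynamic, infusion and hematology parameters ships with the
#' package; heart rate (8867-4, `{beats}/min`) and arterial oxygen saturation
#' (2708-6) are the anchor entries, the remainder are drawn from the public
#' LOINC table and marked `provenance = "external-standard"` in the asset.
#'
#' @param path Path to a registry JSON file. Defaults to the shipped asset.
#' @return A tibble with columns `name`, `loinc`, `unit`, `display`, `type`,
#'   `provenance`.
#' @examples
#' reg <- code_registry()
#' lookup_code("HR", reg)
#' @export
code_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_registry.json",
    package = "icufusion", mustWork = TRUE
  )
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reg <- purrr::imap(raw$entries, function(e, nm) {
    tibble::tibble(
      name = nm, loinc = e$loinc, unit = e$unit,
      display = e$display %||% nm, type = e$type %||% "decimal",
      provenance = e$provenance %||% "external-standard"
    )
  }) |> dplyr::bind_rows()
  bad <- reg$loinc[!grepl("^[0-9]{1,7}-[0-9]$", reg$loinc)]
  if (length(bad) > 0) {
    stop_icufusion(
      paste0("registry contains malformed LOINC codes: ", toString(bad)),
      "icufusion_registry_error"
    )
  }
  if (anyDuplicated(reg$loinc) > 0) {
    stop_icufusion(
      "registry maps distinct parameter names to the same LOINC code",
      "icufusion_registry_error"
    )
  }
  reg
}

#' Look up the LOINC code and UCUM unit of a canonical parameter
#'
#' @param name Canonical parameter name, e.g. `"HR"`.
#' @param registry A registry tibble from [code_registry()].
#' @return A list with elements `loinc`, `unit`, `display`, `type`.
#' @examples
#' lookup_code("HR")$loinc # "8867-4"
#' @export
lookup_code <- function(name, registry = code_registry()) {
  stopifnot(is.character(name), length(name) == 1L)
  hit <- registry[registry$name == name, ]
  if (nrow(hit) != 1L) {
    stop_icufusion(
      paste0("unknown parameter name: '", name, "'"),
      "icufusion_unknown_parameter"
    )
  }
  list(
    loinc = hit$loinc, unit = hit$unit,
    display = hit$display, type = hit$type
  )
}

# -- observation components ---------------------------------------------------

loinc_ok <- function(code) grepl("^[0-9]{1,7}-[0-9]$", code)

component_type_of <- function(value) {
  if (is.list(value) && all(c("low", "high") %in% names(value))) {
    return("range")
  }
  if (is.logical(value)) {
    return("boolean")
  }
  if (is.integer(value)) {
    return("integer")
  }
  if (is.numeric(value)) {
    return("decimal")
  }
  if (is.character(value)) {
    return("string")
  }
  stop_icufusion("unsupported component value", "icufusion_validation_error")
}

#' Build one observation component
#'
#' A component is one coded measurement inside an observation record: a LOINC
#' code, a display name, a typed value (decimal, integer, string, boolean, or
#' a `list(low =, high =)` range) and a UCUM unit (required for numeric
#' values).
#'
#' @param code LOINC code string.
#' @param value The measured value.
#' @param display Human-readable name; defaults to `code`.
#' @param unit UCUM unit string; required when `value` is numeric.
#' @return A one-row tibble with columns `code`, `display`, `type`, `value`
#'   (list-column), `unit`.
#' @export
obs_component <- function(code, value, display = code, unit = NA_character_) {
  if (!is.character(code) || length(code) != 1L || !loinc_ok(code)) {
    stop_icufusion(
      paste0("component code must be a LOINC-shaped string, got '", code, "'"),
      "icufusion_validation_error"
    )
  }
  type <- component_type_of(value)
  if (type %in% c("decimal", "integer")) {
    if (!all(is.finite(value))) {
      stop_icufusion("numeric component values must be finite",
        "icufusion_validation_error")
    }
    if (is.na(unit)) {
      stop_icufusion("numeric components require a UCUM unit",
        "icufusion_validation_error")
    }
  }
  if (type == "range") {
    if (!is.finite(value$low) || !is.finite(value$high) ||
      value$low > value$high) {
      stop_icufusion("range component requires finite low <= high",
        "icufusion_validation_error")
    }
  }
  tibble::tibble(
    code = code, display = display, type = type,
    value = list(value), unit = unit
  )
}

# -- ISO 8601 handling --------------------------------------------------------

#' Parse an ISO 8601 timestamp with explicit timezone
#'
#' Accepts `...Z` or a `+HH:MM` / `-HHMM` offset; anything without an explicit
#' timezone designator is rejected, since multi-device fusion needs
#' unambiguous ordering.
#'
#' @param x Character vector of timestamps.
#' @return POSIXct in UTC.
#' @export
parse_iso8601 <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  stopifnot(is.character(x))
  ok <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})$",
    x
  )
  if (!all(ok)) {
    stop_icufusion(
      paste0(
        "timestamp not ISO 8601 with explicit timezone: ",
        toString(x[!ok])
      ),
      "icufusion_validation_error"
    )
  }
  norm <- sub("Z$", "+0000", x)
  norm <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", norm)
  # insert :00 seconds when absent so one strptime format suffices
  norm <- sub(
    "^(\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2})([+-]\\d{4})$", "\\1:00\\2",
    norm
  )
  out <- as.POSIXct(strptime(norm, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  if (anyNA(out)) {
    stop_icufusion("unparseable timestamp", "icufusion_validation_error")
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_iso8601 <- function(t) {
  frac <- as.numeric(t) %% 1
  fmt <- if (any(frac > 1e-9)) "%Y-%m-%dT%H:%M:%OS6Z" else "%Y-%m-%dT%H:%M:%SZ"
  format(t, fmt, tz = "UTC")
}

# -- observation records ------------------------------------------------------

#' Construct a FHIR-style observation record
#'
#' An observation is the lingua franca between package layers: a category
#' code, a subject (patient) identifier, a timezone-aware effective time, a
#' device descriptor, and a non-empty ordered list of coded components with
#' unique codes.
#'
#' @param code Observation category, e.g. `"vital-signs"`.
#' @param subject Patient identifier (non-empty string).
#' @param effective_time POSIXct or ISO 8601 string with explicit timezone.
#' @param device_type,device_location Device descriptor strings.
#' @param components A components tibble, usually `bind_rows()` of
#'   [obs_component()] calls. Insertion order is preserved.
#' @return A one-row observation tibble with a `components` list-column.
#' @examples
#' make_observation(
#'   "vital-signs", "P001", "2024-04-14T21:20:00Z", "monitor", "BED07",
#'   obs_component("8867-4", 88, "Heart rate", "{beats}/min")
#' )
#' @export
make_observation <- function(code, subject, effective_time,
                             device_type, device_location, components) {
  if (!is.character(subject) || length(subject) != 1L || !nzchar(subject)) {
    stop_icufusion("subject must be a non-empty string",
      "icufusion_validation_error")
  }
  if (!tibble::is_tibble(components) || nrow(components) == 0L) {
    stop_icufusion("components must be a non-empty tibble",
      "icufusion_validation_error")
  }
  if (anyDuplicated(components$code) > 0) {
    stop_icufusion("component codes must be unique within one record",
      "icufusion_validation_error")
  }
  t <- parse_iso8601(effective_time)
  out <- tibble::tibble(
    code = code, subject = subject, effective_time = t,
    device_type = device_type, device_location = device_location,
    components = list(components)
  )
  validate_observations(out)
}

#' Validate an observation tibble
#'
#' Checks every record against the observation invariants (non-empty subject,
#' timezone-aware time, non-empty components with unique codes, component
#' invariants). Returns its input invisibly changed (for piping) or raises a
#' validation error.
#'
#' @param obs An observation tibble.
#' @return `obs`, invisibly validated.
#' @export
validate_observations <- function(obs) {
  need <- c(
    "code", "subject", "effective_time", "device_type",
    "device_location", "components"
  )
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0) {
    stop_icufusion(
      paste0("observation tibble lacks columns: ", toString(missing)),
      "icufusion_validation_error"
    )
  }
  if (any(!nzchar(obs$subject) | is.na(obs$subject))) {
    stop_icufusion("subject must be non-empty", "icufusion_validation_error")
  }
  if (!inherits(obs$effective_time, "POSIXct") || anyNA(obs$effective_time)) {
    stop_icufusion("effective_time must be valid POSIXct",
      "icufusion_validation_error")
  }
  purrr::walk(obs$components, function(cmp) {
    if (!tibble::is_tibble(cmp) || nrow(cmp) == 0L) {
      stop_icufusion("components must be non-empty",
        "icufusion_validation_error")
    }
    if (anyDuplicated(cmp$code) > 0) {
      stop_icufusion("component codes must be unique within one record",
        "icufusion_validation_error")
    }
    if (!all(loinc_ok(cmp$code))) {
      stop_icufusion("component codes must be LOINC-shaped",
        "icufusion_validation_error")
    }
    numeric_rows <- cmp$type %in% c("decimal", "integer")
    if (any(numeric_rows & is.na(cmp$unit))) {
      stop_icufusion("numeric components require a unit",
        "icufusion_validation_error")
    }
  })
  obs
}

component_to_list <- function(row) {
  v <- row$value[[1]]
  list(
    code = row$code, display = row$display, type = row$type,
    value = if (row$type == "range") list(low = v$low, high = v$high) else v,
    unit = if (is.na(row$unit)) NULL else row$unit
  )
}

#' Write observations as newline-delimited JSON
#'
#' One JSON object per line with fields `code`, `subject`, `effectiveTime`
#' (ISO 8601 UTC), `device {type, location}` and `components`. The encoding
#' round-trips: `read_obs_ndjson(write_obs_ndjson(x))` reproduces `x`
#' field-for-field.
#'
#' @param obs Observation tibble.
#' @param path File path (or connection) to write to.
#' @return `path`, invisibly.
#' @export
write_obs_ndjson <- function(obs, path) {
  validate_observations(obs)
  lines <- purrr::map_chr(seq_len(nrow(obs)), function(i) {
    cmp <- obs$components[[i]]
    o <- list(
      code = obs$code[i],
      subject = obs$subject[i],
      effectiveTime = format_iso8601(obs$effective_time[i]),
      device = list(
        type = obs$device_type[i],
        location = obs$device_location[i]
      ),
      components = purrr::map(seq_len(nrow(cmp)), function(j) {
        component_to_list(cmp[j, ])
      })
    )
    jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

component_from_list <- function(c) {
  value <- switch(c$type,
    decimal = as.numeric(c$value),
    integer = as.integer(c$value),
    boolean = as.logical(c$value),
    string = as.character(c$value),
    range = list(low = as.numeric(c$value$low), high = as.numeric(c$value$high)),
    stop_icufusion(paste0("unknown component type '", c$type, "'"),
      "icufusion_parse_error")
  )
  tibble::tibble(
    code = c$code, display = c$display, type = c$type,
    value = list(value), unit = c$unit %||% NA_character_
  )
}

#' Read observations from newline-delimited JSON
#'
#' @param path File path (or connection) produced by [write_obs_ndjson()].
#' @return An observation tibble. A malformed line raises a parse error
#'   carrying the line number.
#' @export
read_obs_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      code = character(), subject = character(),
      effective_time = as.POSIXct(character(), tz = "UTC"),
      device_type = character(), device_location = character(),
      components = list()
    ))
  }
  recs <- purrr::imap(lines, function(line, i) {
    o <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) {
        stop_icufusion(
          paste0("malformed NDJSON at line ", i, ": ", conditionMessage(e)),
          "icufusion_parse_error", line = i
        )
      }
    )
    cmp <- dplyr::bind_rows(purrr::map(o$components, component_from_list))
    tibble::tibble(
      code = o$code, subject = o$subject,
      effective_time = parse_iso8601(o$effectiveTime),
      device_type = o$device$type, device_location = o$device$location,
      components = list(cmp)
    )
  })
  validate_observations(dplyr::bind_rows(recs))
}

#' Flatten observation components to a long tibble
#'
#' One row per component, carrying the subject, effective time, device, LOINC
#' code and (via the registry) the canonical parameter name. Non-scalar
#' values (ranges) are dropped with `NA`.
#'
#' @param obs Observation tibble.
#' @param registry Code registry tibble used to recover canonical names.
#' @return A tibble with columns `subject`, `effective_time`, `device_type`,
#'   `code`, `name`, `value`, `unit`, `obs_id`.
#' @export
obs_flatten <- function(obs, registry = code_registry()) {
  validate_observations(obs)
  purrr::map(seq_len(nrow(obs)), function(i) {
    cmp <- obs$components[[i]]
    tibble::tibble(
      obs_id = i,
      subject = obs$subject[i],
      effective_time = obs$effective_time[i],
      device_type = obs$device_type[i],
      code = cmp$code,
      value = purrr::map_dbl(cmp$value, function(v) {
        if (is.numeric(v) && length(v) == 1L) as.numeric(v) else NA_real_
      }),
      unit = cmp$unit
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(
      dplyr::select(registry, name = "name", code = "loinc"),
      by = "code"
    )
}
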