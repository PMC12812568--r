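#' Canonical sleep/HRV parameter names
#'
#' Column order used throughout the package: three sleep-architecture
#' durations followed by four autonomic (HRV) metrics.
#'
#' @return Character vector of the seven canonical column names.
#' @export
sleep_parameters <- function() {
  c("total_sleep_h", "deep_sleep_h", "light_sleep_h",
    "sdnn_ms", "rmssd_ms", "lf_hf", "pnn50_pct")
}

#' Units of the canonical parameters
#' @return Named character vector mapping parameter name to unit.
#' @export
sleep_parameter_units <- function() {
  c(total_sleep_h = "h", deep_sleep_h = "h", light_sleep_h = "h",
    sdnn_ms = "ms", rmssd_ms = "ms", lf_hf = "", pnn50_pct = "%")
}

#' Default physiological constraint set
#'
#' The static knowledge base of physiological plausibility rules used during
#' synthesis: closed box bounds per parameter, the deep-sleep ratio band
#' deep/total in \[0.1, 0.35\], the stage-sum rule deep + light <= total, and
#' strict clinical thresholds (SDNN < 30 ms implies severe autonomic
#' dysfunction; LF/HF > 4 implies sympathetic dominance).
#'
#' Bounds for deep and light sleep are implied by the total-sleep box and the
#' ratio band; all other bounds are standard clinical plausibility ranges.
#' The clinical-endpoint definition used for report scoring additionally
#' treats RMSSD < 20 ms as autonomic dysfunction (see [label_events()]);
#' that threshold is deliberately not part of the synthesis box system.
#'
#' @return An object of class `constraint_set`: a list with elements
#'   `box_bounds` (named list of length-2 numeric vectors), `ratio_bound`,
#'   `sum_rule` (logical), and `clinical_thresholds` (a tibble with columns
#'   parameter, comparator, cutoff, label).
#' @export
#' @examples
#' cs <- default_constraints()
#' cs$box_bounds$total_sleep_h
default_constraints <- function() {
  cs <- list(
    version = "1.0",
    box_bounds = list(
      total_sleep_h = c(3, 12),
      deep_sleep_h  = c(0.3, 4.2),
      light_sleep_h = c(0, 12),
      sdnn_ms       = c(15, 220),
      rmssd_ms      = c(10, 180),
      lf_hf         = c(0.1, 7),
      pnn50_pct     = c(0, 70)
    ),
    ratio_bound = c(0.1, 0.35),
    sum_rule = TRUE,
    clinical_thresholds = tibble::tibble(
      parameter  = c("sdnn_ms", "lf_hf"),
      comparator = c("<", ">"),
      cutoff     = c(30, 4),
      label      = c("severe_autonomic_dysfunction", "sympathetic_dominance")
    )
  )
  structure(cs, class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> version", x$version, "\n")
  for (p in names(x$box_bounds)) {
    cat(sprintf("  %-14s [%g, %g]\n", p, x$box_bounds[[p]][1], x$box_bounds[[p]][2]))
  }
  cat(sprintf("  deep/total ratio [%g, %g]; deep + light <= total: %s\n",
              x$ratio_bound[1], x$ratio_bound[2], x$sum_rule))
  invisible(x)
}

assert_records <- function(records, require_finite = TRUE) {
  if (!is.data.frame(records)) {
    rlang::abort("`records` must be a data frame of sleep records.")
  }
  missing <- setdiff(sleep_parameters(), names(records))
  if (length(missing)) {
    rlang::abort(paste0("missing required columns: ", paste(missing, collapse = ", ")))
  }
  for (p in sleep_parameters()) {
    v <- records[[p]]
    if (!is.numeric(v)) rlang::abort(paste0("column `", p, "` is not numeric"))
    if (require_finite && any(!is.finite(v))) {
      rlang::abort(paste0("column `", p, "` contains non-finite values"))
    }
  }
  invisible(records)
}

#' Check sleep records against a constraint set
#'
#' Evaluates every box, ratio and stage-sum constraint (closed intervals) for
#' each row and returns one row per violation.
#'
#' @param records Data frame with the seven canonical columns.
#' @param cs A `constraint_set`, by default [default_constraints()].
#' @return A tibble with columns `row`, `constraint`, `parameter`, `value`,
#'   `bound_lower`, `bound_upper`, `message`; zero rows when every record
#'   satisfies every constraint.
#' @export
#' @examples
#' ok <- tibble::tibble(total_sleep_h = 8, deep_sleep_h = 2, light_sleep_h = 5,
#'                      sdnn_ms = 50, rmssd_ms = 40, lf_hf = 2, pnn50_pct = 20)
#' nrow(check_records(ok)) # 0
check_records <- function(records, cs = default_constraints()) {
  assert_records(records)
  out <- list()
  for (p in sleep_parameters()) {
    b <- cs$box_bounds[[p]]
    v <- records[[p]]
    bad <- which(v < b[1] | v > b[2])
    if (length(bad)) {
      side <- ifelse(v[bad] < b[1], "below", "above")
      lim <- ifelse(v[bad] < b[1], b[1], b[2])
      out[[length(out) + 1L]] <- tibble::tibble(
        row = bad, constraint = "box", parameter = p, value = v[bad],
        bound_lower = b[1], bound_upper = b[2],
        message = sprintf("%s %s %g", p, side, lim)
      )
    }
  }
  ratio <- records$deep_sleep_h / records$total_sleep_h
  rb <- cs$ratio_bound
  bad <- which(ratio < rb[1] | ratio > rb[2])
  if (length(bad)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      row = bad, constraint = "ratio", parameter = "deep_sleep_h",
      value = ratio[bad], bound_lower = rb[1], bound_upper = rb[2],
      message = sprintf("deep/total ratio %.4f outside [%g, %g]", ratio[bad], rb[1], rb[2])
    )
  }
  if (isTRUE(cs$sum_rule)) {
    s <- records$deep_sleep_h + records$light_sleep_h
    bad <- which(s > records$total_sleep_h)
    if (length(bad)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        row = bad, constraint = "sum", parameter = "deep_sleep_h",
        value = s[bad], bound_lower = NA_real_,
        bound_upper = records$total_sleep_h[bad],
        message = sprintf("deep + light = %.4f exceeds total %.4f",
                          s[bad], records$total_sleep_h[bad])
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(row = integer(), constraint = character(),
                          parameter = character(), value = numeric(),
                          bound_lower = numeric(), bound_upper = numeric(),
                          message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row, .data$constraint, .data$parameter)
}

#' Label clinical events for each record
#'
#' Applies the prespecified clinical endpoints: autonomic dysfunction
#' (SDNN < 30 ms and/or RMSSD < 20 ms) and sympathetic dominance
#' (LF/HF > 4). Comparators are strict, so records exactly at a cutoff are
#' negative. The single-parameter rule "SDNN < 30 ms implies severe autonomic
#' dysfunction" used inside the constraint knowledge base is also reported
#' (`severe_autonomic_dysfunction`); the composite endpoint definition is the
#' one used for sensitivity/specificity scoring.
#'
#' @param records Data frame with the canonical columns.
#' @return The input with logical columns `autonomic_dysfunction`,
#'   `sympathetic_dominance` and `severe_autonomic_dysfunction` appended.
#' @export
#' @examples
#' label_events(tibble::tibble(total_sleep_h = 8, deep_sleep_h = 2,
#'   light_sleep_h = 5, sdnn_ms = 25, rmssd_ms = 40, lf_hf = 2, pnn50_pct = 20))
label_events <- function(records) {
  assert_records(records)
  dplyr::mutate(
    tibble::as_tibble(records),
    autonomic_dysfunction = .data$sdnn_ms < 30 | .data$rmssd_ms < 20,
    sympathetic_dominance = .data$lf_hf > 4,
    severe_autonomic_dysfunction = .data$sdnn_ms < 30
  )
}

#' Serialize / deserialize a constraint set as JSON
#'
#' @param cs A `constraint_set`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `constraints_to_json()` returns the JSON string (invisibly when
#'   written to a file); `constraints_from_json()` returns a `constraint_set`.
#' @export
constraints_to_json <- function(cs, path = NULL) {
  x <- unclass(cs)
  x$clinical_thresholds <- as.data.frame(x$clinical_thresholds)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname constraints_to_json
#' @param json JSON string or file path produced by [constraints_to_json()].
#' @export
constraints_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$box_bounds <- lapply(x$box_bounds, as.numeric)
  x$ratio_bound <- as.numeric(x$ratio_bound)
  x$clinical_thresholds <- tibble::as_tibble(x$clinical_thresholds)
  structure(x, class = "constraint_set")
}
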