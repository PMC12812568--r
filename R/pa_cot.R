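read_template <- function(name) {
  path <- system.file("templates", paste0(name, ".txt"), package = "sleepsynth")
  if (path == "") rlang::abort(paste0("template not found: ", name))
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Cluster preamble texts per archetype
#' @return Named character vector (archetype -> preamble text).
#' @export
archetype_preambles <- function() {
  rlang::set_names(
    vapply(archetypes(), function(a) read_template(paste0("preamble_", a)),
           character(1)),
    archetypes()
  )
}

# phrases emitted by render_report and recognized by parse_report; the
# lexicon and the templates are authored together so the round trip is exact
event_lexicon <- function() {
  list(
    autonomic_dysfunction = list(
      positive = "findings indicate autonomic dysfunction",
      negative = "no evidence of autonomic dysfunction",
      pattern = "autonomic dysfunction"
    ),
    sympathetic_dominance = list(
      positive = "findings indicate sympathetic dominance",
      negative = "no evidence of sympathetic dominance",
      pattern = "sympathetic dominance"
    )
  )
}

#' Classify a question for chain-of-thought routing
#'
#' Deterministic keyword rules: a question is *personalized* when it uses
#' first-person possessives about the user's own data ("my SDNN"),
#' otherwise it is a knowledge question. The S-type picks the inference
#' path: S1 = interpretation of own parameter values, S2 = recommendation
#' request, S3 = general mechanism question. When no rule fires the default
#' path (S1 for personalized, S3 otherwise) is returned with a
#' low-confidence flag.
#'
#' @param text Question text (nonempty).
#' @return List with `s_type` (1, 2 or 3), `personalized` (logical),
#'   `low_confidence` (logical).
#' @export
classify_question <- function(text) {
  if (!nzchar(trimws(text))) rlang::abort("`text` must be nonempty")
  lt <- tolower(text)
  personalized <- grepl("\\bmy\\b|\\bmine\\b|\\bam i\\b|\\bdo i\\b", lt)
  param <- grepl("sdnn|rmssd|pnn50|lf/hf|lf-hf|hrv|heart rate variability|sleep duration|deep sleep|light sleep|total sleep", lt)
  interp <- grepl("indicate|mean[s]?\\b|interpret|implication|say about|tell (me|us) about|normal", lt)
  recommend <- grepl("should|recommend|advice|advise|suggest|improve|how can i|what can i do|tips|help me", lt)
  mechanism <- grepl("how does|why does|what is|affect|influence|impact|relationship|role of|explain", lt)
  s_type <- NA_integer_
  if (recommend) s_type <- 2L
  else if (param && interp) s_type <- 1L
  else if (mechanism) s_type <- 3L
  low_confidence <- is.na(s_type)
  if (is.na(s_type)) s_type <- if (personalized) 1L else 3L
  list(s_type = s_type, personalized = personalized,
       low_confidence = low_confidence)
}

#' Assemble the personalized inference chain
#'
#' Report generation uses the fixed generation template alone. For
#' personalized and knowledge Q&A the chain is the cluster preamble of the
#' user's profile followed by exactly one S-template selected by
#' [classify_question()] (concatenation order: preamble, then template).
#' Assembly is total and deterministic.
#'
#' @param profile One-row data frame of profile columns (required for QA
#'   tasks; ignored for reports).
#' @param model A `cluster_model` (required for QA tasks).
#' @param task `"report"`, `"personalized_qa"` or `"knowledge_qa"`.
#' @param question Question text (required for QA tasks).
#' @return A `chain_spec`: list with `task`, `s_type`, `cluster`,
#'   `archetype`, `chain`, `templates`, `low_confidence`.
#' @export
build_chain <- function(profile = NULL, model = NULL,
                        task = c("report", "personalized_qa", "knowledge_qa"),
                        question = NULL) {
  task <- match.arg(task)
  if (task == "report") {
    return(structure(list(task = task, s_type = NA_integer_,
                          cluster = NA_integer_, archetype = NA_character_,
                          chain = read_template("cot_g"),
                          templates = "cot_g", low_confidence = FALSE),
                     class = "chain_spec"))
  }
  if (is.null(question)) rlang::abort("QA tasks require `question`")
  if (is.null(profile) || is.null(model)) {
    rlang::abort("QA tasks require `profile` and a fitted cluster `model`")
  }
  cls <- classify_question(question)
  asg <- assign_cluster(profile, model)[1, ]
  tmpl <- paste0("cot_s", cls$s_type)
  chain <- paste0(asg$preamble, "\n\n", "[Question type S", cls$s_type, "]\n",
                  read_template(tmpl))
  structure(list(task = task, s_type = cls$s_type,
                 cluster = asg$cluster, archetype = asg$archetype,
                 chain = chain,
                 templates = c(paste0("preamble_", asg$archetype), tmpl),
                 low_confidence = cls$low_confidence),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> task = %s, S-type = %s, archetype = %s\n",
              x$task, format(x$s_type), format(x$archetype)))
  cat(x$chain, "\n")
  invisible(x)
}

fmt_param_line <- function(name, value) {
  units <- sleep_parameter_units()
  labels <- c(total_sleep_h = "Total sleep duration",
              deep_sleep_h = "Deep sleep duration",
              light_sleep_h = "Light sleep duration",
              sdnn_ms = "SDNN", rmssd_ms = "RMSSD",
              lf_hf = "LF/HF ratio", pnn50_pct = "PNN50")
  u <- units[[name]]
  sprintf("- %s: %.2f%s", labels[[name]], value,
          if (nzchar(u)) paste0(" ", u) else "")
}

#' Render a structured sleep report for one record
#'
#' Produces the three-section report layout: the seven parameters with
#' units, a sleep-state description that names each triggered clinical
#' event (or its explicit absence) using the shared lexicon, and
#' personalized suggestions keyed to the archetype and events. The lexicon
#' used here is the one [parse_report()] recognizes, so rendering followed
#' by parsing reproduces [label_events()] exactly.
#'
#' @param record One-row data frame with the canonical columns.
#' @param events Optional one-row event labels (computed from the record
#'   when omitted).
#' @param archetype Archetype label steering the suggestion text.
#' @return A `report_document`: list with `parameters`, `state`,
#'   `suggestions` sections and `text` (the assembled document).
#' @export
render_report <- function(record, events = NULL, archetype = "moderate") {
  assert_records(record)
  record <- tibble::as_tibble(record)[1, ]
  if (is.null(events)) events <- label_events(record)
  lex <- event_lexicon()
  params <- vapply(sleep_parameters(), function(p) fmt_param_line(p, record[[p]]),
                   character(1))
  state <- c()
  for (e in names(lex)) {
    state <- c(state, if (isTRUE(events[[e]][1])) {
      paste0(toupper(substring(lex[[e]]$positive, 1, 1)),
             substring(lex[[e]]$positive, 2), ".")
    } else {
      paste0(toupper(substring(lex[[e]]$negative, 1, 1)),
             substring(lex[[e]]$negative, 2), ".")
    })
  }
  if (!events$autonomic_dysfunction[1] && !events$sympathetic_dominance[1]) {
    state <- c(state, "Overall, the autonomic profile is within the expected range.")
  }
  sugg <- c(sub("^\\[[^]]*\\]\\n", "", archetype_preambles()[[archetype]]))
  if (isTRUE(events$autonomic_dysfunction[1])) {
    sugg <- c(sugg, "Consider discussing the reduced heart-rate variability with a clinician and prioritizing recovery, sleep regularity and stress reduction.")
  }
  if (isTRUE(events$sympathetic_dominance[1])) {
    sugg <- c(sugg, "An elevated LF/HF balance suggests sympathetic predominance; relaxation practice and reduced evening stimulation may help.")
  }
  text <- paste(
    "== Sleep parameters ==", paste(params, collapse = "\n"),
    "", "== Sleep state ==", paste(state, collapse = "\n"),
    "", "== Personalized suggestions ==", paste(sugg, collapse = "\n"),
    sep = "\n")
  structure(list(parameters = params, state = state, suggestions = sugg,
                 archetype = archetype, text = text),
            class = "report_document")
}

#' @export
print.report_document <- function(x, ...) { cat(x$text, "\n"); invisible(x) }

#' Parse clinical-event predictions from report text
#'
#' Extracts binary endpoint predictions from a sleep report using the
#' shipped lexicon and regular expressions, negation-aware for the
#' package's own template phrasings ("no evidence of ...", "no signs of
#' ...", "without ..."). Text with no lexicon match yields a negative
#' prediction. Third-party report text is parsed best-effort.
#'
#' @param text Report text (a `report_document` is also accepted).
#' @return Tibble with logical columns `autonomic_dysfunction`,
#'   `sympathetic_dominance`.
#' @export
parse_report <- function(text) {
  if (inherits(text, "report_document")) text <- text$text
  lt <- tolower(paste(text, collapse = "\n"))
  lex <- event_lexicon()
  out <- purrr::map_lgl(lex, function(l) {
    hits <- gregexpr(l$pattern, lt, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(FALSE)
    any(vapply(hits, function(pos) {
      ctx <- substring(lt, max(1, pos - 40), pos - 1)
      !grepl("\\bno evidence of\\s*$|\\bno signs? of\\s*$|\\bwithout\\s*$|\\babsence of\\s*$|\\bnot?\\s+\\w*\\s*$",
             ctx)
    }, logical(1)))
  })
  tibble::tibble(autonomic_dysfunction = out[["autonomic_dysfunction"]],
                 sympathetic_dominance = out[["sympathetic_dominance"]])
}

#' Write chain specs or reports as JSONL
#'
#' One JSON document per line with metadata, the interchange format for
#' assembled chains and rendered reports.
#'
#' @param docs List of `chain_spec` or `report_document` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(unclass(d), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
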