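test_that("question classification separates personalized from knowledge asks", {
  q1 <- classify_question("What does my SDNN value indicate about my cardiac health?")
  expect_true(q1$personalized)
  expect_identical(q1$s_type, 1L)
  expect_false(q1$low_confidence)

  q2 <- classify_question("How does deep sleep duration affect stress resilience?")
  expect_false(q2$personalized)
  expect_identical(q2$s_type, 3L)

  q3 <- classify_question("What should I do to improve my deep sleep?")
  expect_true(q3$personalized)
  expect_identical(q3$s_type, 2L)

  q4 <- classify_question("zzzz qqqq")
  expect_true(q4$low_confidence)
  expect_error(classify_question("  "), "nonempty")
})

test_that("chains are assembled as preamble-then-template, reports verbatim", {
  bp <- blob_profiles()
  m <- cluster_profiles(bp$profiles, seed = 7)

  rep_chain <- build_chain(task = "report")
  expect_identical(rep_chain$chain, sleepsynth:::read_template("cot_g"))
  expect_identical(rep_chain$templates, "cot_g")

  pr <- bp$profiles[1, ]
  qa <- build_chain(pr, m, task = "personalized_qa",
                    question = "What does my RMSSD mean?")
  asg <- assign_cluster(pr, m)
  expect_true(startsWith(qa$chain, asg$preamble))
  expect_true(endsWith(qa$chain, sleepsynth:::read_template(paste0("cot_s", qa$s_type))))
  expect_identical(qa$archetype, asg$archetype)

  expect_error(build_chain(pr, m, task = "personalized_qa"), "question")
  expect_error(build_chain(task = "knowledge_qa", question = "Why?"), "profile")
})

test_that("chain assembly is total and deterministic over every combination", {
  bp <- blob_profiles()
  m <- cluster_profiles(bp$profiles, seed = 7)
  # one representative profile per archetype
  asg <- assign_cluster(bp$profiles, m)
  qs <- c("What does my SDNN value indicate about my cardiac health?",
          "What should I do to improve my sleep?",
          "How does deep sleep affect memory?")
  for (arch in archetypes()) {
    pr <- bp$profiles[which(asg$archetype == arch)[1], ]
    for (task in c("personalized_qa", "knowledge_qa")) {
      for (q in qs) {
        c1 <- build_chain(pr, m, task = task, question = q)
        c2 <- build_chain(pr, m, task = task, question = q)
        expect_identical(c1$chain, c2$chain)
        expect_identical(c1$archetype, arch)
        expect_match(c1$chain, "Step 1", fixed = TRUE)
      }
    }
  }
})

test_that("reports contain the three sections and every parameter once", {
  r <- valid_record()
  doc <- render_report(r)
  expect_match(doc$text, "== Sleep parameters ==", fixed = TRUE)
  expect_match(doc$text, "== Sleep state ==", fixed = TRUE)
  expect_match(doc$text, "== Personalized suggestions ==", fixed = TRUE)
  labels <- c("Total sleep duration", "Deep sleep duration", "Light sleep duration",
              "SDNN", "RMSSD", "LF/HF ratio", "PNN50")
  for (lab in labels) {
    expect_identical(
      lengths(regmatches(doc$text, gregexpr(paste0("- ", lab, ":"), doc$text, fixed = TRUE))),
      1L)
  }
  expect_match(doc$text, "50.00 ms", fixed = TRUE)
})

test_that("event phrases are emitted iff the endpoint triggers", {
  pos <- render_report(valid_record(sdnn = 25))
  expect_match(pos$text, "indicate autonomic dysfunction")
  neg <- render_report(valid_record())
  expect_match(neg$text, "No evidence of autonomic dysfunction", fixed = TRUE)
  expect_match(neg$text, "within the expected range", fixed = TRUE)
  symp <- render_report(valid_record(lf_hf = 5))
  expect_match(symp$text, "indicate sympathetic dominance")
})

test_that("parsing inverts rendering and handles bare text", {
  expect_identical(parse_report("")$autonomic_dysfunction, FALSE)
  expect_identical(parse_report("")$sympathetic_dominance, FALSE)
  p <- parse_report("the patient shows clear sympathetic dominance today")
  expect_true(p$sympathetic_dominance)
  expect_false(p$autonomic_dysfunction)
  p <- parse_report("there is no evidence of sympathetic dominance")
  expect_false(p$sympathetic_dominance)
})

test_that("render/parse round trip reproduces the event labels exactly", {
  set.seed(99)
  # stress the thresholds: HRV values concentrated around the cutoffs
  recs <- fixture_cohort()[1:300, ]
  recs$sdnn_ms <- runif(300, 16, 60)
  recs$rmssd_ms <- runif(300, 10, 40)
  recs$lf_hf <- runif(300, 2, 7)
  truth <- label_events(recs)
  agree <- sapply(seq_len(nrow(recs)), function(i) {
    parsed <- parse_report(render_report(recs[i, ]))
    parsed$autonomic_dysfunction == truth$autonomic_dysfunction[i] &&
      parsed$sympathetic_dominance == truth$sympathetic_dominance[i]
  })
  expect_identical(mean(agree), 1)
})

test_that("documents serialize as JSONL", {
  docs <- list(render_report(valid_record()), build_chain(task = "report"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(docs, path)
  lines <- readLines(path)
  expect_identical(length(lines), 2L)
  expect_silent(jsonlite::fromJSON(lines[1]))
})
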