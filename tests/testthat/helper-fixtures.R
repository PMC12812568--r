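# shared fixtures, built once per test run

valid_record <- function(total = 8, deep = 2, light = 5, sdnn = 50,
                         rmssd = 40, lf_hf = 2, pnn50 = 20) {
  tibble::tibble(total_sleep_h = total, deep_sleep_h = deep,
                 light_sleep_h = light, sdnn_ms = sdnn, rmssd_ms = rmssd,
                 lf_hf = lf_hf, pnn50_pct = pnn50)
}

# random records inside all box bounds (not necessarily ratio/sum valid)
random_inbox_records <- function(n, seed = 1) {
  set.seed(seed)
  cs <- default_constraints()
  tibble::as_tibble(purrr::map(cs$box_bounds, function(b) {
    stats::runif(n, b[1] + 1e-3 * diff(b), b[2] - 1e-3 * diff(b))
  }))
}

fixture_cohort <- local({
  cache <- NULL
  function(n = 1000, seed = 42) {
    if (is.null(cache)) cache <<- generate_fixture(fixture_spec(n = n), seed = seed)
    cache
  }
})

blob_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixture(
        fixture_spec(n = 600, archetype_mixture = c(1, 1, 1) / 3),
        seed = 11)
      cache <<- list(profiles = make_profile(fx),
                     archetype = attr(fx, "manifest")$archetype)
    }
    cache
  }
})
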