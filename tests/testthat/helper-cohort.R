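# The validation cohort used by the end-to-end tests: 20 one-minute
# recordings at resting heart rates (60-90 bpm) with 20 dB white noise,
# fixed master seed.  Generated and evaluated once per test run and cached.

acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(20, hr_range = c(60, 90), duration = 60,
                         master_seed = 101)
      evals <- lapply(coh, function(e) evaluate_record(e$recording))
      cache <<- list(cohort = coh, evals = evals,
                     metrics = do.call(rbind, lapply(evals, `[[`, "metrics")))
    }
    cache
  }
})
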