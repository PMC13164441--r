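# The full-scale synthetic cohort (27 cortical / 18 BG subjects, 1e5 px/ROI,
# fixed master seed) is expensive to generate, and several recovery tests
# interrogate the same cohort — build it once per test run.
get_acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_cohort(cohort_config(seed = 1))
    cache
  }
})
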