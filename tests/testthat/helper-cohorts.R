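# Shared cohort-scale fixture for the acceptance-style checks: three
# replicate cohorts with the default injected effects and two with no
# effects at all. Built once per test run and reused by the hierarchical
# recovery and covariate-comparison blocks. Each cohort is a full run of
# the pipeline: generation, per-subject variational inversion of both
# sessions' deviant responses, group PEBs, PEB-of-PEBs and the GABA model
# comparison.

run_cohort_analysis <- function(spec, model) {
  coh <- generate_cohort(spec, model)
  fits <- fit_cohort(coh, model)
  ga <- analyse_groups(fits, coh$subjects)
  gb <- analyse_gaba(fits, coh$subjects)
  list(subjects = coh$subjects, fits = fits, effects = ga$effects,
       comparison = gb$comparison)
}

acceptance_fixture <- local({
  cache <- NULL
  function(n_power = 5, n_null = 2, seed0 = 500) {
    if (!is.null(cache)) return(cache)
    model <- compile_cmm(network_spec())
    power <- lapply(seq_len(n_power), function(k)
      run_cohort_analysis(cohort_spec(seed = seed0 + k), model))
    null <- lapply(seq_len(n_null), function(k)
      run_cohort_analysis(cohort_spec(effects = default_effects()[0, ],
                                      seed = seed0 + 100 + k), model))
    cache <<- list(model = model, power = power, null = null)
    cache
  }
})

# pull one posterior probability out of a group-analysis effect table
pp_of <- function(effects, family, effect, parameter) {
  effects$pp[effects$family == family & effects$effect == effect &
               effects$parameter == parameter]
}
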