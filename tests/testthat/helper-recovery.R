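# The lambda-recovery experiment (10 seeds of 73-tip MCMC) is used by two
# acceptance checks; run it once per session and cache the result.
recovery_cache <- new.env(parent = emptyenv())

get_recovery_runs <- function() {
  if (is.null(recovery_cache$runs)) {
    recovery_cache$runs <- lambda_recovery_experiment(
      n_seeds = 10, seed = 424L, config = mcmc_config("desk"))
  }
  recovery_cache$runs
}
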