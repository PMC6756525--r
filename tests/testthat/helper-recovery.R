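# The study-scale recovery experiment is expensive (26 rafts, full MCMC),
# so it is run once and shared across the acceptance checks.
.acc <- new.env(parent = emptyenv())

acceptance_recovery <- function() {
  if (is.null(.acc$rep))
    .acc$rep <- run_recovery_experiment(
      recovery_config(), seed = 1,
      variants = c("full", "noangle", "null"), heatmaps = FALSE)
  .acc$rep
}
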