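# Shared training fixtures for the heavier closed-loop tests: a small
# synthetic cohort and one detector-in-loop trained policy per patient,
# built once per test run and reused.

.acc <- new.env(parent = emptyenv())

acceptance_cohort <- function(n = 3) {
  if (is.null(.acc$coh)) .acc$coh <- make_cohort(n, seed = 11)
  .acc$coh
}

acceptance_policy <- function(i) {
  key <- paste0("pol", i)
  if (is.null(.acc[[key]])) {
    coh <- acceptance_cohort()
    .acc[[key]] <- drl_train(
      coh[[i]],
      train_config(memory_days = 100L, iterations = 300L,
                   updates_per_event = 6L),
      seed = i, announced = FALSE)
  }
  .acc[[key]]
}
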