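# Shared synthetic study and discovery run, built once per test session.
# The default configuration is the emulated study design; the classifier
# runs at 150 epochs without cross-validation for the planted-signal
# checks (the logloss plateau on the synthetic module is reached well
# before that).

.cache <- new.env(parent = emptyenv())

the_study <- function() {
  if (is.null(.cache$study)) {
    .cache$study <- simulate_study(simulation_config(seed = 1))
  }
  .cache$study
}

fast_clf_config <- function(seed = 666, ...) {
  classifier_config(epochs = 150, cv_folds = 0, seed = seed, ...)
}

the_discovery <- function() {
  if (is.null(.cache$discovery)) {
    .cache$discovery <- suppressWarnings(
      run_discovery(the_study(), clf_config = fast_clf_config()))
  }
  .cache$discovery
}

# Small atlas for cheap unit tests.
small_atlas <- function(tpm, tissues = NULL, replicates = NULL) {
  if (is.null(tissues)) tissues <- rep("T1", ncol(tpm))
  if (is.null(replicates)) replicates <- seq_len(ncol(tpm))
  expression_atlas(tpm, data.frame(sample_id = colnames(tpm),
                                   tissue = tissues, replicate = replicates,
                                   stringsAsFactors = FALSE))
}
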