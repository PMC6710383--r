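# Shared fixtures: everything is generated in code at test time.

# Small deterministic ensemble with hand-set state, for exact update tests.
manual_ensemble <- function(phases, freqs, t = 0L, last_reset = 0,
                            params = model_params(n_oscillators = length(phases),
                                                  noise_std = 0),
                            targets = unimodal_targets()) {
  e <- init_ensemble(params, targets = targets, seed = 1)
  e$phases[] <- phases
  e$freqs[] <- freqs
  e$last_reset[] <- rep_len(last_reset, length(phases))
  e$t <- as.integer(t)
  e
}

# Modal frequency bin of a finished run (pooled over given channels).
modal_freq <- function(run, channels = NULL) {
  dominant_frequency(phase_freq_histogram(run, channels = channels))
}

# Majority vote with ties going to the smallest value.
majority <- function(x) {
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}
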