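# Shared fixtures for the test suite.

# 4 biological replicates per stage, the hybridization layout.
hyb_assignment <- function(n_rep = 4) {
  stats::setNames(rep(c("growing", "plateau", "atretic"), each = n_rep),
                  paste0(rep(c("G", "P", "A"), each = n_rep), seq_len(n_rep)))
}

# Normalized phase profile from four raw values.
norm_profile <- function(sub, g1, s, g2)
  normalize_proportions(phase_profile(sub, g1, s, g2))

# A fully normalized loop array set ready for model fitting.
normalized_loop_set <- function(..., seed = 1) {
  set <- simulate_loop_arrays(hyb_assignment(), ..., seed = seed)
  normalize_between_quantile(normalize_within_loess(background_correct(set)))
}

# Named effect vector over the first n probes of the default probe space.
effect_vec <- function(n, effect, offset = 0)
  stats::setNames(rep(effect, n), sprintf("P%05d", offset + seq_len(n)))

# n samples per stage, the qPCR validation layout (default 7/7/7).
stage7 <- function(n = 7) {
  stats::setNames(rep(c("growing", "plateau", "atretic"), each = n),
                  paste0(rep(c("G", "P", "A"), each = n), seq_len(n)))
}
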