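# Small deterministic fixtures shared across test files.

# A clean recording made of the template train plus known noise level.
make_recording <- function(seed = 1, frequency = 100, duration_s = 1,
                           noise_rms = 12, ...) {
  generate_recording(seed = seed, frequency = frequency,
                     duration_s = duration_s, noise_rms = noise_rms, ...)
}

# Spearman rho from first principles (average ranks, no library call).
rank_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
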