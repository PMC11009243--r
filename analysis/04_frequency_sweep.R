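#!/usr/bin/env Rscript
# Frequency sweep of the in-silico ERNA dynamics (10-100 Hz).
#
# Complements the scenario battery: the P2 growth ratio across the full
# stimulation-frequency range, 10 iterations per frequency. Outputs:
# results/frequency_sweep/lfs_dynamics.csv.

library(ernasim)

rep <- run_experiment("frequency_sweep", seed = 0, n_iterations = 10,
                      out_dir = "results")
print(rep$tables$lfs, digits = 3)
cat("tables written under", rep$out_dir, "\n")
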