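#!/usr/bin/env Rscript
# Stage 5 — Monte Carlo power of the design.
#
# Repeatedly simulates the full design and refits with the fast
# per-participant-OLS refitter, counting significant linear time effects at
# alpha = 0.05. 200 simulations per valence keep the stage to a few minutes;
# the binomial CI reflects that simulation count.

suppressPackageStartupMessages(library(ptdisc))

cfg <- cohort_config(seed = 20260923L)
for (v in c("positive", "negative")) {
  pw <- power_simulation(cfg, n_sims = 200, valence = v, seed = 41)
  print(pw)
  write.table(
    data.frame(valence = v, power = pw$power, ci_low = pw$ci[1],
               ci_high = pw$ci[2], n_sims = pw$n_sims, alpha = pw$alpha,
               n_participants = pw$n_participants, refitter = pw$refitter),
    sprintf("results/power_%s.tsv", v), sep = "\t",
    row.names = FALSE, quote = FALSE)
}
cat("power tables written to results/power_*.tsv\n")
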