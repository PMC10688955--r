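#!/usr/bin/env Rscript
# Stage 1 - design of experiment.
# Builds the 2^(7-2) resolution-IV fraction of the seven crossing-situation
# factors, verifies its balance through third-order interactions, and writes
# the design plus per-participant randomised trial plans (32 factorial
# trials + 4 collision trials at ranks 7/14/21/28).

library(riskbn)
seed <- 1L
n_participants <- 27L
dir.create("results", showWarnings = FALSE)

design <- build_fractional_design()
cat(sprintf("Fractional design: %d runs of %d factors, resolution %s\n",
            nrow(design), ncol(design), attr(design, "resolution")))

bal <- check_balance(design, order = 3)
cat(sprintf("Unbalanced interaction columns up to order 3: %d (of %d)\n",
            nrow(bal), sum(choose(7, 1:3))))
stopifnot(nrow(bal) == 0)

write.csv(design_to_labels(as.data.frame(design)), "results/design_32.csv",
          row.names = FALSE)

plans <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
  make_trial_plan(design, sprintf("P%02d", p), riskbn:::derive_seed(seed, p, 1L))
}))
write_trial_plan_csv(plans, "results/trial_plans.csv")
cat(sprintf("Wrote %d trial plans (%d trials each, %d collision trials per plan)\n",
            n_participants, 36, 4))
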