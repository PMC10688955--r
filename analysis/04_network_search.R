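#!/usr/bin/env Rscript
# Stage 4 - exhaustive Bayesian-network comparison.
# Scores all 12,288 candidate hybrid networks for each indicator pair on the
# transformed indicator table from stage 2 and writes the rankings. The
# planted structure is Margin/Order -> subjective indicator -> SCR indicator
# (with Orientation also parenting mSA in the maxima pair).

library(riskbn)

md <- read_indicator_csv("results/indicators_transformed.csv")
md <- md[!md$is_collision, ]
cat(sprintf("Scoring %d structures per pair on n = %d records\n",
            count_structures(7, 3), nrow(md)))

best <- list()
for (pair in c("dynamics", "maxima")) {
  t0 <- proc.time()[3]
  s <- search_networks(md, pair)
  cat(sprintf("\n== %s pair (%.1f s) ==\n", pair, proc.time()[3] - t0))
  print(s, top = 5)
  write.csv(head(s$ranking, 20), sprintf("results/ranking_%s.csv", pair),
            row.names = FALSE)
  best[[pair]] <- s$best
}
jsonlite::write_json(best, "results/best_networks.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nWrote results/ranking_{dynamics,maxima}.csv and results/best_networks.json\n")
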