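#!/usr/bin/env Rscript
# Stage 5 - cluster analysis of condition-cell means.
# For each pair's best network from stage 4, enumerates every set partition
# of the subjective node's condition cells and ranks them by BIC, grouping
# experimental conditions that produced an equivalent level of perceived
# risk.

library(riskbn)

md <- read_indicator_csv("results/indicators_transformed.csv")
md <- md[!md$is_collision, ]
best <- jsonlite::fromJSON("results/best_networks.json")

for (pair in names(best)) {
  s <- structure(list(best = as.list(best[[pair]]), pair = pair),
                 class = "network_search")
  cl <- cluster_best_network(s, md)
  cat(sprintf("\n== %s pair: clustering cells of {%s} ==\n",
              pair, best[[pair]]$sa_parents))
  if (is.null(cl)) { cat("best network has no subjective parents\n"); next }
  print(cl)
  top <- head(cl$ranking, 3)
  cat("Runner-up partitions:\n")
  print(top, digits = 5)
  write.csv(head(cl$ranking, 20), sprintf("results/clusters_%s.csv", pair),
            row.names = FALSE)
}
cat("\nWrote results/clusters_{dynamics,maxima}.csv\n")
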