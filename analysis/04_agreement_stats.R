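#!/usr/bin/env Rscript
# Step 4: agreement tables from the study scores.
#
# Rebuilds the distribution table (mean / min / quartiles / max of counted
# cells and PIs per scoring method) and the pairwise agreement statistics
# (Spearman r, Bland-Altman mean difference, SD, limits of agreement, cases
# beyond 1.96 SD, paired t) from results/study/scores.csv.

library(ki67hotspot)

scores <- read.csv("results/study/scores.csv", stringsAsFactors = FALSE)
out_dir <- "results"

tab <- do.call(rbind, lapply(split(scores, scores$arm), function(s) {
  pi_sum <- summarize_distribution(s$pi_percent)
  cnt <- if (all(is.na(s$n_cells))) rep(NA_real_, 6)
         else summarize_distribution(s$n_cells)
  data.frame(arm = s$arm[1],
             metric = c("cells_counted", "ki67_pi_percent"),
             rbind(round(cnt, 1), round(pi_sum, 1)))
}))
write.csv(tab, file.path(out_dir, "summary_table.csv"), row.names = FALSE)
cat("Per-method distribution summary (Table-style):\n")
print(tab, row.names = FALSE)

wide <- function(arm) {
  s <- scores[scores$arm == arm, ]
  stats::setNames(s$pi_percent, s$case_id)
}
cons <- wide("consensus"); rule <- wide("rule"); vds <- wide("vds")
o1 <- wide("observer1"); o2 <- wide("observer2")

pairs <- list(
  observers = paired_scores(names(o1), o1, o2, "observer 1", "observer 2"),
  rule_vs_consensus = paired_scores(names(cons), rule[names(cons)], cons,
                                    "rule-arm DIA", "manual consensus"),
  vds_vs_consensus = paired_scores(names(vds), vds, cons[names(vds)],
                                   "VDS-arm DIA", "manual consensus"))
agr <- lapply(pairs, bland_altman)
for (g in agr) { print(g); cat("\n") }

strip <- function(g) g[setdiff(names(g), c("means", "differences"))]
jsonlite::write_json(lapply(agr, function(g) strip(unclass(g))),
                     file.path(out_dir, "agreement.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/summary_table.csv and results/agreement.json\n")
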