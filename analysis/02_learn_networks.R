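#!/usr/bin/env Rscript
# Learn one Gaussian Bayesian network per group per cohort by BIC-scored
# greedy hill-climbing, serialize the fitted models, and report how well the
# learned structures match the generating templates.

suppressPackageStartupMessages(library(gbnet))

for (net in c("auditory", "visual", "motor")) {
  tbl <- read_roi_table(file.path("results", paste0("cohort_", net, ".csv")))
  spec <- builtin_spec(net)   # for the ground-truth comparison only
  cat("====", net, "network\n")
  for (grp in c("A", "B")) {
    res <- greedy_search(roi_group(tbl, grp))
    out <- file.path("results", sprintf("model_%s_%s.json", net, grp))
    write_gbn(res$bn, out)
    tru <- if (grp == "A") spec$bn_a else spec$bn_b
    same_skel <- identical(skeleton(cpdag(res$bn$dag)), skeleton(tru$dag))
    cat(sprintf("  group %s: %d edges learned in %d moves, BIC %.1f, skeleton %s -> %s\n",
                grp, nrow(res$bn$dag$edges), nrow(res$trace$steps),
                res$trace$final_score,
                if (same_skel) "matches the template" else "differs from the template",
                out))
    for (k in seq_len(nrow(res$bn$dag$edges))) {
      pa <- res$bn$dag$edges[k, 1]; ch <- res$bn$dag$edges[k, 2]
      cat(sprintf("      %s -> %-6s  weight %+.3f\n", pa, ch,
                  res$bn$params[[ch]]$coefficients[[pa]]))
    }
  }
}
cat("\nAt n = 109/82 the learned graphs typically agree with the template up\n")
cat("to Markov equivalence; orientation of reversible edges is a deterministic\n")
cat("tie-break, not an inference.\n")
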