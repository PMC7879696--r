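#!/usr/bin/env Rscript
# Step 4 — demonstrate competing-event masking and its repair.
#
# Scales the exposed arm's competing-AE probabilities five-fold, runs the
# main analysis with and without the competing-AE exclusion on paired
# replicates, and shows that the exclusion moves the PRR back toward the
# generator's true reporting ratio — the dilution argument the
# competing-event sensitivity analysis exists to address.

suppressPackageStartupMessages(library(faersdispro))

dir.create("results", showWarnings = FALSE)

n_rep <- 40
true_ratio <- 0.55
comp_filter <- filter_spec("exclude_competing", "exclude_report",
                           "reaction_in_set", "competing_ae")
rows <- lapply(seq_len(n_rep), function(i) {
  cfg <- masking_scenario(
    generator_config(n_exposed = 20000, n_comparator = 20000,
                     n_ibrutinib = 0, seed = 1000 + i), 5)
  g <- generate(cfg)
  s <- suppressMessages(dedup_latest(g$store))
  co <- build_cohort(s, cohort_spec("sglt2i", "atc_a10_other"))
  prr_raw <- compute_prr(count_events(s, co, "af"))$prr
  co_f <- apply_filters(s, co, list(comp_filter))
  prr_filt <- compute_prr(count_events(s, co_f, "af"))$prr
  data.frame(seed = cfg$seed, prr_unfiltered = prr_raw,
             prr_excl_competing = prr_filt,
             filtered_closer = abs(prr_filt - true_ratio) <
               abs(prr_raw - true_ratio))
})
tab <- suppressMessages(do.call(rbind, rows))
write.table(tab, "results/masking_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf(
  "masking strength 5, %d paired replicates at 20,000 reports/arm:\n",
  n_rep))
cat(sprintf("  median PRR unfiltered:          %.3f\n",
            median(tab$prr_unfiltered)))
cat(sprintf("  median PRR excl. competing AEs: %.3f\n",
            median(tab$prr_excl_competing)))
cat(sprintf("  generator truth:                %.2f\n", true_ratio))
cat(sprintf("  exclusion closer to truth in %d/%d replicates\n",
            sum(tab$filtered_closer), n_rep))
cat("wrote results/masking_comparison.tsv\n")
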