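#!/usr/bin/env Rscript
# Step 2 — the worked example from the published 2x2 counts.
#
# 295 of 62,098 SGLT2-inhibitor reports and 5,565 of 642,031 other-ATC-A10
# reports contained atrial fibrillation / flutter. This computes the
# proportional reporting ratio with its 95% CI, the reporting rates per
# 1000, and the chi-square test, and writes the row to TSV.

suppressPackageStartupMessages(library(faersdispro))

dir.create("results", showWarnings = FALSE)

tab <- contingency_table(295, 62098 - 295, 5565, 642031 - 5565)
print(tab)
res <- compute_prr(tab)
cat("\n")
print(res)

row <- cbind(analysis = "worked_example", as.data.frame(res))
write.table(row, "results/worked_example.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/worked_example.tsv\n")
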