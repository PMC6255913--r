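#!/usr/bin/env Rscript
# Stage 3: cross-list statistics. AD-DEG / MCI-DEG enrichment and
# direction concordance within the merged blood data; a synthetic
# blood-vs-brain overlap with known odds ratio as a positive control for
# the enrichment stack; and gene-set overrepresentation of the AD DEGs.
# Run stages 1-2 first.

suppressPackageStartupMessages(library(admarker))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed")) && i < length(args))
  as.integer(args[i + 1L]) else 20260921L

ad <- utils::read.delim("results/deg_AD_CTL_genes.tsv",
                        colClasses = c(feature_id = "character"))
mci <- utils::read.delim("results/deg_MCI_CTL_genes.tsv",
                         colClasses = c(feature_id = "character"))

# AD-DEGs vs MCI-DEGs: enrichment and shared direction
universe <- union(ad$feature_id, mci$feature_id)
ct <- build_contingency(ad$feature_id[ad$significant],
                        mci$feature_id[mci$significant], universe,
                        labels = c("AD-DEGs", "MCI-DEGs", "tested genes"))
enr <- fisher_enrichment(ct)
conc <- direction_concordance(ad, mci)
message(sprintf(
  "AD vs MCI DEG overlap: a=%d, OR=%.2f (95%%CI %.2f-%.2f), p=%.3g",
  ct$a, enr$or, enr$ci[1], enr$ci[2], enr$p))
message(sprintf("direction concordance: %.1f%% of %d (sign test p=%.3g)",
                100 * conc$proportion, conc$n_overlap, conc$p))
utils::write.table(
  data.frame(comparison = "AD_vs_MCI", a = ct$a, b = ct$b, c = ct$c,
             d = ct$d, or = enr$or, ci_lo = enr$ci[1], ci_hi = enr$ci[2],
             p = enr$p, method = enr$method,
             concordant = conc$n_same_direction,
             overlap = conc$n_overlap, sign_p = conc$p),
  "results/enrichment_ad_mci.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# Synthetic blood-vs-brain overlap with a known OR (positive control)
ol <- generate_overlap_lists(16000, 4000, 3000, target_or = 1.5,
                             concordance = 0.78, seed = seed)
ct2 <- build_contingency(ol$listA$feature_id, ol$listB$feature_id,
                         ol$universe,
                         labels = c("blood DEGs", "brain DEGs", "genes"))
enr2 <- fisher_enrichment(ct2)
ov <- merge(ol$listA, ol$listB, by = "feature_id")
bt <- stats::binom.test(sum(ov$direction.x == ov$direction.y), nrow(ov))
message(sprintf(
  "synthetic blood/brain overlap: OR=%.2f (target 1.5), concordance %.1f%%",
  enr2$or, 100 * mean(ov$direction.x == ov$direction.y)))
utils::write.table(
  data.frame(comparison = "blood_vs_brain_synthetic", a = ct2$a,
             or = enr2$or, ci_lo = enr2$ci[1], ci_hi = enr2$ci[2],
             p = enr2$p,
             concordance = mean(ov$direction.x == ov$direction.y),
             sign_p = bt$p.value),
  "results/enrichment_blood_brain.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# Overrepresentation of AD DEGs (all, up, down) in the gene sets
sets <- read_gmt("scratch/sim/genesets.gmt")
deg_all <- ad$feature_id[ad$significant]
res <- rbind(
  ora(deg_all, ad$feature_id, sets, "all"),
  ora(ad$feature_id[ad$significant & ad$direction == "up"],
      ad$feature_id, sets, "up"),
  ora(ad$feature_id[ad$significant & ad$direction == "down"],
      ad$feature_id, sets, "down"))
utils::write.table(res, "results/ora_ad.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
sig <- res[res$significant & res$direction == "all", ]
message(sprintf("ORA: %d/%d sets significant at BH < 0.01 (top: %s, %s)",
                nrow(sig), sum(res$direction == "all"),
                if (nrow(sig)) sig$set[1] else "none",
                if (nrow(sig)) sig$ratio[1] else ""))

write_run_metadata(list(stage = "concordance", seed = seed,
                        universe_size = length(universe)),
                   "results/03_concordance_metadata.json")
message("stage 3 done: enrichment/ORA tables in results/")
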