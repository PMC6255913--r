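#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic blood cohorts with known ground
# truth, plus a probeset->gene annotation and a gene-set collection with
# planted enrichment. Large raw matrices go to scratch/sim/ (regenerable
# from the seed); small summaries and the truth file go to results/.

suppressPackageStartupMessages(library(admarker))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed")) && i < length(args))
  as.integer(args[i + 1L]) else 20260921L

sim_dir <- "scratch/sim"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_features = 2000, seed = seed)
sim <- generate_cohorts(cfg)
message(sprintf("cohort A: %d samples, cohort B: %d samples, G = %d",
                ncol(sim$datasets$A$matrix), ncol(sim$datasets$B$matrix),
                cfg$n_features))
message(sprintf("planted: %d DEGs, %d panel features",
                nrow(sim$truth$deg), nrow(sim$truth$panel)))

for (lab in c("A", "B")) {
  write_expression_matrix(sim$datasets[[lab]],
                          file.path(sim_dir, paste0("cohort_", lab, ".tsv")))
  write_sample_info(sim$sample_info[[lab]],
                    file.path(sim_dir, paste0("samples_", lab, ".tsv")))
}

# Annotation: ~90% of probesets annotated; some genes carry two probesets
# (mirrors the probeset/gene distinction of array platforms).
set.seed(seed + 900)
fids <- sim$datasets$A$feature_ids
annotated <- runif(length(fids)) < 0.9
gene_pool <- sprintf("%d", 10000 + seq_len(1500))
gene_of <- sample(gene_pool, length(fids), replace = TRUE)
ann <- data.frame(feature_id = fids,
                  gene_id = ifelse(annotated, gene_of, ""),
                  symbol = ifelse(annotated, paste0("GENE", gene_of), ""),
                  stringsAsFactors = FALSE)
utils::write.table(ann, file.path(sim_dir, "annotation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("annotation: %d of %d probesets annotated, %d unique genes",
                sum(annotated), length(fids),
                length(unique(gene_of[annotated]))))

# Gene sets over the annotated gene universe, two planted on the genes of
# true DEG probesets
deg_genes <- unique(ann$gene_id[ann$feature_id %in%
                                  sim$truth$deg$feature_id &
                                  nzchar(ann$gene_id)])
universe <- unique(ann$gene_id[nzchar(ann$gene_id)])
gs <- local({
  set.seed(seed + 901)
  sets <- lapply(1:20, function(j) {
    w <- if (j <= 2) ifelse(universe %in% deg_genes, 6, 1) else
      rep(1, length(universe))
    sample(universe, sample(30:80, 1), prob = w)
  })
  names(sets) <- sprintf("SET%03d", 1:20)
  structure(sets, class = "gene_set_collection")
})
write_gmt(gs, file.path(sim_dir, "genesets.gmt"))

write_truth(sim$truth, "results/simulation_truth.json")
write_run_metadata(list(stage = "simulate", seed = seed,
                        config = unclass(cfg)),
                   "results/01_simulate_metadata.json")
message("stage 1 done: raw data in ", sim_dir,
        ", truth in results/simulation_truth.json")
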