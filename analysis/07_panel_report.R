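#!/usr/bin/env Rscript
# Random-Forest distillation of the union outliers into a minimal
# discriminant panel (OOB tuning + two-step backward purging), DAPC
# confusion-matrix validation, and the consolidated report tables with
# group means alongside the bundled reference summaries.

suppressPackageStartupMessages(library(domestiscan))

full <- read_vcf(file.path("results", "qc", "full_snps.vcf"),
                 file.path("results", "qc", "popmap.tsv"))
union_ids <- readLines(file.path("results", "scan", "rf_candidates.txt"))

X <- full$geno[, match(union_ids, full$map$id), drop = FALSE]
colnames(X) <- union_ids
y <- factor(full$pop_class[full$pop])
res <- backward_purge(X, y, rf_config(ntree_max = 300, seed = 6))
cat("final panel (", length(res$panel), " markers):",
    paste(res$panel, collapse = ", "), "\n")
d <- dapc_confusion(X[, res$panel, drop = FALSE], y)
print(d$confusion)
cat(sprintf("DAPC leave-one-out accuracy: %.1f%%\n", 100 * d$accuracy))

div <- utils::read.table(file.path("results", "stats", "diversity.tsv"),
                         header = TRUE, sep = "\t")
ne <- utils::read.table(file.path("results", "ne_ld", "ne_estimates.tsv"),
                        header = TRUE, sep = "\t")
fst <- as.matrix(utils::read.table(
  file.path("results", "stats", "fst_matrix.tsv"),
  header = TRUE, sep = "\t", check.names = FALSE))
rep_tabs <- report_tables(
  div[, c("pop", "class", "N", "Ar", "Ho", "He", "rarefaction_g")],
  div[, c("pop", "relatedness_mean", "relatedness_sd")],
  ne, fst, full$pop_class, out_dir = file.path("results", "report"))
print(rep_tabs$group_means, row.names = FALSE, digits = 3)

dir.create(file.path("results", "report"), showWarnings = FALSE)
utils::write.table(res$trace,
                   file.path("results", "report", "purge_trace.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(res$panel, file.path("results", "report", "rf_panel.txt"))
utils::write.table(as.data.frame(d$confusion),
                   file.path("results", "report", "dapc_confusion.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
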