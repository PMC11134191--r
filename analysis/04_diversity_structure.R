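#!/usr/bin/env Rscript
# Per-population diversity (Ho, He, rarefied allelic richness), Ritland
# relatedness, pairwise Weir-Cockerham FST with wild/selected group means,
# and PCA ellipse areas on the clumped-neutral set.

suppressPackageStartupMessages(library(domestiscan))

cn <- read_vcf(file.path("results", "scan", "clumped_neutral.vcf"),
               file.path("results", "qc", "popmap.tsv"))
full <- read_vcf(file.path("results", "qc", "full_snps.vcf"),
                 file.path("results", "qc", "popmap.tsv"))

div <- diversity(cn)
rel <- do.call(rbind, lapply(unique(cn$pop), function(p) {
  r <- ritland_relatedness(cn, p)
  data.frame(pop = p, relatedness_mean = r$mean, relatedness_sd = r$sd)
}))
print(merge(div, rel, by = "pop"), row.names = FALSE, digits = 3)

fst <- wc_fst(full)
gm <- fst_group_means(fst, full$pop_class)
print(gm, row.names = FALSE, digits = 3)

ell <- pca_ellipses(cn)
print(ell, row.names = FALSE, digits = 3)

dir.create(file.path("results", "stats"), showWarnings = FALSE)
utils::write.table(merge(div, rel, by = "pop"),
                   file.path("results", "stats", "diversity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(fst),
                   file.path("results", "stats", "fst_matrix.tsv"),
                   sep = "\t", quote = FALSE)
utils::write.table(gm, file.path("results", "stats", "fst_group_means.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ell, file.path("results", "stats", "pca_ellipses.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
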