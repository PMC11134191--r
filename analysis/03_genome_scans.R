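#!/usr/bin/env Rscript
# Dual genome scans on the pooled wild-versus-selected contrast: the
# trimmed chi-square FST-outlier test and the PC-regression Mahalanobis
# test, both parameterized on the clumped set and tested on the full set;
# the deduplicated union defines the candidate domestication loci and the
# clumped-neutral set used by the structure analyses.

suppressPackageStartupMessages(library(domestiscan))

full <- read_vcf(file.path("results", "qc", "full_snps.vcf"),
                 file.path("results", "qc", "popmap.tsv"))
clumped <- read_vcf(file.path("results", "qc", "clumped_snps.vcf"),
                    file.path("results", "qc", "popmap.tsv"))

fs <- fst_outlier_scan(full, clumped$map$id)
cat(sprintf("FST-scan null: FSTbar = %.4f, df = %.2f; %d outliers\n",
            attr(fs, "fstbar"), attr(fs, "df"),
            sum(fs$outlier_fst, na.rm = TRUE)))
ps <- pc_outlier_scan(full, clumped$map$id)
cat(sprintf("PC scan: K = %d, inflation = %.2f; %d outliers\n",
            attr(ps, "K"), attr(ps, "gif"), sum(ps$outlier_pc)))

u <- union_outliers(fs, ps)
cat(sprintf("union: %d FST + %d PC - %d shared = %d outliers\n",
            u$n_fst, u$n_pc, u$n_shared, u$n_union))

cn <- make_clumped_neutral(full, u$union_ids)
cat("clumped-neutral SNPs:", n_markers(cn), "\n")

dir.create(file.path("results", "scan"), showWarnings = FALSE)
utils::write.table(u$table, file.path("results", "scan", "scan_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(u$union_ids, file.path("results", "scan", "union_outliers.txt"))
writeLines(scan_candidates(u), file.path("results", "scan", "rf_candidates.txt"))
write_vcf(cn, file.path("results", "scan", "clumped_neutral.vcf"))
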