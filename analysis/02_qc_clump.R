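#!/usr/bin/env Rscript
# Quality filtering and LD clumping: reads the simulated VCF back through
# the I/O layer, applies the filtering cascade (MAF, sample missingness,
# per-population call rate, per-population HWE) and 10-kb/r2>=0.2 clumping,
# and writes the telescoping filter report plus filtered VCFs.

suppressPackageStartupMessages(library(domestiscan))

ds <- read_vcf(file.path("results", "panel", "panel.vcf"),
               file.path("results", "panel", "popmap.tsv"))
flt <- apply_filters(ds)
print(flt$report, row.names = FALSE)

clumped <- ld_clump(flt$ds)
cat("full SNPs:", n_markers(flt$ds),
    " clumped SNPs:", n_markers(clumped), "\n")

dir.create(file.path("results", "qc"), recursive = TRUE,
           showWarnings = FALSE)
utils::write.table(flt$report,
                   file.path("results", "qc", "filter_report.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_vcf(flt$ds, file.path("results", "qc", "full_snps.vcf"),
          file.path("results", "qc", "popmap.tsv"))
write_vcf(clumped, file.path("results", "qc", "clumped_snps.vcf"))
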