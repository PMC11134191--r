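# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# the default demonstration panel (4 wild populations, 4 strains)
demo_sim <- function(seed = 1) {
  key <- paste0("demo_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- assemble_panel(demo_config(seed = seed))
  .fixture_env[[key]]
}

# demo panel passed through QC + clumping
demo_qc <- function(seed = 1) {
  key <- paste0("qc_", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- demo_sim(seed)
    flt <- apply_filters(sim$ds)
    .fixture_env[[key]] <- list(sim = sim, full = flt$ds,
                                report = flt$report,
                                clumped = ld_clump(flt$ds))
  }
  .fixture_env[[key]]
}

# demo panel genome scans (both methods + union), memoized
demo_scan <- function(seed = 1) {
  key <- paste0("scan_", seed)
  if (is.null(.fixture_env[[key]])) {
    qc <- demo_qc(seed)
    fs <- fst_outlier_scan(qc$full, qc$clumped$map$id)
    ps <- pc_outlier_scan(qc$full, qc$clumped$map$id)
    .fixture_env[[key]] <- union_outliers(fs, ps)
  }
  .fixture_env[[key]]
}

# a small dataset built directly from a dosage matrix
make_ds <- function(geno, pop = rep("p1", nrow(geno)),
                    class = c(p1 = "wild"),
                    chrom = rep("chr1", ncol(geno)),
                    pos = seq_len(ncol(geno)) * 1000L) {
  geno_dataset(geno, sprintf("s%03d", seq_len(nrow(geno))), pop, class,
               data.frame(id = sprintf("m%04d", seq_len(ncol(geno))),
                          chrom = chrom, pos = pos))
}

# random dosage matrix under HWE at given allele frequencies
hwe_geno <- function(n, p) {
  vapply(p, function(pp) stats::rbinom(n, 2, pp), numeric(n))
}
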