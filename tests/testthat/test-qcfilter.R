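test_that("exact HWE p-values match the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(10, 5, 1), c(3, 30, 2),
                c(0, 10, 0), c(7, 1, 7), c(40, 38, 12))
  for (cs in cases)
    expect_equal(hwe_exact_pvalue(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:40) {
    n <- sample(5:80, 1)
    g <- stats::rbinom(n, 2, stats::runif(1, 0.05, 0.95))
    cs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_equal(hwe_exact_pvalue(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
})

test_that("HWE edge cases: monomorphic loci pass, balanced loci do not", {
  expect_equal(hwe_exact_pvalue(30, 0, 0), 1)
  expect_lt(hwe_exact_pvalue(50, 0, 50), 1e-6)
})

test_that("the filter cascade removes hand-planted violations in order", {
  set.seed(21)
  n <- 40
  p <- stats::runif(30, 0.2, 0.8)
  g <- hwe_geno(n, p)
  # marker 1: inside excluded region; marker 2: rare (pooled MAF < 0.05)
  g[, 2] <- c(rep(1, 2), rep(0, n - 2))          # MAF = 0.025
  # marker 3: poor call rate in pop2
  g[21:n, 3] <- NA
  # marker 4: HWE failure in both pops (all hets)
  g[, 4] <- 1
  # sample 1: > 10% missing
  g[1, 5:30] <- NA
  ds <- make_ds(g, pop = rep(c("p1", "p2"), each = 20),
                class = c(p1 = "wild", p2 = "selected"))
  regions <- data.frame(chrom = "chr1", start = 999, end = 1001)
  res <- apply_filters(ds, filter_config(), regions)
  rep_ <- res$report
  expect_equal(rep_$markers_removed[rep_$step == "excluded_regions"], 1)
  expect_equal(rep_$markers_removed[rep_$step == "maf"], 1)
  expect_equal(rep_$samples_removed[rep_$step == "sample_missingness"], 1)
  expect_equal(rep_$markers_removed[rep_$step == "pop_callrate"], 1)
  expect_equal(rep_$markers_removed[rep_$step == "hwe"], 1)
  expect_false(any(c("m0001", "m0002", "m0003", "m0004") %in% res$ds$map$id))
})

test_that("the MAF boundary is exclusive-remove (exactly 0.05 is kept)", {
  n <- 40
  g <- matrix(0L, n, 3)
  g[, 1] <- hwe_geno(n, 0.5)
  g[1:4, 2] <- 1L                                 # MAF = 4/80 = 0.05
  g[1:3, 3] <- 1L                                 # MAF = 3/80 < 0.05
  ds <- make_ds(g, pop = rep(c("p1", "p2"), each = 20),
                class = c(p1 = "wild", p2 = "wild"))
  res <- apply_filters(ds, filter_config(hwe_p_min = 1e-12))
  expect_true("m0002" %in% res$ds$map$id)
  expect_false("m0003" %in% res$ds$map$id)
})

test_that("filter report telescopes and filtering is idempotent", {
  qc <- demo_qc()
  rp <- qc$report
  for (k in 2:nrow(rp)) {
    expect_equal(rp$markers_retained[k],
                 rp$markers_retained[k - 1] - rp$markers_removed[k])
    expect_equal(rp$samples_retained[k],
                 rp$samples_retained[k - 1] - rp$samples_removed[k])
  }
  again <- apply_filters(qc$full, filter_config())
  expect_equal(n_markers(again$ds), n_markers(qc$full))
  expect_equal(n_samples(again$ds), n_samples(qc$full))
})

test_that("higher-MAF members win clumping; distant pairs are untouched", {
  set.seed(4)
  base <- stats::rbinom(60, 2, 0.3)
  flip <- function(x, k) { i <- sample(60, k); x[i] <- 2 - x[i]; x }
  g <- cbind(base, flip(base, 3), base, flip(base, 2))
  g[1:12, 2] <- pmin(g[1:12, 2] + 1, 2)  # raise MAF of marker 2
  ds <- make_ds(g, pop = rep("p1", 60),
                pos = c(1000L, 6000L, 50000L, 65000L))
  mafs <- maf(ds)
  out <- ld_clump(ds, filter_config())
  # pair (1,2): 5 kb apart, correlated; lower-MAF member dropped
  dropped <- if (mafs[1] < mafs[2]) "m0001" else "m0002"
  expect_false(dropped %in% out$map$id)
  # pair (3,4): 15 kb apart, r^2 high but outside the 10-kb window
  expect_true(all(c("m0003", "m0004") %in% out$map$id))
})

test_that("greedy clumping matches the O(n^2) elimination oracle", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 40; m <- 60
    # blocks of correlated markers: copies of a template with noise
    g <- matrix(0L, n, m)
    j <- 1
    while (j <= m) {
      k <- sample(1:4, 1)
      tmpl <- stats::rbinom(n, 2, stats::runif(1, 0.1, 0.9))
      for (b in seq_len(min(k, m - j + 1))) {
        x <- tmpl
        nm <- sample(n, sample(0:6, 1))
        x[nm] <- stats::rbinom(length(nm), 2, 0.5)
        g[, j] <- x
        j <- j + 1
      }
    }
    pos <- sort(sample.int(200000, m))
    ds <- make_ds(g, pop = rep("p1", n), pos = pos)
    cfg <- filter_config()
    expect_identical(ld_clump(ds, cfg)$map$id, clump_oracle(ds, cfg))
  }
})

test_that("no surviving within-window pair violates the r^2 threshold", {
  qc <- demo_qc()
  ds <- qc$clumped
  cfg <- filter_config()
  viol <- 0
  for (cols in split(seq_len(n_markers(ds)), ds$map$chrom)) {
    pos <- ds$map$pos[cols]
    for (a in seq_along(cols)) {
      b <- a + 1
      while (b <= length(cols) && pos[b] - pos[a] <= cfg$clump_window_bp) {
        r2 <- composite_r2(ds$geno[, cols[a]], ds$geno[, cols[b]])
        if (!is.na(r2) && r2 >= cfg$clump_r2_max) viol <- viol + 1
        b <- b + 1
      }
    }
  }
  expect_equal(viol, 0)
})
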