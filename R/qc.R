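#' Filtering configuration
#'
#' Defaults mirror standard SNP-array practice for population-genomic QC:
#' pooled minor allele frequency below 0.05 removed (exactly 0.05 retained),
#' samples with more than 10% missing data removed, markers with call rate
#' below 0.95 in any single population removed, markers out of
#' Hardy-Weinberg equilibrium at p < 0.01 in at least half the populations
#' removed, and LD clumping in a 10-kb window at r^2 >= 0.2 keeping the
#' higher-MAF member of each pair.
#'
#' @param maf_min pooled MAF threshold (markers with MAF < `maf_min` removed).
#' @param sample_missing_max maximum per-sample missing fraction.
#' @param pop_callrate_min minimum per-population marker call rate.
#' @param hwe_p_min HWE exact-test p-value threshold.
#' @param hwe_pop_frac fraction of populations that must fail HWE for removal.
#' @param clump_window_bp clumping window (bp).
#' @param clump_r2_max r^2 threshold for clumping.
#' @param pc_outlier_rounds rounds of iterative PCA loading-outlier removal
#'   after clumping (|loading z| > 6, at most 5 rounds); 0 disables.
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf_min = 0.05, sample_missing_max = 0.10,
                          pop_callrate_min = 0.95, hwe_p_min = 0.01,
                          hwe_pop_frac = 0.5, clump_window_bp = 10000,
                          clump_r2_max = 0.2, pc_outlier_rounds = 0) {
  stopifnot(maf_min > 0, maf_min <= 1, sample_missing_max > 0,
            sample_missing_max <= 1, pop_callrate_min > 0,
            pop_callrate_min <= 1, hwe_p_min > 0, hwe_p_min <= 1,
            hwe_pop_frac > 0, hwe_pop_frac <= 1, clump_window_bp > 0,
            clump_r2_max > 0, clump_r2_max <= 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test (Levene-Haldane distribution of heterozygote counts
#' conditional on allele counts): the p-value sums the probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) return(NA_real_)
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  # log Levene-Haldane probability for each possible het count
  logp <- vapply(hets, function(h) {
    a <- (rare - h) / 2           # rare-allele homozygotes
    b <- (2 * n - rare - h) / 2   # common homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("impossible heterozygote count for allele totals")
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}

#' Apply the marker/sample filtering cascade
#'
#' Steps, in order: (1) excluded-region removal, (2) pooled-MAF filter over
#' all retained samples combined, (3) per-sample missingness, (4)
#' per-population call rate, (5) per-population HWE. A telescoping report of
#' counts is returned alongside the filtered dataset ("full SNPs").
#'
#' @param ds a `geno_ds`.
#' @param cfg a [filter_config()].
#' @param regions optional data.frame from [read_regions()].
#' @return list with `ds` (filtered) and `report` (data.frame: step,
#'   markers_removed, samples_removed, markers_retained, samples_retained).
#' @export
apply_filters <- function(ds, cfg = filter_config(), regions = NULL) {
  if (length(unique(ds$pop)) < 2) stop("need >= 2 populations")
  rep_rows <- list()
  note <- function(step, mrem, srem) {
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      step = step, markers_removed = mrem, samples_removed = srem,
      markers_retained = n_markers(ds), samples_retained = n_samples(ds))
  }
  note("input", 0L, 0L)

  if (!is.null(regions) && nrow(regions)) {
    drop <- markers_in_regions(ds$map, regions)
    ds <- subset_geno(ds, markers = !drop)
    note("excluded_regions", sum(drop), 0L)
  } else note("excluded_regions", 0L, 0L)

  mafs <- maf(ds)
  drop <- is.na(mafs) | mafs < cfg$maf_min
  ds <- subset_geno(ds, markers = !drop)
  note("maf", sum(drop), 0L)

  smiss <- rowMeans(is.na(ds$geno))
  sdrop <- smiss > cfg$sample_missing_max
  ds <- subset_geno(ds, samples = !sdrop)
  note("sample_missingness", 0L, sum(sdrop))

  pops <- unique(ds$pop)
  cr_ok <- rep(TRUE, n_markers(ds))
  for (p in pops) {
    cr <- colMeans(!is.na(ds$geno[pop_samples(ds, p), , drop = FALSE]))
    cr_ok <- cr_ok & cr >= cfg$pop_callrate_min
  }
  ds <- subset_geno(ds, markers = cr_ok)
  note("pop_callrate", sum(!cr_ok), 0L)

  fail <- matrix(FALSE, length(pops), n_markers(ds))
  for (pi in seq_along(pops)) {
    g <- ds$geno[pop_samples(ds, pops[pi]), , drop = FALSE]
    pv <- apply(g, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)   # all missing: treated as pass
      hwe_exact_pvalue(sum(x == 0), sum(x == 1), sum(x == 2))
    })
    fail[pi, ] <- !is.na(pv) & pv < cfg$hwe_p_min
  }
  hwe_drop <- colMeans(fail) >= cfg$hwe_pop_frac
  ds <- subset_geno(ds, markers = !hwe_drop)
  note("hwe", sum(hwe_drop), 0L)

  if (n_markers(ds) == 0) stop("no markers survive filtering")
  list(ds = ds, report = do.call(rbind, rep_rows))
}

# r^2 between two dosage vectors over jointly non-missing samples
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' LD clumping
#'
#' Greedy per-chromosome pass: every marker pair closer than the window with
#' dosage-correlation r^2 at or above the threshold loses its lower-MAF
#' member (on a MAF tie the right/larger-position marker is dropped). Because
#' each pair's r^2 is fixed, the result is the unique fixpoint of iterative
#' pair elimination in positional order; no surviving within-window pair
#' violates the threshold.
#'
#' @param ds a `geno_ds` (markers sorted by position).
#' @param cfg a [filter_config()].
#' @return a `geno_ds` restricted to the retained markers.
#' @export
ld_clump <- function(ds, cfg = filter_config()) {
  keep <- rep(TRUE, n_markers(ds))
  mafs <- maf(ds)
  for (cols in split(seq_len(n_markers(ds)), ds$map$chrom)) {
    pos <- ds$map$pos[cols]
    for (a in seq_along(cols)) {
      i <- cols[a]
      if (!keep[i]) next
      b <- a + 1
      while (b <= length(cols) && pos[b] - pos[a] <= cfg$clump_window_bp) {
        j <- cols[b]
        if (keep[j]) {
          r2 <- pair_r2(ds$geno[, i], ds$geno[, j])
          if (!is.na(r2) && r2 >= cfg$clump_r2_max) {
            if (mafs[j] < mafs[i] || isTRUE(all.equal(mafs[i], mafs[j]))) {
              keep[j] <- FALSE
            } else {
              keep[i] <- FALSE
              break
            }
          }
        }
        b <- b + 1
      }
    }
  }
  out <- subset_geno(ds, markers = keep)
  if (cfg$pc_outlier_rounds > 0) out <- drop_loading_outliers(out, cfg)
  out
}

# iterative PCA loading-outlier removal (optional post-clumping step)
drop_loading_outliers <- function(ds, cfg, k = 5, z_max = 6) {
  for (round in seq_len(min(cfg$pc_outlier_rounds, 5))) {
    X <- scaled_imputed_matrix(ds)
    k_use <- min(k, nrow(X) - 1, ncol(X) - 1)
    sv <- svd(X, nu = 0, nv = k_use)
    drop <- rep(FALSE, ncol(X))
    for (j in seq_len(k_use)) {
      v <- sv$v[, j]
      z <- (v - stats::median(v)) / stats::mad(v)
      drop <- drop | abs(z) > z_max
    }
    if (!any(drop)) break
    ds <- subset_geno(ds, markers = !drop)
  }
  ds
}

# mean-imputed, frequency-scaled dosage matrix (samples x markers)
scaled_imputed_matrix <- function(ds, markers = NULL) {
  g <- if (is.null(markers)) ds$geno else ds$geno[, markers, drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  mu <- 2 * p
  sdv <- sqrt(pmax(2 * p * (1 - p), 1e-12))
  X <- sweep(g, 2, mu)
  X[is.na(X)] <- 0
  sweep(X, 2, sdv, "/")
}
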