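#' Composite LD r-squared between two loci
#'
#' Squared Pearson correlation of unphased dosage vectors over jointly
#' non-missing samples (the Burrows composite measure for genotypic data).
#'
#' @param g1,g2 dosage vectors.
#' @return r^2, or `NA` when fewer than 2 joint calls or zero variance.
#' @export
composite_r2 <- function(g1, g2) pair_r2(g1, g2)

#' LD-based contemporary effective size (single-sample method)
#'
#' Mean composite r^2 over between-chromosome marker pairs (physical linkage
#' excluded), corrected for the sampling contribution with the random-mating
#' bias approximations of Waples (2006) / NeEstimator v2: for harmonic
#' sample size S >= 30, E(r^2 | drift = 0) = 1/S + 3.19/S^2 and
#' Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2'); for S < 30,
#' E(r^2) = 0.0018 + 0.907/S + 4.44/S^2 and
#' Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2'), where r2' is the
#' drift residual. A non-positive residual yields an infinite estimate.
#' Confidence intervals use a delete-one-individual jackknife with a
#' chi-square approximation on the effective degrees of freedom.
#'
#' @param ds a `geno_ds`.
#' @param pop population label.
#' @param maf_min alleles below this frequency (within the population
#'   sample) are excluded.
#' @param n_snps random markers retained for the pair computation.
#' @param seed integer seed for the marker subsample.
#' @param min_samples minimum individuals required.
#' @return list: pop, S (harmonic mean pair sample size), n_pairs, r2_mean,
#'   r2_drift, Ne_hat, CI (low, high; Inf allowed).
#' @export
estimate_ne <- function(ds, pop, maf_min = 0.05, n_snps = 5000, seed = 1,
                        min_samples = 10, n_snps_ci = 800) {
  si <- pop_samples(ds, pop)
  if (length(si) < min_samples)
    stop("population ", pop, " has fewer than ", min_samples, " samples")
  if (length(unique(ds$map$chrom)) < 2)
    stop("cross-chromosome pairing requires >= 2 chromosomes")
  g <- ds$geno[si, , drop = FALSE]
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(colSums(!is.na(g)), 1))
  keep <- which(!is.na(p) & pmin(p, 1 - p) >= maf_min)
  set.seed(seed)
  if (length(keep) > n_snps) keep <- sort(sample(keep, n_snps))
  g <- g[, keep, drop = FALSE]
  chrom <- ds$map$chrom[keep]

  stat <- ne_r2_stats(g, chrom)
  res <- ne_from_r2(stat$r2_mean, stat$S)

  # jackknife over individuals -> chi-square CI on the drift residual;
  # computed on a capped marker subset to keep the resampling tractable
  n <- nrow(g)
  jcols <- seq_len(ncol(g))
  if (length(jcols) > n_snps_ci) jcols <- sort(sample(jcols, n_snps_ci))
  gj <- g[, jcols, drop = FALSE]
  jack <- vapply(seq_len(n), function(i) {
    s <- ne_r2_stats(gj[-i, , drop = FALSE], chrom[jcols])
    s$r2_mean
  }, numeric(1))
  theta <- stat$r2_mean
  jvar <- (n - 1) / n * sum((jack - mean(jack))^2)
  ci <- c(NA_real_, NA_real_)
  if (jvar > 0) {
    ndf <- max(2 * theta^2 / jvar, 2)   # effective df from jackknife CV
    r2_hi <- theta * ndf / stats::qchisq(0.025, ndf)
    r2_lo <- theta * ndf / stats::qchisq(0.975, ndf)
    ci <- c(ne_from_r2(r2_hi, stat$S)$Ne,   # larger r2 -> smaller Ne
            ne_from_r2(r2_lo, stat$S)$Ne)
  }
  list(pop = pop, S = stat$S, n_pairs = stat$n_pairs,
       r2_mean = stat$r2_mean, r2_drift = res$r2_drift, Ne_hat = res$Ne,
       CI = ci)
}

# Mean between-chromosome r^2 and harmonic-mean pair sample size.
# r^2 is the Burrows composite disequilibrium with the n/(n-1) small-sample
# factor over the product of allele-frequency variances (the estimator the
# random-mating sampling corrections were calibrated on).
ne_r2_stats <- function(g, chrom) {
  if (!anyNA(g)) {
    n <- nrow(g)
    p <- colMeans(g) / 2
    delta <- crossprod(g) / (2 * n) - 2 * outer(p, p)
    pq <- p * (1 - p)
    r2 <- (n / (n - 1))^2 * delta^2 / outer(pq, pq)
    r2[pq == 0, ] <- NA; r2[, pq == 0] <- NA
    between <- outer(chrom, chrom, "!=") & upper.tri(r2)
    use <- between & !is.na(r2)
    return(list(r2_mean = mean(r2[use]), n_pairs = sum(use), S = n))
  }
  ok <- !is.na(g)
  Xc <- g; Xc[!ok] <- 0
  n_j <- crossprod(ok)                    # joint non-missing counts
  sx <- crossprod(ok, Xc)                 # sums of x over joint support
  sxy <- crossprod(Xc)
  nj <- pmax(n_j, 1)
  px <- sx / (2 * nj)                     # freq of x over the joint support
  delta <- sxy / (2 * nj) - 2 * px * t(px)
  pqx <- px * (1 - px)
  denom <- pqx * t(pqx)
  fac <- (nj / pmax(nj - 1, 1))^2
  r2 <- ifelse(denom > 0 & n_j >= 2, fac * delta^2 / denom, NA_real_)
  between <- outer(chrom, chrom, "!=") & upper.tri(r2)
  use <- between & !is.na(r2)
  list(r2_mean = mean(r2[use]), n_pairs = sum(use),
       S = 1 / mean(1 / n_j[use]))
}

# Waples (2006) random-mating bias correction and estimator inversion
ne_from_r2 <- function(r2_mean, S) {
  if (S >= 30) {
    r2_drift <- r2_mean - (1 / S + 3.19 / S^2)
    disc <- 1 / 9 - 2.76 * r2_drift
    ne <- if (r2_drift <= 0 || disc < 0 && r2_drift <= 0) Inf else
      (1 / 3 + sqrt(max(disc, 0))) / (2 * r2_drift)
  } else {
    r2_drift <- r2_mean - (0.0018 + 0.907 / S + 4.44 / S^2)
    disc <- 0.308^2 - 2.08 * r2_drift
    ne <- if (r2_drift <= 0) Inf else
      (0.308 + sqrt(max(disc, 0))) / (2 * r2_drift)
  }
  if (!is.infinite(ne) && ne < 0) ne <- Inf
  list(r2_drift = r2_drift, Ne = ne)
}

#' Ne/Nb estimates for every population
#' @param ds a `geno_ds`.
#' @inheritParams estimate_ne
#' @return data.frame: pop, class, S, n_pairs, r2_mean, r2_drift, Ne_hat,
#'   CI_low, CI_high.
#' @export
estimate_ne_all <- function(ds, maf_min = 0.05, n_snps = 5000, seed = 1,
                            min_samples = 10) {
  pops <- unique(ds$pop)
  rows <- lapply(pops, function(p) {
    r <- estimate_ne(ds, p, maf_min, n_snps,
                     seed = derive_seed(seed, paste0("ne_", p)),
                     min_samples = min_samples)
    data.frame(pop = p, class = unname(ds$pop_class[p]), S = r$S,
               n_pairs = r$n_pairs, r2_mean = r$r2_mean,
               r2_drift = r$r2_drift, Ne_hat = r$Ne_hat,
               CI_low = r$CI[1], CI_high = r$CI[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
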