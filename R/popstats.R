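#' Per-population diversity indices
#'
#' Observed heterozygosity is the mean fraction of heterozygous calls over
#' non-missing genotypes; expected heterozygosity is the unbiased estimator
#' 2*p*q*2n/(2n-1) averaged over loci; allelic richness is computed by
#' rarefaction to a common allele-sample depth g = 2 x the smallest
#' per-locus non-missing count over all populations, so values are
#' comparable across populations.
#'
#' @param ds a `geno_ds`.
#' @param rarefaction_g optional override of the rarefaction depth (alleles).
#' @return data.frame: pop, class, N, Ar, Ho, He, plus the depth used.
#' @export
diversity <- function(ds, rarefaction_g = NULL) {
  pops <- unique(ds$pop)
  if (is.null(rarefaction_g)) {
    gmin <- Inf
    for (p in pops) {
      g <- ds$geno[pop_samples(ds, p), , drop = FALSE]
      nn <- colSums(!is.na(g))
      nn <- nn[nn >= 2]          # all-missing / singleton loci skipped
      if (length(nn)) gmin <- min(gmin, min(nn))
    }
    rarefaction_g <- 2 * gmin
  }
  rows <- lapply(pops, function(p) {
    g <- ds$geno[pop_samples(ds, p), , drop = FALSE]
    nn <- colSums(!is.na(g))
    ok <- nn >= 2
    het <- colSums(g == 1, na.rm = TRUE)
    ho <- mean((het / nn)[ok])
    pa <- colSums(g, na.rm = TRUE) / (2 * nn)
    he <- mean((2 * pa * (1 - pa) * (2 * nn) / (2 * nn - 1))[ok])
    ar <- mean(rarefied_richness(colSums(g, na.rm = TRUE)[ok],
                                 (2 * nn)[ok], rarefaction_g))
    data.frame(pop = p, class = unname(ds$pop_class[p]), N = nrow(g),
               Ar = ar, Ho = ho, He = he,
               rarefaction_g = rarefaction_g, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# expected number of distinct alleles among g sampled allele copies, per
# locus, for a biallelic locus with alt count ca out of n2 total copies
rarefied_richness <- function(ca, n2, g) {
  g <- pmin(g, n2)
  miss_alt <- exp(lchoose(n2 - ca, g) - lchoose(n2, g))
  miss_ref <- exp(lchoose(ca, g) - lchoose(n2, g))
  (1 - miss_alt) + (1 - miss_ref)
}

#' Ritland pairwise relatedness within a population
#'
#' For a pair (x, y) and a biallelic locus with within-population allele
#' frequencies p and 1-p, the per-locus estimate is
#' r_l = 2 * (x_A y_A / p_A + x_B y_B / p_B - 1), where x_A in \{0, 0.5, 1\}
#' is the individual's proportion of allele A. The multilocus estimate is
#' the mean over polymorphic loci with both genotypes present. The scaling
#' makes clones average 1 and unrelated pairs 0 under Hardy-Weinberg
#' proportions.
#'
#' @param ds a `geno_ds`.
#' @param pop population label.
#' @return list with `pairs` (data.frame id1, id2, r), `mean`, `sd`.
#' @export
ritland_relatedness <- function(ds, pop) {
  si <- pop_samples(ds, pop)
  if (length(si) < 2) stop("need >= 2 samples in population ", pop)
  g <- ds$geno[si, , drop = FALSE]
  p <- colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  poly <- !is.na(p) & p > 0 & p < 1
  n <- nrow(g)
  out <- data.frame(id1 = character(0), id2 = character(0), r = numeric(0))
  res <- vector("list", n * (n - 1) / 2); k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xa <- g[i, ] / 2; ya <- g[j, ] / 2
    use <- poly & !is.na(xa) & !is.na(ya)
    rl <- 2 * (xa[use] * ya[use] / p[use] +
                 (1 - xa[use]) * (1 - ya[use]) / (1 - p[use]) - 1)
    k <- k + 1
    res[[k]] <- data.frame(id1 = ds$sample_ids[si[i]],
                           id2 = ds$sample_ids[si[j]],
                           r = mean(rl), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, res)
  list(pairs = pairs, mean = mean(pairs$r), sd = stats::sd(pairs$r))
}

# Weir-Cockerham (1984) variance components per locus for a grouping
# factor. Returns per-locus a, b, c, the uncorrected (infinite-sample-limit)
# ratio, pooled expected heterozygosity, and a usability flag.
wc_components <- function(geno, group) {
  group <- as.factor(group)
  r <- nlevels(group)
  M <- ncol(geno)
  ni <- pi <- hi <- matrix(0, r, M)
  for (k in seq_len(r)) {
    g <- geno[group == levels(group)[k], , drop = FALSE]
    ni[k, ] <- colSums(!is.na(g))
    pi[k, ] <- colSums(g, na.rm = TRUE) / (2 * pmax(ni[k, ], 1))
    hi[k, ] <- colSums(g == 1, na.rm = TRUE) / pmax(ni[k, ], 1)
  }
  nbar <- colMeans(ni)
  nc <- (colSums(ni) - colSums(ni^2) / pmax(colSums(ni), 1)) / (r - 1)
  pbar <- colSums(ni * pi) / pmax(r * nbar, 1e-12)
  s2 <- colSums(ni * sweep(pi, 2, pbar)^2) / pmax((r - 1) * nbar, 1e-12)
  hbar <- colSums(ni * hi) / pmax(r * nbar, 1e-12)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  he <- 2 * pbar * (1 - pbar)
  denom_nc <- pbar * (1 - pbar) + s2 / r
  theta_nocorr <- ifelse(denom_nc > 0, s2 / denom_nc, NA_real_)
  usable <- colSums(ni >= 2) == r & (pbar > 0) & (pbar < 1)
  list(a = a, b = b, c = cc, he = he, theta_nocorr = theta_nocorr,
       usable = usable, r = r)
}

#' Weir-Cockerham multilocus FST
#'
#' Variance components a, b, c per locus; the multilocus estimate is the
#' ratio of sums, theta = sum(a) / sum(a + b + c). Loci monomorphic across
#' the compared groups (or with fewer than 2 non-missing genotypes in a
#' group) are excluded.
#'
#' @param ds a `geno_ds`.
#' @param group1,group2 vectors of population labels defining two pooled
#'   groups; when both are `NULL` all pairwise population estimates are
#'   returned as a symmetric matrix.
#' @param per_locus when TRUE also return per-locus theta and the
#'   uncorrected per-locus ratio used by the outlier scan.
#' @return a symmetric matrix (all-pairs mode), or a list with `theta` and,
#'   when requested, per-locus columns.
#' @export
wc_fst <- function(ds, group1 = NULL, group2 = NULL, per_locus = FALSE) {
  if (is.null(group1)) {
    pops <- unique(ds$pop)
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)[-length(pops)])
      for (j in (i + 1):length(pops)) {
        m[i, j] <- m[j, i] <- wc_fst(ds, pops[i], pops[j])$theta
      }
    return(m)
  }
  keep <- ds$pop %in% c(group1, group2)
  grp <- ifelse(ds$pop[keep] %in% group1, "g1", "g2")
  comp <- wc_components(ds$geno[keep, , drop = FALSE], grp)
  u <- comp$usable & !is.na(comp$a)
  theta <- sum(comp$a[u]) / sum((comp$a + comp$b + comp$c)[u])
  out <- list(theta = theta, n_loci = sum(u))
  if (per_locus) {
    abc <- comp$a + comp$b + comp$c
    out$theta_locus <- ifelse(comp$usable & abc != 0, comp$a / abc, NA_real_)
    out$theta_nocorr <- ifelse(comp$usable, comp$theta_nocorr, NA_real_)
    out$he <- comp$he
  }
  out
}

#' Group-mean summary of a pairwise FST matrix
#' @param fst symmetric pop x pop matrix.
#' @param pop_class named class vector over the matrix's populations.
#' @return data.frame with contrast (wild-wild, wild-selected,
#'   selected-selected) and mean FST.
#' @export
fst_group_means <- function(fst, pop_class) {
  pops <- rownames(fst)
  cls <- pop_class[pops]
  rows <- list()
  for (ctr in list(c("wild", "wild"), c("wild", "selected"),
                   c("selected", "selected"))) {
    vals <- c()
    for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
      pc <- sort(c(cls[i], cls[j]))
      if (identical(unname(pc), sort(ctr))) vals <- c(vals, fst[i, j])
    }
    rows[[length(rows) + 1]] <- data.frame(
      contrast = paste(ctr, collapse = "-"),
      mean_fst = if (length(vals)) mean(vals) else NA_real_,
      n_pairs = length(vals))
  }
  do.call(rbind, rows)
}
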