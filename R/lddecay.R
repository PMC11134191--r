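#' Binned LD decay along one chromosome
#'
#' All within-chromosome marker pairs separated by at most `max_dist` are
#' assigned to equal-width distance bins and the mean composite r^2 per bin
#' is recorded. A seeded subsample of individuals keeps curves comparable
#' across populations of different size.
#'
#' @param ds a `geno_ds`.
#' @param pop population label.
#' @param chrom chromosome name.
#' @param max_dist maximum pair separation (bp).
#' @param n_bins number of equal-width bins over (0, max_dist].
#' @param subsample individuals drawn (without replacement) per population.
#' @param seed integer seed for the subsample.
#' @return data.frame: bin, dist_mid, mean_r2, n_pairs (empty bins have
#'   n_pairs = 0 and NA mean).
#' @export
binned_ld <- function(ds, pop, chrom, max_dist = 500000, n_bins = 100,
                      subsample = 30, seed = 1) {
  si <- pop_samples(ds, pop)
  set.seed(seed)
  if (length(si) > subsample) si <- sort(sample(si, subsample))
  cols <- which(ds$map$chrom == chrom)
  if (length(cols) < 2) stop("chromosome ", chrom, " has < 2 markers")
  g <- ds$geno[si, cols, drop = FALSE]
  pos <- ds$map$pos[cols]
  m <- length(cols)
  ii <- rep(seq_len(m - 1), times = (m - 1):1)
  jj <- sequence((m - 1):1) + ii
  d <- pos[jj] - pos[ii]
  keep <- d <= max_dist
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  r2 <- if (!anyNA(g)) {
    C <- suppressWarnings(stats::cor(g))^2
    C[cbind(ii, jj)]
  } else {
    vapply(seq_along(ii), function(k) pair_r2(g[, ii[k]], g[, jj[k]]),
           numeric(1))
  }
  width <- max_dist / n_bins
  bin <- pmin(pmax(ceiling(d / width), 1L), n_bins)
  ok <- !is.na(r2)
  mean_r2 <- tapply(r2[ok], factor(bin[ok], levels = seq_len(n_bins)), mean)
  n_pairs <- tapply(rep(1, sum(ok)), factor(bin[ok], levels = seq_len(n_bins)),
                    sum)
  n_pairs[is.na(n_pairs)] <- 0
  data.frame(bin = seq_len(n_bins),
             dist_mid = (seq_len(n_bins) - 0.5) * width,
             mean_r2 = as.numeric(mean_r2),
             n_pairs = as.numeric(n_pairs))
}

#' Hill-Weir expected r-squared under drift-recombination equilibrium
#'
#' E(r^2) = (10+C)/((2+C)(11+C)) * (1 + ((3+C)(12+12C+C^2)) /
#' (n(2+C)(11+C))), with C the population-scaled recombination parameter
#' and n the number of sampled chromosomes. At C = 0 and n -> Inf this is
#' 10/22.
#'
#' @param C non-negative scaled recombination value(s).
#' @param n number of sampled chromosomes (2 x individuals).
#' @return expected r^2.
#' @export
hill_weir_er2 <- function(C, n) {
  (10 + C) / ((2 + C) * (11 + C)) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay curve to binned LD
#'
#' Fits the per-bp scaled recombination rate c in C = c * d by weighted
#' (pair-count) nonlinear least squares on the bin means, restarting from
#' three fixed initial values before giving up. The half-decay distance is
#' the d at which the fitted curve reaches half its value at d -> 0,
#' found numerically on the fitted curve.
#'
#' @param bins data.frame from [binned_ld()].
#' @param n_chromosomes_sampled number of sampled chromosomes
#'   (2 x individuals used for r^2).
#' @return list: c_per_bp, half_decay_bp, fitted (data.frame of d and
#'   fitted r^2), convergence info.
#' @export
hill_weir_fit <- function(bins, n_chromosomes_sampled) {
  b <- bins[bins$n_pairs > 0 & !is.na(bins$mean_r2), ]
  if (nrow(b) < 5) stop("need >= 5 non-empty bins to fit")
  n <- n_chromosomes_sampled
  d <- b$dist_mid; y <- b$mean_r2; w <- b$n_pairs
  fit <- NULL
  for (c0 in c(1e-3, 1e-4, 1e-5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ hill_weir_er2(cc * d, n),
                        start = list(cc = c0),
                        lower = 1e-12, upper = 10,
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Hill-Weir fit failed from all starts; bins: ", nrow(b),
         ", r2 range [", format(min(y)), ", ", format(max(y)), "]")
  cc <- stats::coef(fit)[["cc"]]
  e0 <- hill_weir_er2(0, n)
  target <- e0 / 2
  f <- function(dd) hill_weir_er2(cc * dd, n) - target
  upper <- 1 / cc
  while (f(upper) > 0 && upper < 1e12) upper <- upper * 10
  half <- stats::uniroot(f, c(1e-6, upper))$root
  list(c_per_bp = cc, half_decay_bp = half,
       fitted = data.frame(d = d, r2_hat = hill_weir_er2(cc * d, n)))
}

#' Per-population, per-chromosome LD decay with half-decay distances
#'
#' @param ds a `geno_ds`.
#' @param pops populations (default all).
#' @inheritParams binned_ld
#' @return data.frame: pop, class, chrom, c_per_bp, half_decay_bp.
#' @export
ld_decay_table <- function(ds, pops = unique(ds$pop), max_dist = 500000,
                           n_bins = 100, subsample = 30, seed = 1) {
  rows <- list()
  for (p in pops) for (ch in unique(ds$map$chrom)) {
    bins <- binned_ld(ds, p, ch, max_dist, n_bins, subsample,
                      seed = derive_seed(seed, paste0("ld_", p)))
    n_used <- 2 * min(length(pop_samples(ds, p)), subsample)
    fit <- tryCatch(hill_weir_fit(bins, n_used), error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      pop = p, class = unname(ds$pop_class[p]), chrom = ch,
      c_per_bp = if (is.null(fit)) NA_real_ else fit$c_per_bp,
      half_decay_bp = if (is.null(fit)) NA_real_ else fit$half_decay_bp,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Two-way ANOVA on half-decay distances
#'
#' Ordinary two-factor linear model with interaction
#' (half_decay ~ class * chrom), sequential (type-I) sums of squares.
#'
#' @param decay data.frame with columns class, chrom, half_decay_bp.
#' @return the `anova` table of the fitted model.
#' @export
decay_anova <- function(decay) {
  d <- decay[!is.na(decay$half_decay_bp), ]
  if (length(unique(d$class)) < 2 || length(unique(d$chrom)) < 2)
    stop("need >= 2 levels of class and chromosome")
  tab <- table(d$class, d$chrom)
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: class ", rownames(tab)[idx[1]],
         " x chromosome ", colnames(tab)[idx[2]])
  }
  fit <- stats::lm(half_decay_bp ~ class * chrom, data = d)
  if (stats::var(d$half_decay_bp) == 0) {
    # degenerate constant response: no effect of anything
    out <- suppressWarnings(stats::anova(fit))
    k <- seq_len(nrow(out) - 1)
    out[k, "F value"] <- 0
    out[k, "Pr(>F)"] <- 1
    return(out)
  }
  stats::anova(fit)
}
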