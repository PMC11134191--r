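# Independent reference implementations ("oracles") used to cross-check the
# package's algorithms. These share no code with the implementation paths.

# exact HWE p-value by direct multinomial enumeration of heterozygote
# configurations conditional on allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  prob <- function(h) {
    a <- (nA - h) / 2
    b <- n - a - h
    exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }
  hs <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  ps <- vapply(hs, prob, numeric(1))
  sum(ps[ps <= prob(n_Aa) * (1 + 1e-9)])
}

# O(n^2) iterative elimination clumping: repeatedly find the first violating
# pair in positional order and drop its lower-MAF member
clump_oracle <- function(ds, cfg) {
  alive <- rep(TRUE, n_markers(ds))
  mafs <- maf(ds)
  repeat {
    dropped <- FALSE
    idx <- which(alive)
    for (ai in seq_along(idx)) {
      for (bi in seq_along(idx)) {
        if (bi <= ai) next
        i <- idx[ai]; j <- idx[bi]
        if (ds$map$chrom[i] != ds$map$chrom[j]) next
        if (ds$map$pos[j] - ds$map$pos[i] > cfg$clump_window_bp) next
        ok <- !is.na(ds$geno[, i]) & !is.na(ds$geno[, j])
        if (sum(ok) < 2) next
        if (stats::sd(ds$geno[ok, i]) == 0 ||
              stats::sd(ds$geno[ok, j]) == 0) next
        r2 <- stats::cor(ds$geno[ok, i], ds$geno[ok, j])^2
        if (r2 >= cfg$clump_r2_max) {
          if (mafs[j] < mafs[i] ||
                isTRUE(all.equal(mafs[i], mafs[j]))) alive[j] <- FALSE
          else alive[i] <- FALSE
          dropped <- TRUE
          break
        }
      }
      if (dropped) break
    }
    if (!dropped) break
  }
  ds$map$id[alive]
}

# windowless brute-force ROH scanner: every window evaluated by direct
# counting, runs walked with plain loops, segments found by exhaustive
# search for the longest homozygous-bounded sub-interval within the
# heterozygote allowance
roh_oracle_chrom <- function(geno, pos, L, t, params) {
  m <- length(geno)
  segs <- list()
  if (m >= L) {
    qual <- logical(m - L + 1)
    for (w in seq_len(m - L + 1)) {
      win <- geno[w:(w + L - 1)]
      qual[w] <- sum(win == 1, na.rm = TRUE) <= params$max_het_in_window &&
        sum(is.na(win)) <= params$max_missing_in_window
    }
    in_roh <- logical(m)
    for (i in seq_len(m)) {
      ws <- max(1, i - L + 1):min(m - L + 1, i)
      in_roh[i] <- mean(qual[ws]) >= t
    }
    hcount <- cumsum(!is.na(geno) & geno == 1)
    is_hom <- function(v) !is.na(geno[v]) && geno[v] != 1
    i <- 1
    while (i <= m) {
      if (!in_roh[i]) { i <- i + 1; next }
      j <- i
      while (j < m && in_roh[j + 1]) j <- j + 1
      piece_start <- i
      for (k in i:j) {
        end_piece <- k == j || (pos[k + 1] - pos[k]) > params$max_gap_bp
        if (end_piece) {
          best <- c(0, 0)
          for (a in piece_start:k) {
            if (!is_hom(a)) next
            for (b in k:a) {
              if (b - a + 1 <= best[2] - best[1] + 1 && best[2] > 0) break
              if (!is_hom(b)) next
              nh <- hcount[b] - hcount[a]
              if (nh <= params$max_het_in_segment) {
                best <- c(a, b)
                break
              }
            }
          }
          if (best[2] > 0) {
            idx <- best[1]:best[2]
            len <- pos[best[2]] - pos[best[1]]
            if (length(idx) >= L &&
                  len >= params$min_len_bp &&
                  len / length(idx) <= params$min_density_bp_per_snp)
              segs[[length(segs) + 1]] <-
                c(start = pos[best[1]], end = pos[best[2]], n = length(idx))
          }
          piece_start <- k + 1
        }
      }
      i <- j + 1
    }
  }
  if (!length(segs)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, segs)
}

# random blocky genotype fixture for the ROH oracle comparisons
roh_random_fixture <- function() {
  m <- sample(80:400, 1)
  pos <- sort(sample.int(4e6, m))
  geno <- integer(m)
  i <- 1
  while (i <= m) {
    k <- min(sample(10:120, 1), m - i + 1)
    geno[i:(i + k - 1)] <- if (stats::runif(1) < 0.5)
      stats::rbinom(k, 1, 0.05) * 2L else stats::rbinom(k, 2, 0.5)
    i <- i + k
  }
  geno[sample(m, round(0.03 * m))] <- NA
  L <- sample(10:40, 1)
  list(geno = geno, pos = pos, L = L, t = floor(1000 / L) / 1000,
       params = roh_params(min_len_bp = sample(c(1e5, 2e5, 4e5), 1),
                           max_gap_bp = sample(c(5e5, 1e6), 1)))
}

# one-sided hypergeometric tail by direct summation of binomial coefficients
hyper_tail_oracle <- function(k_c, k_u, n_u, n_c) {
  ks <- k_c:min(k_u, n_c)
  sum(exp(lchoose(k_u, ks) + lchoose(n_u - k_u, n_c - ks) -
            lchoose(n_u, n_c)))
}

# expected allele count over all C(6, g) exhaustive subsamples
ar_oracle_2n6 <- function(ca, g = 4) {
  copies <- c(rep(1, ca), rep(0, 6 - ca))
  subs <- utils::combn(6, g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}
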