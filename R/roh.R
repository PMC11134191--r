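#' ROH calling parameters
#'
#' Sliding-window parameters follow the standardized array protocol: the
#' window/segment SNP count L is derived from the panel so that the expected
#' number of false-positive ROH is alpha, and the per-SNP window-hit
#' threshold t is (N_out + 1)/L truncated to three decimals.
#'
#' @param alpha tolerated expected count of false-positive ROH (0.05).
#' @param n_out desired outer SNPs on either side of a segment (0).
#' @param max_het_in_window,max_het_in_segment heterozygote allowance (1).
#' @param max_missing_in_window missing-call allowance per window (5).
#' @param min_len_bp minimum segment length (200 kb).
#' @param min_density_bp_per_snp at least one SNP per this many bp (50 kb).
#' @param max_gap_bp maximum interval between consecutive segment SNPs (1 Mb).
#' @param L,t explicit overrides; when NULL they are computed per population
#'   with [compute_window_params()].
#' @return a `roh_params` list.
#' @export
roh_params <- function(alpha = 0.05, n_out = 0, max_het_in_window = 1,
                       max_het_in_segment = 1, max_missing_in_window = 5,
                       min_len_bp = 200000, min_density_bp_per_snp = 50000,
                       max_gap_bp = 1000000, L = NULL, t = NULL) {
  structure(as.list(environment()), class = "roh_params")
}

#' Population-specific window size and hit threshold
#'
#' L = ceiling( ln(alpha / (n_s * n_i)) / ln(1 - mean_het) ), where n_s is
#' the number of genotyped SNPs, n_i the number of genotyped individuals and
#' mean_het the mean heterozygosity across all SNPs; rounding is upward
#' (longer windows are conservative). t = (n_out + 1)/L truncated to three
#' decimals.
#'
#' @param n_s number of SNPs.
#' @param n_i number of individuals.
#' @param mean_het mean per-SNP heterozygosity, in (0, 1).
#' @param alpha false-positive allowance.
#' @param n_out outer-SNP count.
#' @return list(L, t).
#' @export
compute_window_params <- function(n_s, n_i, mean_het, alpha = 0.05,
                                  n_out = 0) {
  stopifnot(n_s >= 1, n_i >= 1)
  if (mean_het <= 0 || mean_het >= 1)
    stop("mean heterozygosity must be in (0, 1)")
  L <- ceiling(log(alpha / (n_s * n_i)) / log(1 - mean_het))
  L <- max(L, 1)
  t <- floor(1000 * (n_out + 1) / L) / 1000
  list(L = as.integer(L), t = t)
}

# sliding-window ROH scan for one individual on one chromosome.
# geno: dosage vector; pos: positions. Returns segments data.frame.
roh_scan_chrom <- function(geno, pos, L, t, params) {
  m <- length(geno)
  if (m < L) return(empty_segments())
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  # window qualification via running sums
  ch <- cumsum(c(0, het)); cm <- cumsum(c(0, mis))
  nw <- m - L + 1
  whet <- ch[(L + 1):(m + 1)] - ch[1:nw]
  wmis <- cm[(L + 1):(m + 1)] - cm[1:nw]
  wok <- whet <= params$max_het_in_window & wmis <= params$max_missing_in_window
  # per-SNP hit fraction: windows [max(1, i-L+1) .. min(nw, i)] cover SNP i
  cwk <- cumsum(c(0, as.numeric(wok)))
  lo <- pmax(1, seq_len(m) - L + 1); hi <- pmin(nw, seq_len(m))
  nwin <- hi - lo + 1
  nhit <- cwk[hi + 1] - cwk[lo]
  in_roh <- nhit / nwin >= t
  # maximal runs of in-ROH SNPs
  r <- rle(in_roh)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  segs <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split at large inter-SNP gaps
    gaps <- which(diff(pos[idx]) > params$max_gap_bp)
    pieces <- split(idx, cumsum(seq_along(idx) %in% (gaps + 1)))
    for (pc in pieces) {
      # the called segment is the longest sub-run within the heterozygote
      # allowance, starting and ending with a homozygous call (the window
      # threshold can mark a few flanking non-homozygous SNPs)
      pc <- best_subrun(pc, het, mis, params$max_het_in_segment)
      if (length(pc) < L) next                       # segment-level L minimum
      len <- pos[pc[length(pc)]] - pos[pc[1]]
      if (len < params$min_len_bp) next
      if (len / length(pc) > params$min_density_bp_per_snp) next
      segs[[length(segs) + 1]] <- data.frame(
        start_bp = pos[pc[1]], end_bp = pos[pc[length(pc)]],
        n_snps = length(pc), length_bp = len)
    }
  }
  if (!length(segs)) return(empty_segments())
  do.call(rbind, segs)
}

# longest contiguous sub-run of pc with at most `allow` heterozygous calls,
# trimmed so both ends are homozygous non-missing calls; ties -> leftmost
best_subrun <- function(pc, het, mis, allow) {
  h <- which(het[pc])
  bounds <- c(0, h, length(pc) + 1)
  best <- integer(0)
  n_h <- length(h)
  for (i in 0:max(0, n_h - allow)) {
    lo <- bounds[i + 1] + 1
    hi <- bounds[min(i + allow + 1, length(bounds) - 1) + 1] - 1
    if (i + allow >= n_h) hi <- length(pc)
    if (lo > hi) next
    sub <- pc[lo:hi]
    while (length(sub) && (het[sub[1]] || mis[sub[1]])) sub <- sub[-1]
    while (length(sub) && (het[sub[length(sub)]] || mis[sub[length(sub)]]))
      sub <- sub[-length(sub)]
    if (length(sub) > length(best)) best <- sub
  }
  best
}

empty_segments <- function() {
  data.frame(start_bp = integer(0), end_bp = integer(0),
             n_snps = integer(0), length_bp = integer(0))
}

roh_length_class <- function(len_bp) {
  cut(len_bp / 1e6, breaks = c(0.2, 0.5, 1, 2, 4, 8),
      labels = c("0.2-0.5Mb", "0.5-1Mb", "1-2Mb", "2-4Mb", "4-8Mb"),
      right = FALSE)
}

#' Call runs of homozygosity for one population
#'
#' Applies the per-population sample/marker QC (individual call rate > 0.9,
#' near-duplicate removal at PI_HAT > 0.95, marker call rate >= 0.95,
#' minimum population size), derives L and t from the retained panel, then
#' runs the sliding-window scan per individual and chromosome. Candidate
#' runs are split at over-large gaps and must satisfy the segment-level SNP
#' count, heterozygote, length and density rules.
#'
#' @param ds a `geno_ds`.
#' @param pop population label.
#' @param params a [roh_params()].
#' @param qc apply the sample/marker QC (disable for constructed fixtures).
#' @param min_pop_size smallest analyzable population (default 15; ignored
#'   when `qc = FALSE`).
#' @return data.frame of segments: sample, pop, chrom, start_bp, end_bp,
#'   n_snps, length_bp, length_class; attribute `"params"` carries L and t.
#' @export
call_roh <- function(ds, pop, params = roh_params(), qc = TRUE,
                     min_pop_size = 15) {
  si <- pop_samples(ds, pop)
  g <- ds$geno[si, , drop = FALSE]
  ids <- ds$sample_ids[si]
  if (qc) {
    cr <- rowMeans(!is.na(g))
    keep <- cr > 0.90
    g <- g[keep, , drop = FALSE]; ids <- ids[keep]
    if (nrow(g) >= 2) {
      dup <- duplicate_samples(g)
      if (length(dup)) { g <- g[-dup, , drop = FALSE]; ids <- ids[-dup] }
    }
    mk <- colMeans(!is.na(g)) >= 0.95
    g <- g[, mk, drop = FALSE]
    map <- ds$map[mk, , drop = FALSE]
    if (nrow(g) <= min_pop_size) {
      warning("population ", pop, " below size cutoff after QC; skipped")
      return(cbind(sample = character(0), pop = character(0),
                   chrom = character(0), empty_segments()))
    }
  } else map <- ds$map

  if (is.null(params$L) || is.null(params$t)) {
    nn <- colSums(!is.na(g))
    mean_het <- mean(colSums(g == 1, na.rm = TRUE)[nn > 0] / nn[nn > 0])
    wp <- compute_window_params(ncol(g), nrow(g), mean_het,
                                params$alpha, params$n_out)
  } else wp <- list(L = params$L, t = params$t)

  chroms <- split(seq_len(nrow(map)), map$chrom)
  segs <- list()
  for (i in seq_len(nrow(g))) for (ch in names(chroms)) {
    cols <- chroms[[ch]]
    s <- roh_scan_chrom(g[i, cols], map$pos[cols], wp$L, wp$t, params)
    if (nrow(s))
      segs[[length(segs) + 1]] <- cbind(sample = ids[i], pop = pop,
                                        chrom = ch, s)
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    cbind(sample = character(0), pop = character(0), chrom = character(0),
          empty_segments())
  out$length_class <- roh_length_class(out$length_bp)
  attr(out, "params") <- wp
  out
}

# PLINK-style method-of-moments PI_HAT on a marker subset; returns indices
# of samples to drop so that no retained pair exceeds the threshold
duplicate_samples <- function(g, threshold = 0.95, n_snps = 5000) {
  cols <- which(colSums(!is.na(g)) == nrow(g))
  if (length(cols) > n_snps) cols <- sort(sample(cols, n_snps))
  if (length(cols) < 50) return(integer(0))
  gg <- g[, cols, drop = FALSE]
  p <- colMeans(gg) / 2
  poly <- p > 0 & p < 1
  gg <- gg[, poly, drop = FALSE]; p <- p[poly]
  if (!ncol(gg)) return(integer(0))
  q <- 1 - p
  e0_ibs0 <- sum(2 * p^2 * q^2)
  e0_ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
  e0_ibs2 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibs1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e1_ibs2 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  n <- nrow(gg)
  drop <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (i %in% drop || j %in% drop) next
    diffs <- abs(gg[i, ] - gg[j, ])
    ibs0 <- sum(diffs == 2); ibs1 <- sum(diffs == 1)
    ibs2 <- ncol(gg) - ibs0 - ibs1
    z0 <- min(max(ibs0 / e0_ibs0, 0), 1)
    z1 <- min(max((ibs1 - z0 * e0_ibs1) / e1_ibs1, 0), 1 - z0)
    z2 <- max(0, min(1 - z0 - z1,
                     (ibs2 - z0 * e0_ibs2 - z1 * e1_ibs2) / ncol(gg)))
    pihat <- z1 / 2 + z2
    if (pihat > threshold) drop <- c(drop, j)
  }
  drop
}

#' Total assayable length from a simulated homozygote
#'
#' Creates a single fully homozygous individual on the same marker map and
#' re-runs the segment caller with the same parameters; the summed segment
#' length is the maximal detectable ROH length L_TOTAL.
#'
#' @param map marker map data.frame.
#' @param L,t window parameters used for the real calls.
#' @param params a [roh_params()].
#' @return total length in bp.
#' @export
roh_l_total <- function(map, L, t, params = roh_params()) {
  chroms <- split(seq_len(nrow(map)), map$chrom)
  tot <- 0
  for (cols in chroms) {
    s <- roh_scan_chrom(rep(0L, length(cols)), map$pos[cols], L, t, params)
    tot <- tot + sum(s$length_bp)
  }
  tot
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH = sum of qualifying ROH lengths / L_TOTAL, with segments restricted
#' to a minimum length (1 Mb by default, limiting false positives from
#' short runs).
#'
#' @param segments data.frame from [call_roh()] (possibly several
#'   populations row-bound), with a `sample` column.
#' @param samples character vector of all analyzed samples (so zero-ROH
#'   individuals appear with F_ROH = 0).
#' @param l_total_bp L_TOTAL from [roh_l_total()].
#' @param min_len_bp minimum qualifying segment length.
#' @return data.frame: sample, sum_roh_bp, f_roh.
#' @export
froh <- function(segments, samples, l_total_bp, min_len_bp = 1e6) {
  if (l_total_bp <= 0) stop("l_total_bp must be positive")
  s <- segments[segments$length_bp >= min_len_bp, , drop = FALSE]
  sums <- tapply(s$length_bp, factor(s$sample, levels = samples), sum)
  sums[is.na(sums)] <- 0
  data.frame(sample = samples, sum_roh_bp = as.numeric(sums),
             f_roh = as.numeric(sums) / l_total_bp,
             stringsAsFactors = FALSE)
}

#' Per-marker ROH incidence and island calls
#'
#' @param segments data.frame from [call_roh()].
#' @param map marker map.
#' @param n_individuals number of individuals analyzed.
#' @param island_quantile incidence quantile above which contiguous runs
#'   are reported as ROH islands.
#' @return list: `incidence` (data.frame id, chrom, pos, incidence) and
#'   `islands` (data.frame chrom, start_bp, end_bp, peak_incidence).
#' @export
roh_incidence <- function(segments, map, n_individuals,
                          island_quantile = 0.99) {
  cov <- numeric(nrow(map))
  for (k in seq_len(nrow(segments))) {
    hit <- map$chrom == segments$chrom[k] &
      map$pos >= segments$start_bp[k] & map$pos <= segments$end_bp[k]
    cov <- cov + hit
  }
  inc <- cov / max(n_individuals, 1)
  thr <- stats::quantile(inc, island_quantile)
  isl <- list()
  if (thr > 0) {
    for (cols in split(seq_len(nrow(map)), map$chrom)) {
      r <- rle(inc[cols] >= thr & inc[cols] > 0)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        idx <- cols[starts[k]:ends[k]]
        isl[[length(isl) + 1]] <- data.frame(
          chrom = map$chrom[idx[1]], start_bp = map$pos[idx[1]],
          end_bp = map$pos[idx[length(idx)]],
          peak_incidence = max(inc[idx]))
      }
    }
  }
  list(incidence = data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                              incidence = inc),
       islands = if (length(isl)) do.call(rbind, isl) else
         data.frame(chrom = character(0), start_bp = integer(0),
                    end_bp = integer(0), peak_incidence = numeric(0)))
}
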