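#' Genome-scan configuration
#'
#' @param hmin minimum pooled expected heterozygosity for a locus to enter
#'   the FST-scan fit and testing (0.1).
#' @param q_threshold q-value cutoff declaring an outlier (0.05).
#' @param trim_fraction fraction trimmed from each tail of the neutral FST
#'   distribution before the chi-square fit (0.05).
#' @param K number of principal components for the PC-based scan; `NULL`
#'   chooses the largest eigenvalue gap among the first 10.
#' @param qvalue_method multiple-testing method passed to
#'   [stats::p.adjust()] (`"BH"`).
#' @return a `scan_config` list.
#' @export
scan_config <- function(hmin = 0.1, q_threshold = 0.05,
                        trim_fraction = 0.05, K = NULL,
                        qvalue_method = "BH") {
  stopifnot(trim_fraction > 0, trim_fraction < 0.5)
  structure(as.list(environment()), class = "scan_config")
}

#' FST-based outlier scan (trimmed chi-square null)
#'
#' The wild and selected classes are pooled into two demes. Per-locus
#' uncorrected FST ratios on the neutral-parameterization (clumped) marker
#' set, restricted to loci with pooled expected heterozygosity >= hmin, are
#' symmetrically trimmed and a scaled chi-square null
#' (FST * df / FSTbar ~ chi-square(df)) is fitted by maximum likelihood on
#' the truncated sample. Right-tail p-values are then assigned to every
#' full-set locus with He >= hmin, with q-values by Benjamini-Hochberg.
#'
#' @param full_ds full marker dataset (`geno_ds` with both classes).
#' @param neutral_ids marker ids of the clumped (neutral-parameterization)
#'   subset; must be a subset of `full_ds` markers.
#' @param cfg a [scan_config()].
#' @return data.frame: id, theta_nocorr, he, fst_p, fst_q, outlier_fst;
#'   attributes `"fstbar"` and `"df"` carry the fitted null.
#' @export
fst_outlier_scan <- function(full_ds, neutral_ids, cfg = scan_config()) {
  cls <- ds_class_factor(full_ds)
  comp <- wc_components(full_ds$geno, cls)
  x_all <- comp$theta_nocorr
  he_all <- comp$he
  nid <- match(neutral_ids, full_ds$map$id)
  if (anyNA(nid)) stop("neutral markers not all present in full dataset")
  x_neut <- x_all[nid]; he_neut <- he_all[nid]
  use <- !is.na(x_neut) & he_neut >= cfg$hmin
  fit <- fit_trimmed_chisq(x_neut[use], cfg$trim_fraction)
  testable <- !is.na(x_all) & he_all >= cfg$hmin
  p <- rep(NA_real_, length(x_all))
  p[testable] <- stats::pchisq(x_all[testable] * fit$df / fit$fstbar,
                               fit$df, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[testable] <- stats::p.adjust(p[testable], method = cfg$qvalue_method)
  out <- data.frame(id = full_ds$map$id, theta_nocorr = x_all, he = he_all,
                    fst_p = p, fst_q = q,
                    outlier_fst = !is.na(q) & q < cfg$q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "fstbar") <- fit$fstbar
  attr(out, "df") <- fit$df
  out
}

ds_class_factor <- function(ds) {
  cls <- ds$pop_class[ds$pop]
  if (length(unique(cls)) < 2)
    stop("need both wild and selected samples for the two-group contrast")
  factor(cls, levels = c("wild", "selected"))
}

# ML fit of x ~ fstbar * chisq(df)/df on a symmetrically trimmed sample,
# with the likelihood truncated to the trimming interval
fit_trimmed_chisq <- function(x, trim) {
  x <- sort(x[is.finite(x) & x > 0])
  if (length(x) < 20) stop("too few loci for the trimmed chi-square fit")
  lo <- stats::quantile(x, trim); hi <- stats::quantile(x, 1 - trim)
  xt <- x[x >= lo & x <= hi]
  nll <- function(par) {
    fb <- exp(par[1]); df <- exp(par[2])
    sc <- df / fb
    denom <- stats::pchisq(hi * sc, df) - stats::pchisq(lo * sc, df)
    if (!is.finite(denom) || denom <= 0) return(1e10)
    -sum(stats::dchisq(xt * sc, df, log = TRUE) + log(sc)) +
      length(xt) * log(denom)
  }
  init <- c(log(mean(xt)), log(2))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  if (opt$convergence != 0)
    stop("trimmed chi-square fit did not converge; trimmed n = ",
         length(xt), ", mean = ", format(mean(xt)))
  list(fstbar = exp(opt$par[1]), df = exp(opt$par[2]))
}

#' PC-based outlier scan (robust Mahalanobis on regression z-scores)
#'
#' Principal components are computed on the mean-imputed, frequency-scaled
#' clumped matrix. Every full-set marker's scaled dosage vector is regressed
#' on the K component score vectors, giving K z-scores per marker; the
#' robust Mahalanobis distance of the z-vectors, rescaled by the genomic
#' inflation factor (median distance over the chi-square(K) median), yields
#' chi-square(K) p-values and Benjamini-Hochberg q-values.
#'
#' @inheritParams fst_outlier_scan
#' @return data.frame: id, mahalanobis_d2, pc_p, pc_q, outlier_pc;
#'   attributes `"K"` and `"gif"`.
#' @export
pc_outlier_scan <- function(full_ds, neutral_ids, cfg = scan_config()) {
  nid <- match(neutral_ids, full_ds$map$id)
  if (anyNA(nid)) stop("neutral markers not all present in full dataset")
  Xc <- scaled_imputed_matrix(full_ds, nid)
  n <- nrow(Xc)
  kmax <- min(10, n - 1, ncol(Xc) - 1)
  sv <- svd(Xc, nu = kmax, nv = 0)
  K <- cfg$K %||% pick_k_eigengap(sv$d[seq_len(kmax)])
  if (K > kmax) stop("K exceeds available components")
  U <- sv$u[, seq_len(K), drop = FALSE]      # orthonormal score directions
  Y <- scaled_imputed_matrix(full_ds)
  B <- crossprod(U, Y)                        # K x M regression coefficients
  rss <- pmax(colSums(Y^2) - colSums(B^2), 1e-12)
  sigma <- sqrt(rss / pmax(n - K, 1))
  Z <- t(B) / sigma                           # M x K z-scores
  rc <- MASS::cov.rob(Z)
  d2 <- stats::mahalanobis(Z, rc$center, rc$cov)
  gif <- stats::median(d2) / stats::qchisq(0.5, K)
  p <- stats::pchisq(d2 / gif, K, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = cfg$qvalue_method)
  out <- data.frame(id = full_ds$map$id, mahalanobis_d2 = d2, pc_p = p,
                    pc_q = q, outlier_pc = q < cfg$q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "K") <- K
  attr(out, "gif") <- gif
  out
}

# choose K at the largest log-scale eigenvalue gap among the leading
# components (the relative gap is scale-free, so a dominant first axis does
# not mask structure on later axes)
pick_k_eigengap <- function(d) {
  ev <- log(d^2)
  if (length(ev) < 2) return(1L)
  gaps <- ev[-length(ev)] - ev[-1]
  as.integer(which.max(gaps))
}

#' Combine both scans and deduplicate the union
#'
#' @param fst_scan result of [fst_outlier_scan()].
#' @param pc_scan result of [pc_outlier_scan()].
#' @return list: `table` (merged per-marker data.frame with an
#'   `outlier_union` flag, stable marker order), `union_ids`, and counts
#'   n_fst, n_pc, n_shared, n_union.
#' @export
union_outliers <- function(fst_scan, pc_scan) {
  stopifnot(identical(fst_scan$id, pc_scan$id))
  tab <- cbind(fst_scan, pc_scan[, setdiff(names(pc_scan), "id")])
  tab$outlier_union <- tab$outlier_fst | tab$outlier_pc
  n_fst <- sum(tab$outlier_fst, na.rm = TRUE)
  n_pc <- sum(tab$outlier_pc, na.rm = TRUE)
  n_shared <- sum(tab$outlier_fst & tab$outlier_pc, na.rm = TRUE)
  list(table = tab, union_ids = tab$id[which(tab$outlier_union)],
       n_fst = n_fst, n_pc = n_pc, n_shared = n_shared,
       n_union = n_fst + n_pc - n_shared)
}

#' Candidate markers for panel distillation
#'
#' The union outliers, extended (when the union is smaller than `min_n`)
#' with the top-ranked remaining markers by the smaller of the two scan
#' q-values. The backward-purging step needs a candidate list of workable
#' size even when few loci clear the outlier threshold on a small panel;
#' the scans' outlier calls themselves are not altered.
#'
#' @param u result of [union_outliers()].
#' @param min_n minimum candidate-list size (20).
#' @return character vector of marker ids.
#' @export
scan_candidates <- function(u, min_n = 20) {
  ids <- u$union_ids
  if (length(ids) >= min_n) return(ids)
  qmin <- pmin(u$table$fst_q, u$table$pc_q, na.rm = TRUE)
  extra <- u$table$id[order(qmin)]
  extra <- setdiff(extra, ids)
  c(ids, extra[seq_len(min_n - length(ids))])
}

#' Build the clumped-neutral marker set
#'
#' Removes every union outlier from the full set and re-clumps the
#' remainder.
#'
#' @param full_ds full `geno_ds`.
#' @param union_ids outlier marker ids.
#' @param cfg a [filter_config()] for the re-clumping.
#' @return a `geno_ds`.
#' @export
make_clumped_neutral <- function(full_ds, union_ids,
                                 cfg = filter_config()) {
  keep <- !(full_ds$map$id %in% union_ids)
  if (!any(keep)) stop("all markers are outliers; empty neutral set")
  ld_clump(subset_geno(full_ds, markers = keep), cfg)
}
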