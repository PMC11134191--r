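#' Hypergeometric term enrichment of outlier markers
#'
#' A marker carries a term when any of its annotated genes carries it. For
#' each term, the one-sided hypergeometric p-value asks whether the term is
#' overrepresented among the candidate markers relative to the annotated
#' universe; q-values are Benjamini-Hochberg.
#'
#' @param candidates candidate marker ids.
#' @param universe universe marker ids (candidates must be a subset).
#' @param annotations list from [read_annotation()].
#' @param fdr flag threshold (0.1).
#' @return data.frame: term_id, n_candidate_in_term, n_candidate,
#'   n_universe_in_term, n_universe, p_hypergeom, fdr_q, enriched.
#' @export
enrich <- function(candidates, universe, annotations, fdr = 0.1) {
  if (!length(universe)) stop("empty universe")
  if (!all(candidates %in% universe))
    stop("candidates must be a subset of the universe")
  mg <- annotations$marker_gene
  gt <- annotations$gene_term
  m2t <- merge(mg, gt, by = "gene_id")
  m2t <- m2t[m2t$marker_id %in% universe, c("marker_id", "term_id")]
  m2t <- unique(m2t)
  terms <- unique(m2t$term_id)
  n_u <- length(universe)
  n_c <- length(candidates)
  rows <- lapply(terms, function(tm) {
    in_term <- unique(m2t$marker_id[m2t$term_id == tm])
    k_u <- length(in_term)
    k_c <- sum(candidates %in% in_term)
    p <- stats::phyper(k_c - 1, k_u, n_u - k_u, n_c, lower.tail = FALSE)
    data.frame(term_id = tm, n_candidate_in_term = k_c, n_candidate = n_c,
               n_universe_in_term = k_u, n_universe = n_u,
               p_hypergeom = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_hypergeom), ]
  out$fdr_q <- stats::p.adjust(out$p_hypergeom, method = "BH")
  out$enriched <- out$fdr_q < fdr
  rownames(out) <- NULL
  out
}

#' Per-population 95% PCA ellipse areas
#'
#' Scores on the first two principal components of the mean-imputed,
#' frequency-scaled matrix; per population the 2x2 score covariance gives
#' semi-axes A, B = sqrt(eigenvalue x chi-square_2(0.95)) and area pi*A*B.
#' Standardized area is the z-score of areas across populations.
#'
#' @param ds a `geno_ds` (typically the clumped-neutral set).
#' @param min_samples populations below this size are skipped with a
#'   warning (3).
#' @return data.frame: pop, class, A, B, area, standardized_area.
#' @export
pca_ellipses <- function(ds, min_samples = 3) {
  X <- scaled_imputed_matrix(ds)
  sv <- svd(X, nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2])
  chi2 <- stats::qchisq(0.95, df = 2)
  pops <- unique(ds$pop)
  rows <- list()
  for (p in pops) {
    si <- pop_samples(ds, p)
    if (length(si) < min_samples) {
      warning("population ", p, " has < ", min_samples, " samples; skipped")
      next
    }
    cv <- stats::cov(scores[si, , drop = FALSE])
    ev <- sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    A <- sqrt(ev[1] * chi2); B <- sqrt(ev[2] * chi2)
    rows[[length(rows) + 1]] <- data.frame(
      pop = p, class = unname(ds$pop_class[p]), A = A, B = B,
      area = pi * A * B, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$standardized_area <- as.numeric(scale(out$area))
  out
}

#' Shannon-Wiener admixture index per population
#'
#' H = -sum(qbar_k log qbar_k) over the population-mean admixture
#' proportions; 0 for a single-cluster population, log(K) for uniform
#' admixture.
#'
#' @param q Q matrix (samples x K) from [read_qmatrix()].
#' @param pop population label per Q row.
#' @param per_individual when TRUE, average the per-individual indices
#'   instead of using the mean-Q row.
#' @return data.frame: pop, shannon_H.
#' @export
shannon_admixture <- function(q, pop, per_individual = FALSE) {
  hfun <- function(v) {
    v <- v[v > 0]
    -sum(v * log(v))
  }
  pops <- unique(pop)
  H <- vapply(pops, function(p) {
    rows <- q[pop == p, , drop = FALSE]
    if (per_individual) mean(apply(rows, 1, hfun)) else hfun(colMeans(rows))
  }, numeric(1))
  data.frame(pop = pops, shannon_H = H, stringsAsFactors = FALSE)
}

#' Two-way ANOVA of standardized ellipse area
#'
#' Sequential-F linear model standardized_area ~ admixture + relatedness,
#' optionally with the interaction.
#'
#' @param records data.frame with columns standardized_area, shannon_H,
#'   relatedness (one row per population).
#' @param interaction fit the interaction term too.
#' @return the `anova` table.
#' @export
ellipse_anova <- function(records, interaction = FALSE) {
  if (nrow(records) < 6) stop("need >= 6 populations")
  if (abs(stats::cor(records$shannon_H, records$relatedness)) > 0.99)
    stop("admixture and relatedness are collinear")
  f <- if (interaction)
    standardized_area ~ shannon_H * relatedness else
      standardized_area ~ shannon_H + relatedness
  stats::anova(stats::lm(f, data = records))
}

#' Consolidated report tables
#'
#' Combines the per-population diversity, relatedness and Ne tables into a
#' single summary with per-class group means, plus the pairwise-FST group
#' summary; written as TSVs when `out_dir` is given.
#'
#' @param diversity_tab result of [diversity()].
#' @param relatedness_tab data.frame pop, relatedness_mean, relatedness_sd.
#' @param ne_tab result of [estimate_ne_all()].
#' @param fst pairwise FST matrix.
#' @param pop_class named class vector.
#' @param out_dir optional output directory.
#' @return list: `summary` (per-population table), `group_means`,
#'   `fst_groups`.
#' @export
report_tables <- function(diversity_tab, relatedness_tab, ne_tab, fst,
                          pop_class, out_dir = NULL) {
  s <- merge(diversity_tab, relatedness_tab, by = "pop")
  s <- merge(s, ne_tab[, c("pop", "Ne_hat", "CI_low", "CI_high")], by = "pop")
  s <- s[order(s$class, s$pop), ]
  gm <- do.call(rbind, lapply(split(s, s$class), function(d) {
    data.frame(class = d$class[1], N = mean(d$N), Ar = mean(d$Ar),
               Ho = mean(d$Ho), He = mean(d$He),
               relatedness = mean(d$relatedness_mean),
               Ne = mean(d$Ne_hat[is.finite(d$Ne_hat)]))
  }))
  fg <- fst_group_means(fst, pop_class)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(s, file.path(out_dir, "population_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gm, file.path(out_dir, "group_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fg, file.path(out_dir, "fst_group_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(fst),
                       file.path(out_dir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
  }
  list(summary = s, group_means = gm, fst_groups = fg)
}
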