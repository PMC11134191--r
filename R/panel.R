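#' Random-Forest panel configuration
#'
#' @param ntree_max largest forest size scanned (OOB error is read off one
#'   cumulative run, so the whole 1..ntree_max range is evaluated).
#' @param top_fractions importance-ranking fractions screened in the first
#'   purging step.
#' @param n_purge_replicates replicate forests averaged per purging
#'   iteration (3).
#' @param seed integer seed.
#' @return an `rf_config` list.
#' @export
rf_config <- function(ntree_max = 1000,
                      top_fractions = c(0.01, 0.02, 0.05, 0.10, 0.20, 0.30),
                      n_purge_replicates = 3, seed = 1) {
  stopifnot(ntree_max >= 1, all(top_fractions > 0), all(top_fractions <= 1))
  structure(as.list(environment()), class = "rf_config")
}

#' mtry grid derived from the predictor count
#'
#' \{floor(sqrt(p)), 2*floor(sqrt(p)), floor(0.1 p), floor(0.2 p),
#' floor(p/3), p\}, deduplicated, restricted to [1, p].
#'
#' @param p number of predictors.
#' @return integer vector.
#' @export
mtry_grid <- function(p) {
  g <- c(floor(sqrt(p)), 2 * floor(sqrt(p)), floor(0.1 * p),
         floor(0.2 * p), floor(p / 3), p)
  sort(unique(pmin(pmax(g, 1), p)))
}

# mean-impute missing dosages within class (forests need complete columns)
impute_by_class <- function(X, y) {
  for (cl in levels(y)) {
    rows <- y == cl
    mu <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- colMeans(X, na.rm = TRUE)[is.nan(mu)]
    for (j in which(colSums(is.na(X[rows, , drop = FALSE])) > 0)) {
      miss <- rows & is.na(X[, j])
      X[miss, j] <- mu[j]
    }
  }
  X[is.na(X)] <- 0
  X
}

rf_run <- function(X, y, ntree, mtry, sampsize) {
  randomForest::randomForest(
    x = X, y = y, ntree = ntree, mtry = min(mtry, ncol(X)),
    strata = y, sampsize = sampsize,
    importance = TRUE)
}

#' Tune forest size and mtry by OOB error
#'
#' One cumulative forest run evaluates the OOB error rate over the whole
#' 1..ntree_max range at the default mtry; the chosen ntree is the first
#' value within one standard error of the minimum. The mtry grid from
#' [mtry_grid()] is then scanned at that ntree, again taking the first
#' value within one standard error of the minimum. Bootstrap samples are
#' stratified with per-class size equal to the smallest class count.
#'
#' @param X predictor matrix (samples x markers; missing values are
#'   mean-imputed within class).
#' @param y two-level class factor.
#' @param cfg an [rf_config()].
#' @return list: ntree, mtry, oob_by_ntree, oob_by_mtry.
#' @export
tune_forest <- function(X, y, cfg = rf_config()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes")
  X <- impute_by_class(as.matrix(X), y)
  sampsize <- rep(min(table(y)), nlevels(y))
  set.seed(cfg$seed)
  rf <- rf_run(X, y, cfg$ntree_max, floor(sqrt(ncol(X))), sampsize)
  oob <- rf$err.rate[, "OOB"]
  se <- sqrt(min(oob) * (1 - min(oob)) / length(y))
  ntree_star <- which(oob <= min(oob) + se)[1]
  grid <- mtry_grid(ncol(X))
  oob_m <- vapply(grid, function(m) {
    set.seed(derive_seed(cfg$seed, paste0("mtry", m)))
    rf_run(X, y, ntree_star, m, sampsize)$err.rate[ntree_star, "OOB"]
  }, numeric(1))
  se_m <- sqrt(min(oob_m) * (1 - min(oob_m)) / length(y))
  mtry_star <- grid[which(oob_m <= min(oob_m) + se_m)[1]]
  list(ntree = ntree_star, mtry = mtry_star,
       oob_by_ntree = oob, oob_by_mtry = stats::setNames(oob_m, grid))
}

#' Two-step backward purging of the outlier panel
#'
#' Step 1 ranks all candidates by permutation importance (mean decrease in
#' accuracy) and screens nested top-importance fractions by OOB error,
#' keeping one fraction above the minimizer as the conservative candidate
#' list. Step 2 iteratively removes the marker with the lowest importance
#' averaged over replicate forests until two remain, recording the mean OOB
#' error at each panel size; the final panel minimizes OOB error, with ties
#' going to the smaller panel.
#'
#' @inheritParams tune_forest
#' @param tuned optional result of [tune_forest()] (computed when NULL).
#' @return list: `panel` (marker names), `trace` (data.frame panel_size,
#'   oob_er), `candidates`, `tuned`, `oob_by_fraction`.
#' @export
backward_purge <- function(X, y, cfg = rf_config(), tuned = NULL) {
  y <- droplevels(as.factor(y))
  X <- impute_by_class(as.matrix(X), y)
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  if (ncol(X) < 3) stop("need >= 3 candidate markers to purge")
  if (is.null(tuned)) tuned <- tune_forest(X, y, cfg)
  sampsize <- rep(min(table(y)), nlevels(y))

  set.seed(derive_seed(cfg$seed, "rank"))
  rf0 <- rf_run(X, y, tuned$ntree, tuned$mtry, sampsize)
  imp <- randomForest::importance(rf0, type = 1)[, 1]
  ranked <- names(sort(imp, decreasing = TRUE))

  fr <- sort(unique(cfg$top_fractions))
  sizes <- unique(pmax(2, pmin(ncol(X), ceiling(fr * ncol(X)))))
  oob_f <- vapply(sizes, function(k) {
    sub <- X[, ranked[seq_len(k)], drop = FALSE]
    set.seed(derive_seed(cfg$seed, paste0("frac", k)))
    rf_run(sub, y, tuned$ntree, tuned$mtry, sampsize)$err.rate[tuned$ntree, "OOB"]
  }, numeric(1))
  best <- which.min(oob_f)
  cand_k <- sizes[min(best + 1, length(sizes))]  # one fraction above the min
  candidates <- ranked[seq_len(cand_k)]

  panel <- candidates
  trace <- data.frame(panel_size = integer(0), oob_er = numeric(0))
  panels_by_size <- list()
  while (length(panel) >= 2) {
    oobs <- numeric(cfg$n_purge_replicates)
    imps <- matrix(0, cfg$n_purge_replicates, length(panel))
    for (rpl in seq_len(cfg$n_purge_replicates)) {
      set.seed(derive_seed(cfg$seed, paste0("purge", length(panel), "_", rpl)))
      rf <- rf_run(X[, panel, drop = FALSE], y, tuned$ntree,
                   min(tuned$mtry, length(panel)), sampsize)
      oobs[rpl] <- rf$err.rate[tuned$ntree, "OOB"]
      imps[rpl, ] <- randomForest::importance(rf, type = 1)[panel, 1]
    }
    trace <- rbind(trace, data.frame(panel_size = length(panel),
                                     oob_er = mean(oobs)))
    panels_by_size[[as.character(length(panel))]] <- panel
    if (length(panel) == 2) break
    panel <- panel[-which.min(colMeans(imps))]
  }
  # smallest panel within one standard error of the minimum OOB error:
  # under replicate noise a plain arg-min absorbs chance-correlated
  # markers, so parsimony gets the same allowance as the tuning step
  mn <- min(trace$oob_er)
  se <- sqrt(mn * (1 - mn) / length(y))
  sel_size <- min(trace$panel_size[trace$oob_er <= mn + se])
  best_panel <- panels_by_size[[as.character(sel_size)]]
  list(panel = best_panel, trace = trace, candidates = candidates,
       tuned = tuned, oob_by_fraction = stats::setNames(oob_f, sizes))
}

#' DAPC-style confusion matrix on a marker panel
#'
#' Principal components explaining at least `var_explained` of the panel
#' genotype variance are retained and a linear discriminant is fitted on
#' the scores; classes are predicted by leave-one-out cross-validation.
#' A singular within-class covariance triggers a warning and a reduction
#' in retained components.
#'
#' @param X panel genotype matrix (samples x markers).
#' @param y class factor.
#' @param var_explained PC variance fraction retained (0.9).
#' @return list: `confusion` (actual x predicted), `accuracy`.
#' @export
dapc_confusion <- function(X, y, var_explained = 0.9) {
  y <- droplevels(as.factor(y))
  X <- impute_by_class(as.matrix(X), y)
  if (ncol(X) < 2) stop("panel needs >= 2 markers")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  npc <- max(1, which(cum >= var_explained)[1])
  npc <- min(npc, nrow(X) - nlevels(y) - 1)
  pred <- NULL
  while (npc >= 1) {
    S <- pc$x[, seq_len(npc), drop = FALSE]
    fit <- tryCatch(MASS::lda(S, grouping = y, CV = TRUE),
                    error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit$class)) { pred <- fit$class; break }
    warning("singular within-class covariance; reducing retained PCs to ",
            npc - 1)
    npc <- npc - 1
  }
  if (is.null(pred)) stop("LDA failed at every retained-PC count")
  cm <- table(actual = y, predicted = pred)
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm), n_pc = npc)
}
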