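#' Validate a pipeline configuration
#'
#' Fills every omitted knob with the pipeline defaults (MAF 0.05, call rate
#' 0.95, HWE 0.01 in half the populations, 10-kb/0.2 clumping, Hmin 0.1,
#' q 0.05, 5K markers for Ne, 500-kb/100-bin/30-individual LD decay, ROH
#' 200-kb/50-kb/1000-kb with 1 het and 5 missing, enrichment FDR 0.1) and
#' rejects unknown keys by name.
#'
#' @param config a named list (e.g. from [yaml::read_yaml()]) or a YAML
#'   file path; `NULL` yields the full default configuration.
#' @return validated config list with classes filled in.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  known <- c("seed", "filter", "scan", "rf", "roh", "ne", "lddecay",
             "enrich_fdr", "sim")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  merge_args <- function(fn, args) {
    ok <- names(args) %in% names(formals(fn))
    if (!all(ok)) stop("unknown config key: ", names(args)[!ok][1])
    do.call(fn, args)
  }
  list(seed = as.integer(config$seed %||% 1),
       filter = merge_args(filter_config, config$filter %||% list()),
       scan = merge_args(scan_config, config$scan %||% list()),
       rf = merge_args(rf_config, config$rf %||% list()),
       roh = merge_args(roh_params, config$roh %||% list()),
       ne = utils::modifyList(list(maf_min = 0.05, n_snps = 5000),
                              config$ne %||% list()),
       lddecay = utils::modifyList(
         list(max_dist = 500000, n_bins = 100, subsample = 30),
         config$lddecay %||% list()),
       enrich_fdr = config$enrich_fdr %||% 0.1,
       sim = config$sim %||% NULL)
}

#' Run the full analysis pipeline
#'
#' Chains QC -> clumping -> genome scans -> clumped-neutral construction ->
#' diversity/relatedness/FST -> Ne -> LD decay -> ROH/F_ROH -> RF panel ->
#' report, on a provided dataset or on a fresh simulation. Stage seeds are
#' derived deterministically from the global seed, so re-running with the
#' same config reproduces every output.
#'
#' @param ds a `geno_ds`; when `NULL` the demo simulation is used.
#' @param config configuration accepted by [validate_config()].
#' @param out_dir optional directory for report TSVs.
#' @param regions optional excluded-region data.frame.
#' @param stages character subset of stages to run (dependencies must be
#'   included; a missing dependency is a named error).
#' @return list of stage outputs.
#' @export
run_pipeline <- function(ds = NULL, config = NULL, out_dir = NULL,
                         regions = NULL,
                         stages = c("qc", "scan", "stats", "ne", "lddecay",
                                    "roh", "panel", "report")) {
  cfg <- validate_config(config)
  res <- list(config = cfg)
  if (is.null(ds)) {
    sim <- assemble_panel(demo_config(seed = cfg$seed))
    ds <- sim$ds
    res$truth <- sim$truth
  }
  res$input <- ds

  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stop("stage '", stage, "' requires stage '", dep, "'")
  }
  if ("qc" %in% stages) {
    flt <- apply_filters(ds, cfg$filter, regions)
    res$qc <- flt
    res$full <- flt$ds
    res$clumped <- ld_clump(flt$ds, cfg$filter)
  }
  if ("scan" %in% stages) {
    need("scan", "full")
    fs <- fst_outlier_scan(res$full, res$clumped$map$id, cfg$scan)
    ps <- pc_outlier_scan(res$full, res$clumped$map$id, cfg$scan)
    res$scan <- union_outliers(fs, ps)
    res$clumped_neutral <- make_clumped_neutral(res$full,
                                                res$scan$union_ids,
                                                cfg$filter)
  }
  if ("stats" %in% stages) {
    need("stats", "clumped_neutral")
    cn <- res$clumped_neutral
    res$diversity <- diversity(cn)
    res$relatedness <- do.call(rbind, lapply(unique(cn$pop), function(p) {
      r <- ritland_relatedness(cn, p)
      data.frame(pop = p, relatedness_mean = r$mean, relatedness_sd = r$sd)
    }))
    res$fst <- wc_fst(res$full)
  }
  if ("ne" %in% stages) {
    need("ne", "clumped_neutral")
    res$ne <- estimate_ne_all(res$clumped_neutral,
                              maf_min = cfg$ne$maf_min,
                              n_snps = cfg$ne$n_snps,
                              seed = derive_seed(cfg$seed, "ne"))
  }
  if ("lddecay" %in% stages) {
    need("lddecay", "full")
    res$lddecay <- ld_decay_table(res$full,
                                  max_dist = cfg$lddecay$max_dist,
                                  n_bins = cfg$lddecay$n_bins,
                                  subsample = cfg$lddecay$subsample,
                                  seed = derive_seed(cfg$seed, "lddecay"))
  }
  if ("roh" %in% stages) {
    need("roh", "full")
    segs <- list(); ids <- character(0); ltot <- c()
    for (p in unique(res$full$pop)) {
      s <- call_roh(res$full, p, cfg$roh, qc = TRUE)
      wp <- attr(s, "params")
      segs[[p]] <- s
      ids <- c(ids, unique(ds$sample_ids[pop_samples(res$full, p)]))
      if (!is.null(wp))
        ltot[p] <- roh_l_total(res$full$map, wp$L, wp$t, cfg$roh)
    }
    res$roh_segments <- do.call(rbind, segs)
    if (length(ltot))
      res$froh <- froh(res$roh_segments, ids, max(ltot))
  }
  if ("panel" %in% stages) {
    need("panel", "scan")
    uid <- scan_candidates(res$scan)
    if (length(uid) >= 3) {
      X <- res$full$geno[, match(uid, res$full$map$id), drop = FALSE]
      y <- factor(res$full$pop_class[res$full$pop])
      rfc <- cfg$rf; rfc$seed <- derive_seed(cfg$seed, "rf")
      res$panel <- backward_purge(X, y, rfc)
      res$dapc <- dapc_confusion(
        X[, res$panel$panel, drop = FALSE], y)
    }
  }
  if ("report" %in% stages) {
    need("report", "diversity")
    need("report", "ne")
    res$report <- report_tables(res$diversity, res$relatedness, res$ne,
                                res$fst, ds$pop_class, out_dir)
  }
  res
}
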