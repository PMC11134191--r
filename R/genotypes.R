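#' Genotype dataset container
#'
#' The central in-memory data model: a samples x markers matrix of alternate
#' allele dosages (0, 1, 2 or `NA` for a missing call) together with a marker
#' map, sample identifiers, a sample-to-population map and a population class
#' (wild or selected) per population.
#'
#' @param geno integer matrix (samples x markers) of dosages in \{0,1,2,NA\}.
#' @param sample_ids character vector of unique sample identifiers.
#' @param pop character vector, population label per sample.
#' @param pop_class named character vector mapping each population label to
#'   `"wild"` or `"selected"`.
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per marker, sorted by chromosome then position.
#'
#' @return An object of class `geno_ds`.
#' @export
geno_dataset <- function(geno, sample_ids, pop, pop_class, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(
    nrow(geno) == length(sample_ids),
    nrow(geno) == length(pop),
    ncol(geno) == nrow(map),
    !anyDuplicated(sample_ids)
  )
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (!all(pop %in% names(pop_class)))
    stop("populations without a class: ",
         paste(setdiff(unique(pop), names(pop_class)), collapse = ", "))
  if (!all(pop_class %in% c("wild", "selected")))
    stop("pop_class values must be 'wild' or 'selected'")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(map)))
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "G"
  # enforce sort by chrom then pos; unique positions per chrom
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    message("markers unsorted on input; sorting by chromosome and position")
    map <- map[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
  }
  if (anyDuplicated(map[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in marker map")
  rownames(map) <- NULL
  dimnames(geno) <- list(sample_ids, map$id)
  structure(
    list(geno = geno, sample_ids = sample_ids, pop = pop,
         pop_class = pop_class, map = map),
    class = "geno_ds"
  )
}

#' @export
print.geno_ds <- function(x, ...) {
  cat(sprintf("geno_ds: %d samples x %d markers, %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  tab <- table(x$pop)
  cls <- x$pop_class[names(tab)]
  cat(sprintf("  %d populations (%d wild, %d selected)\n",
              length(tab), sum(cls == "wild"), sum(cls == "selected")))
  cat(sprintf("  missingness: %.2f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.geno_ds <- function(x) dim(x$geno)

#' Number of markers / samples
#' @param ds a `geno_ds`.
#' @return integer count.
#' @export
n_markers <- function(ds) ncol(ds$geno)

#' @rdname n_markers
#' @export
n_samples <- function(ds) nrow(ds$geno)

#' Subset a genotype dataset
#'
#' @param ds a `geno_ds`.
#' @param samples logical/integer/character index over samples (optional).
#' @param markers logical/integer/character index over markers (optional).
#' @return a `geno_ds` restricted to the given samples and markers.
#' @export
subset_geno <- function(ds, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(ds$geno)) else samples
  if (is.character(si)) si <- match(si, ds$sample_ids)
  mi <- if (is.null(markers)) seq_len(ncol(ds$geno)) else markers
  if (is.character(mi)) mi <- match(mi, ds$map$id)
  geno_dataset(ds$geno[si, mi, drop = FALSE],
               ds$sample_ids[si], ds$pop[si],
               ds$pop_class, ds$map[mi, , drop = FALSE])
}

#' Samples belonging to a population or class
#' @param ds a `geno_ds`.
#' @param pop population label.
#' @return integer sample indices.
#' @export
pop_samples <- function(ds, pop) which(ds$pop %in% pop)

#' @rdname pop_samples
#' @param class `"wild"` or `"selected"`.
#' @export
class_samples <- function(ds, class) {
  which(ds$pop_class[ds$pop] == class)
}

#' Per-marker alternate allele frequency over a sample subset
#' @param ds a `geno_ds`.
#' @param samples optional sample index (default: all).
#' @return numeric vector, `NaN` where all calls are missing.
#' @export
alt_freq <- function(ds, samples = NULL) {
  g <- if (is.null(samples)) ds$geno else ds$geno[samples, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Per-marker minor allele frequency
#' @inheritParams alt_freq
#' @return numeric vector in [0, 0.5].
#' @export
maf <- function(ds, samples = NULL) {
  p <- alt_freq(ds, samples)
  pmin(p, 1 - p)
}
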