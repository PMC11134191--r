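#' Bundled reference summary tables
#'
#' Small plain-text reference tables for the eastern oyster wild/selected
#' SNP-array panel (per-site diversity, relatedness and LD-based effective
#' size; group-mean pairwise FST at all markers and at union outlier
#' markers), bundled for demonstration and regression of the report
#' arithmetic. The single-generation hatchery F1 cohort DBX1 is grouped as
#' wild (it underwent no selective breeding) but is excluded from the wild
#' Ne mean, being a one-generation cohort whose estimate reflects its
#' breeder count rather than a wild population size.
#'
#' @return `reference_diversity_ne()`: data.frame of per-site statistics;
#'   `reference_fst_groups()`: data.frame of group-mean FST.
#' @export
reference_diversity_ne <- function() {
  utils::read.table(
    system.file("extdata", "diversity_ne_reference.tsv",
                package = "domestiscan"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname reference_diversity_ne
#' @export
reference_fst_groups <- function() {
  utils::read.table(
    system.file("extdata", "fst_group_reference.tsv",
                package = "domestiscan"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Group means of a per-site summary table
#'
#' Column means per group; the wild Ne mean is reported both with and
#' without single-generation hatchery cohorts (`ne_exclude` sites).
#'
#' @param tab data.frame like [reference_diversity_ne()].
#' @param ne_exclude site names excluded from the wild Ne mean.
#' @return list of per-group mean vectors plus `wild_ne_mean` (exclusions
#'   applied).
#' @export
summary_group_means <- function(tab, ne_exclude = "DBX1") {
  out <- lapply(split(tab, tab$group), function(d)
    colMeans(d[, c("N", "Ar", "Ho", "He", "relatedness", "Ne")]))
  wild <- tab[tab$group == "wild" & !(tab$site %in% ne_exclude), ]
  out$wild_ne_mean <- mean(wild$Ne)
  out
}

#' Expected effective number of breeders from a sex-ratio cross
#'
#' Nb = 4 Nf Nm / (Nf + Nm); an 18-female x 12-male cross gives 28.8.
#'
#' @param n_female,n_male breeder counts.
#' @return expected Nb.
#' @export
expected_nb <- function(n_female, n_male) {
  4 * n_female * n_male / (n_female + n_male)
}
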