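#' Read genotypes from VCF with a population map
#'
#' Only the GT field is consumed; array-QC INFO fields are ignored. Non-SNP
#' and multi-allelic records are skipped with a warning giving the count.
#' Samples present in the VCF but absent from the popmap are an error.
#'
#' @param path path to a VCF (4.x) file, plain or gzipped.
#' @param popmap_path path to a 2- or 3-column TSV: sample, population
#'   and optionally class (`wild`/`selected`). When the class column is
#'   absent every population defaults to `"wild"` with a warning.
#' @return a [geno_dataset()] object.
#' @export
read_vcf <- function(path, popmap_path) {
  pm <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  if (any(!is_snp))
    warning(sum(!is_snp), " non-SNP or multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_pm <- setdiff(samples, pm$sample)
  if (length(missing_pm))
    stop("samples absent from popmap: ", paste(missing_pm, collapse = ", "))
  dos <- gt_to_dosage(gt)                      # markers x samples
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
           fix[is.na(ids) | ids == ".", "POS"])
  map <- data.frame(id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  pm <- pm[match(samples, pm$sample), ]
  cls <- vapply(split(pm$class, pm$pop), `[[`, character(1), 1)
  geno_dataset(t(dos), samples, pm$pop, cls, map)
}

# "0/1"-style GT strings (phased or unphased) -> integer dosage matrix
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  core <- sub(":.*", "", gt)
  d[core %in% c("0/0", "0|0")] <- 0L
  d[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[core %in% c("1/1", "1|1")] <- 2L
  d
}

#' Read a population map
#' @param path 2/3-column TSV (sample, population[, class]).
#' @return data.frame with columns sample, pop, class.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(pm) == 2) {
    warning("popmap has no class column; defaulting every population to 'wild'")
    pm$V3 <- "wild"
  }
  if (ncol(pm) != 3) stop("popmap must have 2 or 3 tab-separated columns")
  names(pm) <- c("sample", "pop", "class")
  if (!all(pm$class %in% c("wild", "selected")))
    stop("popmap class column must be 'wild' or 'selected'")
  if (anyDuplicated(pm$sample)) stop("duplicate sample ids in popmap")
  pm
}

#' Write a dataset as VCF (+ popmap)
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns; a round trip through
#' [read_vcf()] reproduces the dosage matrix, sample ids and marker map.
#'
#' @param ds a `geno_ds`.
#' @param path output VCF path.
#' @param popmap_path optional path for a matching 3-column popmap TSV.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path, popmap_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ds$sample_ids), collapse = "\t"), con)
  if (n_markers(ds) > 0) {
    gtcode <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = n_markers(ds), ncol = n_samples(ds))
    dos <- t(ds$geno)
    ok <- !is.na(dos)
    gt[ok] <- gtcode[dos[ok] + 1L]
    body <- paste(ds$map$chrom, ds$map$pos, ds$map$id, ds$map$ref, ds$map$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    if (n_samples(ds) == 0)
      body <- paste(ds$map$chrom, ds$map$pos, ds$map$id, ds$map$ref,
                    ds$map$alt, ".", "PASS", ".", "GT", sep = "\t")
    writeLines(body, con)
  }
  if (!is.null(popmap_path)) write_popmap(ds, popmap_path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
write_popmap <- function(ds, popmap_path) {
  utils::write.table(
    data.frame(ds$sample_ids, ds$pop, unname(ds$pop_class[ds$pop])),
    popmap_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(popmap_path)
}

#' Read a BED file of excluded regions
#'
#' Standard BED semantics: 0-based half-open intervals, which is also the
#' package's internal convention.
#'
#' @param path BED path (first three columns used).
#' @return data.frame with columns chrom, start, end.
#' @export
read_regions <- function(path) {
  rg <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(rg) < 3) stop("BED needs >= 3 columns")
  rg <- rg[, 1:3]
  names(rg) <- c("chrom", "start", "end")
  rg$start <- as.integer(rg$start); rg$end <- as.integer(rg$end)
  bad <- which(!(rg$start < rg$end))
  if (length(bad)) stop("BED line ", bad[1], ": start must be < end")
  rg
}

#' Which markers fall inside a region set?
#' @param map marker map (`id`, `chrom`, `pos` 1-based).
#' @param regions data.frame from [read_regions()].
#' @return logical vector over markers.
#' @export
markers_in_regions <- function(map, regions) {
  hit <- logical(nrow(map))
  pos0 <- map$pos - 1L                      # to 0-based
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (map$chrom == regions$chrom[i] &
                    pos0 >= regions$start[i] & pos0 < regions$end[i])
  }
  hit
}

#' Read an admixture-proportion (Q) matrix
#'
#' Rows are renormalized when their sum is within 1e-3 of 1; larger
#' deviations are an error naming the offending line.
#'
#' @param path TSV of K proportions per sample, optionally with a leading
#'   sample-id column.
#' @return numeric matrix (samples x K); rownames are sample ids when given.
#' @export
read_qmatrix <- function(path) {
  q <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  ids <- NULL
  if (is.character(q[[1]])) { ids <- q[[1]]; q <- q[, -1, drop = FALSE] }
  q <- as.matrix(q)
  if (!is.numeric(q)) stop("Q matrix has non-numeric entries")
  if (any(q < 0)) stop("Q proportions must be non-negative")
  s <- rowSums(q)
  bad <- which(abs(s - 1) > 1e-3)
  if (length(bad))
    stop("Q matrix line ", bad[1], ": proportions sum to ",
         format(s[bad[1]]), ", not 1")
  q <- q / s
  if (!is.null(ids)) rownames(q) <- ids
  q
}

#' Read marker-to-gene and gene-to-term annotation tables
#'
#' @param marker_gene_path 2-column TSV (marker_id, gene_id).
#' @param gene_term_path 2-column TSV (gene_id, term_id).
#' @return list with data.frames `marker_gene` and `gene_term`.
#' @export
read_annotation <- function(marker_gene_path, gene_term_path) {
  mg <- utils::read.table(marker_gene_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  gt <- utils::read.table(gene_term_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(mg) != 2) stop("marker-gene table must have 2 columns")
  if (ncol(gt) != 2) stop("gene-term table must have 2 columns")
  names(mg) <- c("marker_id", "gene_id")
  names(gt) <- c("gene_id", "term_id")
  list(marker_gene = mg, gene_term = gt)
}
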