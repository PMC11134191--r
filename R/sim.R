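#' Simulator configuration
#'
#' Defaults emulate a multi-chromosome SNP-array panel: several wild
#' populations with mild differentiation, plus captive strains derived from
#' them by a handful of generations of small-broodstock breeding and optional
#' per-locus viability selection.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp physical chromosome length (bp).
#' @param n_markers_per_chrom markers per chromosome (positions uniform).
#' @param morgans_per_chrom genetic length per chromosome (Morgans);
#'   crossovers are Poisson with no interference.
#' @param wild_Ne contemporary effective size of each wild population.
#' @param ancestral_Ne size of the shared ancestral population during the
#'   burn-in; a historical bottleneck of this size is what builds
#'   realistic short-range LD into the panel.
#' @param n_wild_pops number of wild populations.
#' @param wild_Fst_target mean pairwise FST among wild populations; must lie
#'   in [0, 0.1].
#' @param n_samples_per_pop individuals sampled per wild population.
#' @param burnin_generations shared ancestral burn-in generations at
#'   `ancestral_Ne` (>= 20; the default 100 lets linked LD approach
#'   drift-recombination equilibrium).
#' @param strain_specs list of [strain_spec()] objects.
#' @param seed global integer seed; every strain derivation uses a
#'   deterministic sub-seed derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chrom = 10, chrom_len_bp = 3e6,
                       n_markers_per_chrom = 300, morgans_per_chrom = 0.25,
                       wild_Ne = 300, ancestral_Ne = 100, n_wild_pops = 4,
                       wild_Fst_target = 0.03, n_samples_per_pop = 32,
                       burnin_generations = 100,
                       strain_specs = NULL, seed = 1) {
  stopifnot(n_chrom > 0, chrom_len_bp > 0, n_markers_per_chrom > 1,
            wild_Ne > 1, ancestral_Ne > 1, n_wild_pops > 0,
            wild_Fst_target >= 0, wild_Fst_target <= 0.1,
            burnin_generations >= 20)
  structure(list(n_chrom = n_chrom, chrom_len_bp = chrom_len_bp,
                 n_markers_per_chrom = n_markers_per_chrom,
                 morgans_per_chrom = morgans_per_chrom,
                 wild_Ne = wild_Ne, ancestral_Ne = ancestral_Ne,
                 n_wild_pops = n_wild_pops,
                 wild_Fst_target = wild_Fst_target,
                 n_samples_per_pop = n_samples_per_pop,
                 burnin_generations = burnin_generations,
                 strain_specs = strain_specs, seed = as.integer(seed)),
            class = "sim_config")
}

#' Captive-strain breeding specification
#'
#' @param source_pop label of the wild source population.
#' @param n_female,n_male broodstock counts drawn each generation.
#' @param generations number of captive generations (1-17).
#' @param n_offspring cohort size produced each generation.
#' @param selected_loci integer marker indices under viability selection.
#' @param s selection coefficient; survival is multiplied by (1+s) per copy
#'   of the alternate allele at each selected locus.
#' @param admix_from optional `list(strain = <label>, prop = <fraction>)`:
#'   in the first captive generation, this fraction of offspring take their
#'   father from the named (already-derived) strain's final cohort.
#' @param overdispersion family-size overdispersion; 0 gives Poisson family
#'   sizes, larger values emulate sweepstakes variance in reproductive
#'   success (parent weights drawn from a Gamma with CV^2 = overdispersion).
#' @param label strain label.
#' @param pop_class exported class label; `"selected"` for bred lines, but a
#'   single-generation hatchery F1 cohort is conventionally grouped with the
#'   wild populations because it underwent no selective breeding.
#' @return a `strain_spec` list.
#' @export
strain_spec <- function(source_pop, n_female, n_male, generations,
                        n_offspring = 100, selected_loci = integer(0),
                        s = 0, admix_from = NULL, overdispersion = 0,
                        label = NULL, pop_class = "selected") {
  stopifnot(generations >= 1, generations <= 17, s >= 0,
            n_female >= 1, n_male >= 1, n_offspring >= 2,
            pop_class %in% c("wild", "selected"))
  structure(list(source_pop = source_pop, n_female = n_female,
                 n_male = n_male, generations = generations,
                 n_offspring = n_offspring,
                 selected_loci = if (identical(selected_loci, "auto"))
                   "auto" else as.integer(selected_loci),
                 s = s,
                 admix_from = admix_from, overdispersion = overdispersion,
                 label = label %||% paste0("strain_", source_pop),
                 pop_class = pop_class),
            class = "strain_spec")
}

# sample from a vector (robust to length-1 vectors)
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic sub-seed from a global seed and a stage label
#' @param seed integer seed.
#' @param label character stage name.
#' @return integer below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}

# marker map with uniform positions per chromosome
make_map <- function(cfg) {
  pos <- lapply(seq_len(cfg$n_chrom), function(c) {
    sort(sample.int(cfg$chrom_len_bp, cfg$n_markers_per_chrom))
  })
  data.frame(
    id = sprintf("chr%02d_m%04d", rep(seq_len(cfg$n_chrom),
                                      each = cfg$n_markers_per_chrom),
                 unlist(lapply(pos, seq_along))),
    chrom = sprintf("chr%02d", rep(seq_len(cfg$n_chrom),
                                   each = cfg$n_markers_per_chrom)),
    pos = unlist(pos), ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# Per-gamete inheritance phase (0/1 = which parental haplotype) at every
# marker, under Poisson crossovers with no interference.
# map_g: list(chrom_index list of marker columns, gpos = genetic pos per marker)
make_phase <- function(n_gam, map_g, morgans) {
  M <- length(map_g$gpos)
  P <- matrix(0L, n_gam, M)
  for (ci in seq_along(map_g$chrom_cols)) {
    cols <- map_g$chrom_cols[[ci]]
    g <- map_g$gpos[cols]
    start <- sample(0:1, n_gam, replace = TRUE)
    k <- stats::rpois(n_gam, morgans)
    P[, cols] <- start
    for (j in which(k > 0)) {
      br <- sort(stats::runif(k[j], 0, morgans))
      P[j, cols] <- (start[j] + findInterval(g, br)) %% 2L
    }
  }
  P
}

# Produce gamete matrices from a haplotype pool.
# H: 2N x M haplotypes (rows 2i-1, 2i belong to individual i).
# parent: integer vector of individual indices, one per gamete.
# Optionally transmits a parallel label matrix with the same phases.
make_gametes <- function(H, parent, map_g, morgans, L = NULL) {
  n <- length(parent)
  P <- make_phase(n, map_g, morgans)
  M <- ncol(H)
  rowidx <- matrix(2L * parent - 1L, n, M) + P
  idx <- cbind(as.vector(rowidx), rep(seq_len(M), each = n))
  G <- matrix(H[idx], n, M)
  if (is.null(L)) return(list(G = G))
  list(G = G, L = matrix(L[idx], n, M))
}

map_geometry <- function(map, chrom_len_bp, morgans) {
  chrom_cols <- split(seq_len(nrow(map)), map$chrom)
  gpos <- map$pos / chrom_len_bp * morgans
  list(chrom_cols = chrom_cols, gpos = gpos)
}

# one generation of Wright-Fisher random mating (monoecious) at size N
wf_generation <- function(H, N, map_g, morgans) {
  mothers <- sample.int(nrow(H) / 2, N, replace = TRUE)
  fathers <- sample.int(nrow(H) / 2, N, replace = TRUE)
  g1 <- make_gametes(H, mothers, map_g, morgans)$G
  g2 <- make_gametes(H, fathers, map_g, morgans)$G
  H2 <- matrix(0L, 2 * N, ncol(H))
  H2[seq(1, 2 * N, 2), ] <- g1
  H2[seq(2, 2 * N, 2), ] <- g2
  H2
}

#' Simulate wild progenitor populations
#'
#' Builds an ancestral pool with background LD by a shared Wright-Fisher
#' burn-in with recombination at `ancestral_Ne` (a historical bottleneck
#' that lets linked LD approach drift-recombination equilibrium), then lets
#' each wild population drift independently at `wild_Ne` for a number of
#' generations calibrated so the realized mean pairwise FST approximates
#' `wild_Fst_target` (t = ln(1 - FST) / ln(1 - 1/(2Ne)); t = 0 reproduces
#' identical frequencies and FST ~ 0, with the populations then drawn as
#' disjoint samples of one panmictic pool).
#'
#' @param cfg a [sim_config()].
#' @return list with `pops` (per population: haplotype matrix `H` and a
#'   `geno_ds` `ds` of sampled individuals), `map`, `anc_freq`, and the
#'   divergence generations used.
#' @export
simulate_wild <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "wild"))
  map <- make_map(cfg)
  map_g <- map_geometry(map, cfg$chrom_len_bp, cfg$morgans_per_chrom)
  M <- nrow(map)
  Ne <- cfg$wild_Ne
  Na <- cfg$ancestral_Ne
  p_anc <- stats::runif(M, 0.05, 0.95)
  H <- matrix(stats::rbinom(2 * Na * M, 1, rep(p_anc, each = 2 * Na)),
              2 * Na, M)
  for (t in seq_len(cfg$burnin_generations))
    H <- wf_generation(H, Na, map_g, cfg$morgans_per_chrom)
  t_div <- if (cfg$wild_Fst_target <= 0) 0L else {
    t <- log(1 - cfg$wild_Fst_target) / log(1 - 1 / (2 * Ne))
    if (t > 200) stop("infeasible wild_Fst_target for this wild_Ne")
    as.integer(round(t))
  }
  # disjoint founders per population when there is no divergence phase
  if (t_div == 0 && cfg$n_wild_pops * cfg$n_samples_per_pop > Na)
    H <- wf_generation(H, cfg$n_wild_pops * cfg$n_samples_per_pop,
                       map_g, cfg$morgans_per_chrom)
  pool_n <- nrow(H) / 2
  pops <- list()
  for (i in seq_len(cfg$n_wild_pops)) {
    if (t_div > 0) {
      Hp <- H
      for (t in seq_len(t_div))
        Hp <- wf_generation(Hp, Ne, map_g, cfg$morgans_per_chrom)
    } else {
      rows <- interleave_rows(((i - 1) * cfg$n_samples_per_pop + 1):
                                (i * cfg$n_samples_per_pop))
      Hp <- H[rows, , drop = FALSE]
    }
    lab <- sprintf("wild%d", i)
    keep <- sort(sample.int(nrow(Hp) / 2,
                            min(cfg$n_samples_per_pop, nrow(Hp) / 2)))
    rows <- as.vector(rbind(2 * keep - 1, 2 * keep))
    dos <- Hp[rows[c(TRUE, FALSE)], , drop = FALSE] +
      Hp[rows[c(FALSE, TRUE)], , drop = FALSE]
    ids <- sprintf("%s_s%03d", lab, seq_along(keep))
    cls <- stats::setNames("wild", lab)
    pops[[lab]] <- list(H = Hp,
                        ds = geno_dataset(dos, ids, rep(lab, length(ids)),
                                          cls, map))
  }
  list(pops = pops, map = map, anc_freq = colMeans(H), t_div = t_div,
       cfg = cfg)
}

#' Derive a captive strain from a wild population
#'
#' Each generation samples broodstock from the previous cohort (generation 1
#' from the wild source), forms offspring by random pairing of a random
#' mother and father (Poisson family sizes, optionally overdispersed),
#' applies recombination, applies viability selection with survival
#' proportional to (1+s) per selected-allele copy, and records the pedigree.
#' Founder-haplotype labels are propagated so realized identity-by-descent
#' tracts and inbreeding are known exactly.
#'
#' @param wild result of [simulate_wild()].
#' @param spec a [strain_spec()].
#' @param seed integer seed for this derivation.
#' @param other_strains named list of previously derived strains (for
#'   `admix_from`).
#' @param n_samples individuals sampled from the final cohort into the
#'   exported dataset.
#' @return list with `ds` (a `geno_ds`, pop class `"selected"`), `H`, `L`
#'   (final haplotypes and founder labels) and `truth` (pedigree inbreeding,
#'   realized IBD inbreeding and tracts, per-generation breeder counts and
#'   Nb, ancestry fractions, selected loci).
#' @export
derive_strain <- function(wild, spec, seed, other_strains = NULL,
                          n_samples = 32) {
  set.seed(seed)
  src <- wild$pops[[spec$source_pop]]
  if (is.null(src)) stop("unknown source population: ", spec$source_pop)
  map <- wild$map
  map_g <- map_geometry(map, wild$cfg$chrom_len_bp,
                        wild$cfg$morgans_per_chrom)
  Npool <- nrow(src$H) / 2
  nb <- spec$n_female + spec$n_male
  if (nb > Npool) stop("broodstock exceeds wild population size")

  # founders: distinct wild individuals; females first
  founders <- sample.int(Npool, nb)
  H <- src$H[as.vector(rbind(2 * founders - 1, 2 * founders)), , drop = FALSE]
  L <- matrix(rep(seq_len(2 * nb), ncol(H)), 2 * nb, ncol(H))
  anc <- rep(0, nb)                     # admixture-source ancestry fraction
  sex <- rep(c("F", "M"), c(spec$n_female, spec$n_male))
  K <- diag(0.5, nb)                    # kinship; founders unrelated
  Fped <- rep(0, nb)

  adm <- spec$admix_from
  admH <- admL <- NULL
  adm_nb <- 0L
  if (!is.null(adm)) {
    os <- other_strains[[adm$strain]]
    if (is.null(os)) stop("admix_from strain not available: ", adm$strain)
    admH <- os$H; admL <- max(L) + os$L
    adm_nb <- nrow(admH) / 2
  }

  nb_expected <- nb_pedigree <- numeric(spec$generations)
  nf_real <- nm_real <- integer(spec$generations)

  for (g in seq_len(spec$generations)) {
    females <- which(sex == "F"); males <- which(sex == "M")
    if (!length(females) || !length(males))
      stop("no broodstock of one sex at generation ", g)
    # broodstock drawn from the cohort, capped at the spec'd counts
    if (length(females) > spec$n_female)
      females <- resample(females, spec$n_female)
    if (length(males) > spec$n_male)
      males <- resample(males, spec$n_male)
    wf <- parent_weights(length(females), spec$overdispersion)
    wm <- parent_weights(length(males), spec$overdispersion)
    n_off <- spec$n_offspring

    # viability selection: an oversized candidate cohort is culled to
    # n_off survivors with probability proportional to (1+s) per selected
    # allele copy (relative survival; cohort size is maintained by the
    # hatchery, so selection acts through relative viability)
    nb_batch <- if (length(spec$selected_loci)) 3 * n_off else n_off
    mo <- resample(females, nb_batch, replace = TRUE, prob = wf)
    ext <- if (adm_nb > 0 && g == 1)
      stats::runif(nb_batch) < adm$prop else rep(FALSE, nb_batch)
    fa <- resample(males, nb_batch, replace = TRUE, prob = wm)
    gm <- make_gametes(H, mo, map_g, wild$cfg$morgans_per_chrom, L)
    gf <- make_gametes(H, fa, map_g, wild$cfg$morgans_per_chrom, L)
    if (any(ext)) {
      fa_ext <- sample.int(adm_nb, sum(ext), replace = TRUE)
      ge <- make_gametes(admH, fa_ext, map_g,
                         wild$cfg$morgans_per_chrom, admL)
      gf$G[ext, ] <- ge$G; gf$L[ext, ] <- ge$L
    }
    keep <- if (length(spec$selected_loci)) {
      w <- (1 + spec$s)^rowSums(gm$G[, spec$selected_loci, drop = FALSE] +
                                  gf$G[, spec$selected_loci, drop = FALSE])
      if (!any(w > 0) || sum(w > 0) < n_off)
        stop("population extinct under selection at generation ", g)
      sample.int(nb_batch, n_off, prob = w)
    } else seq_len(n_off)
    kids_m <- mo[keep]; kids_f <- fa[keep]; kids_ext <- ext[keep]
    kids_H <- interleave(gm$G[keep, , drop = FALSE],
                         gf$G[keep, , drop = FALSE])$geno
    kids_L <- interleave(gm$L[keep, , drop = FALSE],
                         gf$L[keep, , drop = FALSE])$geno

    nf_real[g] <- length(unique(kids_m))
    nm_real[g] <- length(unique(kids_f[!kids_ext]))
    nb_expected[g] <- 4 * spec$n_female * spec$n_male /
      (spec$n_female + spec$n_male)
    nb_pedigree[g] <- pedigree_nb(kids_m, kids_f[!kids_ext],
                                  length(females), length(males))

    # pedigree kinship and inbreeding (external fathers treated as new
    # unrelated non-inbred individuals)
    Ko <- kinship_advance(K, kids_m, kids_f, kids_ext)
    Fped <- Ko$F; K <- Ko$K
    anc_m <- anc[kids_m] / 2
    anc_f <- ifelse(kids_ext, 0.5, anc[kids_f] / 2)
    anc <- anc_m + anc_f
    H <- kids_H; L <- kids_L
    sex <- sample(c("F", "M"), n_off, replace = TRUE)
    # guarantee both sexes for any further generation
    if (g < spec$generations) {
      if (!any(sex == "F")) sex[1] <- "F"
      if (!any(sex == "M")) sex[length(sex)] <- "M"
    }
  }

  n_out <- min(n_samples, spec$n_offspring)
  pick <- sort(sample.int(spec$n_offspring, n_out))
  rows <- interleave_rows(pick)
  Hs <- H[rows, , drop = FALSE]; Ls <- L[rows, , drop = FALSE]
  dos <- Hs[c(TRUE, FALSE), , drop = FALSE] + Hs[c(FALSE, TRUE), , drop = FALSE]
  ids <- sprintf("%s_s%03d", spec$label, seq_len(n_out))
  cls <- stats::setNames(spec$pop_class, spec$label)
  ds <- geno_dataset(dos, ids, rep(spec$label, n_out), cls, map)

  f_ibd <- ibd_inbreeding(Ls)
  tracts <- ibd_tracts(Ls, map)
  truth <- list(
    strain = spec$label,
    f_pedigree = Fped[pick], f_ibd = f_ibd,
    f_pedigree_all = Fped,
    ibd_tracts = tracts,
    nb_expected = nb_expected, nb_pedigree = nb_pedigree,
    n_female_realized = nf_real, n_male_realized = nm_real,
    selected_loci = spec$selected_loci, s = spec$s,
    ancestry_admix = anc[pick], generations = spec$generations)
  list(ds = ds, H = H, L = L, truth = truth)
}

parent_weights <- function(n, overdispersion) {
  if (overdispersion <= 0) return(rep(1, n))
  stats::rgamma(n, shape = 1 / overdispersion, rate = 1 / overdispersion)
}

interleave <- function(g1, g2) {
  n <- nrow(g1)
  H <- matrix(0L, 2 * n, ncol(g1))
  H[seq(1, 2 * n, 2), ] <- g1
  H[seq(2, 2 * n, 2), ] <- g2
  list(geno = H)
}

interleave_rows <- function(ind) as.vector(rbind(2 * ind - 1, 2 * ind))

# demographic Nb from realized parent usage: per-sex Ne from family-size
# mean/variance, combined as 4NeF*NeM/(NeF+NeM)
pedigree_nb <- function(mothers, fathers, nf, nm) {
  ne_sex <- function(counts, npar) {
    k <- c(counts, rep(0, npar - length(counts)))
    kb <- mean(k); vk <- stats::var(k)
    if (kb <= 0) return(NA_real_)
    (npar * kb - 1) / (kb - 1 + vk / kb)
  }
  nef <- ne_sex(as.integer(table(mothers)), nf)
  nem <- ne_sex(as.integer(table(fathers)), nm)
  if (is.na(nef) || is.na(nem) || nef + nem <= 0) return(NA_real_)
  4 * nef * nem / (nef + nem)
}

# advance a kinship matrix one generation; external fathers unrelated
kinship_advance <- function(K, mo, fa, ext) {
  n <- length(mo)
  fa_safe <- ifelse(ext, 1L, fa)
  S <- 0.5 * (K[mo, , drop = FALSE] +
                ifelse(ext, 0, 1) * K[fa_safe, , drop = FALSE])
  Knew <- 0.5 * (S[, mo, drop = FALSE] +
                   t(ifelse(ext, 0, 1) * t(S[, fa_safe, drop = FALSE])))
  Fo <- ifelse(ext, 0, K[cbind(mo, fa_safe)])
  diag(Knew) <- 0.5 * (1 + Fo)
  list(K = Knew, F = Fo)
}

# realized IBD-based inbreeding: fraction of markers whose two founder
# labels coincide
ibd_inbreeding <- function(L) {
  n <- nrow(L) / 2
  vapply(seq_len(n), function(i)
    mean(L[2 * i - 1, ] == L[2 * i, ]), numeric(1))
}

# runs of label identity per individual and chromosome
ibd_tracts <- function(L, map) {
  n <- nrow(L) / 2
  out <- vector("list", n)
  chroms <- split(seq_len(nrow(map)), map$chrom)
  for (i in seq_len(n)) {
    eq <- L[2 * i - 1, ] == L[2 * i, ]
    res <- list()
    for (ch in names(chroms)) {
      cols <- chroms[[ch]]
      r <- rle(eq[cols])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (j in which(r$values)) {
        res[[length(res) + 1]] <- data.frame(
          chrom = ch, start = map$pos[cols[starts[j]]],
          end = map$pos[cols[ends[j]]], n_snps = r$lengths[j])
      }
    }
    out[[i]] <- if (length(res)) do.call(rbind, res) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), n_snps = integer(0))
  }
  out
}

#' Assemble the full simulated panel
#'
#' Runs [simulate_wild()], derives every strain in `cfg$strain_specs`, and
#' merges the sampled wild and strain cohorts into one dataset with
#' wild/selected population classes. Optionally writes VCF, popmap and a
#' ground-truth JSON to a directory.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `ds` (merged `geno_ds`), `truth` (per-strain list),
#'   `wild` (the [simulate_wild()] result).
#' @export
assemble_panel <- function(cfg, out_dir = NULL) {
  wild <- simulate_wild(cfg)
  specs <- cfg$strain_specs %||% list()
  # "auto" selected loci: one shared set drawn among markers at moderate
  # wild allele frequency, where a viability response can be rapid
  if (any(vapply(specs, function(sp)
    identical(sp$selected_loci, "auto"), logical(1)))) {
    set.seed(derive_seed(cfg$seed, "selected_loci"))
    fbar <- rowMeans(vapply(wild$pops, function(p) alt_freq(p$ds),
                            numeric(nrow(wild$map))))
    cand <- which(fbar >= 0.2 & fbar <= 0.6)
    n_sel <- cfg$n_selected_loci %||% 8
    sel <- sort(resample(cand, min(n_sel, length(cand))))
    specs <- lapply(specs, function(sp) {
      if (identical(sp$selected_loci, "auto"))
        sp$selected_loci <- as.integer(sel)
      sp
    })
  }
  strains <- list()
  truth <- list()
  for (sp in specs) {
    st <- derive_strain(wild, sp, derive_seed(cfg$seed, sp$label),
                        other_strains = strains,
                        n_samples = cfg$n_samples_per_pop)
    strains[[sp$label]] <- st
    truth[[sp$label]] <- st$truth
  }
  all_ds <- c(lapply(wild$pops, `[[`, "ds"), lapply(strains, `[[`, "ds"))
  ds <- merge_datasets(all_ds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(ds, file.path(out_dir, "panel.vcf"),
              file.path(out_dir, "popmap.tsv"))
    tr <- lapply(truth, function(t) t[setdiff(names(t), "ibd_tracts")])
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ds = ds, truth = truth, wild = wild)
}

#' Merge datasets sharing one marker map
#' @param ds_list list of `geno_ds` with identical maps.
#' @return merged `geno_ds`.
#' @export
merge_datasets <- function(ds_list) {
  map <- ds_list[[1]]$map
  for (d in ds_list[-1])
    if (!identical(d$map$id, map$id)) stop("marker maps differ")
  ds_list <- unname(ds_list)
  ids <- unlist(lapply(ds_list, `[[`, "sample_ids"))
  if (anyDuplicated(ids)) stop("duplicate sample ids across datasets")
  geno <- do.call(rbind, lapply(ds_list, `[[`, "geno"))
  pop <- unlist(lapply(ds_list, `[[`, "pop"))
  cls <- do.call(c, lapply(ds_list, `[[`, "pop_class"))
  cls <- cls[!duplicated(names(cls))]
  geno_dataset(geno, ids, pop, cls, map)
}

#' Default demonstration configuration
#'
#' Four wild populations plus four derived strains covering the design
#' space of real breeding programs (1-17 generations in culture): an old
#' multi-generation selected line, a small-broodstock line, a younger
#' admixture cross between strains, and a single-generation hatchery
#' cohort with an 18-female x 12-male cross (expected number of breeders
#' 4*18*12/(18+12) = 28.8). The same loci are under viability selection in
#' all bred lines, emulating parallel domestication pressure from shared
#' culture conditions.
#'
#' @param seed global seed.
#' @param n_selected_loci loci under parallel selection in the selected lines.
#' @param s selection coefficient at those loci.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1, n_selected_loci = 8, s = 0.5) {
  cfg <- sim_config(seed = seed)
  cfg$n_selected_loci <- n_selected_loci
  cfg$strain_specs <- list(
    strain_spec("wild1", 25, 25, generations = 12, selected_loci = "auto",
                s = s, label = "selA"),
    strain_spec("wild2", 10, 8, generations = 8, selected_loci = "auto",
                s = s, label = "selB"),
    strain_spec("wild3", 20, 15, generations = 4, selected_loci = "auto",
                s = s, admix_from = list(strain = "selA", prop = 0.5),
                label = "selC"),
    strain_spec("wild4", 18, 12, generations = 1, label = "hatchF1",
                pop_class = "wild")
  )
  cfg
}
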