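test_that("zero divergence target gives near-zero realized FST", {
  cfg <- sim_config(n_chrom = 4, n_markers_per_chrom = 80,
                    wild_Fst_target = 0, n_wild_pops = 3,
                    n_samples_per_pop = 24, ancestral_Ne = 80,
                    burnin_generations = 20, seed = 11)
  w <- simulate_wild(cfg)
  ds <- merge_datasets(lapply(w$pops, `[[`, "ds"))
  fst <- wc_fst(ds)
  off <- fst[upper.tri(fst)]
  expect_true(all(abs(off) < 0.01))
})

test_that("divergence calibration hits the FST target window", {
  cfg <- sim_config(n_chrom = 4, n_markers_per_chrom = 120,
                    wild_Fst_target = 0.03, n_wild_pops = 4,
                    wild_Ne = 300, ancestral_Ne = 80,
                    burnin_generations = 20, seed = 5)
  w <- simulate_wild(cfg)
  ds <- merge_datasets(lapply(w$pops, `[[`, "ds"))
  fst <- wc_fst(ds)
  expect_gt(mean(fst[upper.tri(fst)]), 0.02)
  expect_lt(mean(fst[upper.tri(fst)]), 0.04)
})

test_that("a fixed seed reproduces the simulation bitwise", {
  cfg <- sim_config(n_chrom = 2, n_markers_per_chrom = 50,
                    ancestral_Ne = 40, wild_Ne = 60, n_wild_pops = 2,
                    n_samples_per_pop = 10, burnin_generations = 20,
                    strain_specs = list(strain_spec("wild1", 5, 5, 2)),
                    seed = 42)
  a <- assemble_panel(cfg)
  b <- assemble_panel(cfg)
  expect_identical(a$ds$geno, b$ds$geno)
  expect_identical(a$truth[[1]]$f_pedigree, b$truth[[1]]$f_pedigree)
})

test_that("expected Nb follows the unequal-sex-ratio formula", {
  expect_equal(expected_nb(18, 12), 28.8)
  sim <- demo_sim()
  expect_equal(unique(sim$truth$hatchF1$nb_expected), 28.8)
})

test_that("neutral one-generation crosses stay within sampling error", {
  cfg <- sim_config(n_chrom = 3, n_markers_per_chrom = 60,
                    ancestral_Ne = 150, wild_Ne = 150, n_wild_pops = 1,
                    wild_Fst_target = 0, n_samples_per_pop = 100,
                    burnin_generations = 20, seed = 9)
  w <- simulate_wild(cfg)
  st <- derive_strain(w, strain_spec("wild1", 50, 50, generations = 1,
                                     n_offspring = 120),
                      seed = 3, n_samples = 120)
  p_par <- alt_freq(w$pops$wild1$ds)
  p_off <- alt_freq(st$ds)
  # drift from 100 broodstock plus sampling of 120 offspring
  z <- (p_off - p_par) / sqrt(pmax(p_par * (1 - p_par), 1e-6) *
                                (1 / 200 + 1 / 240))
  expect_lt(mean(abs(z) > 3, na.rm = TRUE), 0.10)
})

test_that("full-sib mating reproduces the classical inbreeding recursion", {
  # F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4 for repeated full-sib mating;
  # generation 1 is the founding cross of unrelated parents, so after 3
  # captive generations the cohort has seen 2 rounds of sib mating
  f <- c(0, 0)
  for (t in 1:2) f <- c(f[2], (1 + 2 * f[2] + f[1]) / 4)
  expected_f3 <- f[2]          # 0.25 then 0.375
  cfg <- sim_config(n_chrom = 2, n_markers_per_chrom = 40,
                    ancestral_Ne = 60, wild_Ne = 60, n_wild_pops = 1,
                    wild_Fst_target = 0, burnin_generations = 20, seed = 2)
  w <- simulate_wild(cfg)
  st <- derive_strain(w, strain_spec("wild1", 1, 1, generations = 3,
                                     n_offspring = 30),
                      seed = 8, n_samples = 30)
  expect_equal(unique(st$truth$f_pedigree), expected_f3)
  expect_equal(expected_f3, 0.375)
})

test_that("viability selection shifts planted loci beyond neutral drift", {
  sim <- demo_sim()
  sel <- sim$truth$selA$selected_loci
  p_wild <- alt_freq(sim$ds, pop_samples(sim$ds, paste0("wild", 1:4)))
  p_sel <- alt_freq(sim$ds, pop_samples(sim$ds, "selA"))
  shift <- p_sel - p_wild
  neutral <- setdiff(seq_along(shift), sel)
  thr <- stats::quantile(abs(shift[neutral]), 0.99, na.rm = TRUE)
  expect_gte(mean(abs(shift[sel]) > thr), 0.5)
  expect_gt(mean(abs(shift[sel])), mean(abs(shift[neutral])))
  expect_gt(mean(shift[sel]), 0)  # selection favors the alt allele
})

test_that("admixture crosses carry ~50% ancestry from the donor strain", {
  sim <- demo_sim()
  anc <- sim$truth$selC$ancestry_admix
  # half the first-generation offspring take an external father (50/50
  # crosses), so neutral expectation of cohort-mean donor ancestry is
  # prop/2 = 0.25; viability selection enriches donor ancestry because the
  # donor strain is near-fixed for the favored alleles
  expect_gt(mean(anc), 0.12)
  expect_lt(mean(anc), 0.65)
})

test_that("assembled panels satisfy dataset invariants and round-trip", {
  sim <- demo_sim()
  ds <- sim$ds
  expect_true(all(ds$geno[!is.na(ds$geno)] %in% 0:2))
  expect_true(all(ds$pop %in% names(ds$pop_class)))
  expect_false(is.unsorted(order(ds$map$chrom, ds$map$pos)))
  expect_equal(length(sim$truth), 4L)
  # pedigree inbreeding within [0, 1]; IBD tracts non-overlapping
  for (tr in sim$truth) {
    expect_true(all(tr$f_pedigree >= 0 & tr$f_pedigree <= 1))
    expect_true(all(tr$f_ibd >= 0 & tr$f_ibd <= 1))
  }
})

test_that("pedigree inbreeding tracks realized IBD inbreeding", {
  sim <- demo_sim()
  f_ped <- unlist(lapply(sim$truth[c("selA", "selB", "selC")],
                         `[[`, "f_pedigree"))
  f_ibd <- unlist(lapply(sim$truth[c("selA", "selB", "selC")],
                         `[[`, "f_ibd"))
  expect_gt(stats::cor(f_ped, f_ibd), 0.5)
  expect_lt(abs(mean(f_ibd) - mean(f_ped)), 0.1)
})
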