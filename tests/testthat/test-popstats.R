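test_that("heterozygosity definitions on tiny hand-checked cases", {
  # one locus, genotypes (AA, Aa): Ho = 0.5; monomorphic locus adds He 0
  g <- cbind(c(0L, 1L), c(0L, 0L))
  ds <- make_ds(g, pop = c("p1", "p1"), class = c(p1 = "wild"))
  d <- diversity(ds)
  expect_equal(d$Ho, mean(c(0.5, 0)))
  # unbiased He at locus 1: p = 0.25, 2pq * 2n/(2n-1) = 0.375 * 4/3 = 0.5
  expect_equal(d$He, mean(c(0.5, 0)))
  # monomorphic locus contributes Ar = 1
  expect_equal(domestiscan:::rarefied_richness(0, 4, 4), 1)
})

test_that("rarefied allelic richness matches exhaustive subsampling at 2n=6", {
  for (ca in 0:6)
    expect_equal(domestiscan:::rarefied_richness(ca, 6, 4), ar_oracle_2n6(ca),
                 tolerance = 1e-12)
})

test_that("rarefaction depth uses the global minimum across populations", {
  set.seed(3)
  g <- hwe_geno(12, stats::runif(20, 0.3, 0.7))
  g[1:3, 1] <- NA       # pop1 has only 3 callable genotypes at locus 1
  ds <- make_ds(g, pop = rep(c("p1", "p2"), each = 6),
                class = c(p1 = "wild", p2 = "selected"))
  d <- diversity(ds)
  expect_equal(unique(d$rarefaction_g), 2 * 3)
})

test_that("Ritland relatedness: hand arithmetic and HWE expectations", {
  # clone pair, single locus AA at p = 0.5: r = 2 * (1/0.5 - 1) = 2
  g1 <- cbind(c(2L, 2L, 0L, 0L))   # freq 0.5 in the population
  ds <- make_ds(g1, pop = rep("p1", 4), class = c(p1 = "wild"))
  r <- ritland_relatedness(ds, "p1")
  pair12 <- r$pairs$r[r$pairs$id1 == "s001" & r$pairs$id2 == "s002"]
  expect_equal(pair12, 2)
  # clone expectation over HWE genotypes at p = 0.5: enumeration
  # AA (1/4) -> 2, Aa (1/2) -> 0, aa (1/4) -> 2, mean = 1
  rl <- function(gx, gy, p) {
    xa <- gx / 2; ya <- gy / 2
    2 * (xa * ya / p + (1 - xa) * (1 - ya) / (1 - p) - 1)
  }
  expect_equal(0.25 * rl(2, 2, .5) + 0.5 * rl(1, 1, .5) +
                 0.25 * rl(0, 0, .5), 1)
  # unrelated pairs under HWE average to ~0 (Monte-Carlo oracle)
  set.seed(17)
  p <- stats::runif(400, 0.1, 0.9)
  g <- hwe_geno(30, p)
  ds2 <- make_ds(g, pop = rep("q", 30), class = c(q = "wild"),
                 chrom = rep("chr1", 400), pos = seq_len(400) * 1000L)
  rr <- ritland_relatedness(ds2, "q")
  expect_lt(abs(rr$mean), 0.05)
})

# independent scalar implementation of the Weir-Cockerham (1984) variance
# components for two populations at one locus, straight from the printed
# formulas (no shared code with wc_components)
wc_oracle_2pop <- function(counts1, counts2) {
  n1 <- sum(counts1); n2 <- sum(counts2); r <- 2
  p1 <- (2 * counts1[1] + counts1[2]) / (2 * n1)
  p2 <- (2 * counts2[1] + counts2[2]) / (2 * n2)
  h1 <- counts1[2] / n1; h2 <- counts2[2] / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

test_that("multilocus theta matches the independent scalar oracle", {
  # the spec'd hand case: (AA:5, Aa:5, aa:0) vs (AA:0, Aa:5, aa:5)
  g <- c(rep(0L, 5), rep(1L, 5), rep(1L, 5), rep(2L, 5))
  ds <- make_ds(cbind(g), pop = rep(c("p1", "p2"), each = 10),
                class = c(p1 = "wild", p2 = "selected"))
  # dosage counts dosage 0 = ref hom; oracle takes (AA, Aa, aa) as alt hom
  expect_equal(wc_fst(ds, "p1", "p2")$theta,
               wc_oracle_2pop(c(0, 5, 5), c(5, 5, 0)), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    c1 <- c(sample(0:8, 2, TRUE), sample(1:8, 1))
    c2 <- c(sample(0:8, 2, TRUE), sample(1:8, 1))
    gg <- c(rep(2L, c1[1]), rep(1L, c1[2]), rep(0L, c1[3]),
            rep(2L, c2[1]), rep(1L, c2[2]), rep(0L, c2[3]))
    dd <- make_ds(cbind(gg),
                  pop = rep(c("a", "b"), c(sum(c1), sum(c2))),
                  class = c(a = "wild", b = "wild"))
    th <- tryCatch(wc_fst(dd, "a", "b")$theta, error = function(e) NA)
    or <- wc_oracle_2pop(c1, c2)
    if (is.finite(or) && !is.na(th))
      expect_equal(th, or, tolerance = 1e-12)
  }
})

test_that("theta is ~0 for identical frequencies and 1 for fixed difference", {
  set.seed(9)
  g <- hwe_geno(200, rep(0.5, 50))
  ds <- make_ds(g, pop = rep(c("p1", "p2"), each = 100),
                class = c(p1 = "wild", p2 = "wild"))
  expect_lt(abs(wc_fst(ds, "p1", "p2")$theta), 0.01)
  gfix <- cbind(rep(c(0L, 2L), each = 10))
  dsf <- make_ds(gfix, pop = rep(c("p1", "p2"), each = 10),
                 class = c(p1 = "wild", p2 = "selected"))
  expect_equal(wc_fst(dsf, "p1", "p2")$theta, 1)
})

test_that("permuting labels within one panmictic pool drives theta to ~0", {
  set.seed(23)
  g <- hwe_geno(120, stats::runif(150, 0.2, 0.8))
  thetas <- vapply(1:5, function(i) {
    pop <- sample(rep(c("x", "y"), each = 60))
    ds <- make_ds(g, pop = pop, class = c(x = "wild", y = "wild"))
    wc_fst(ds, "x", "y")$theta
  }, numeric(1))
  expect_lt(abs(mean(thetas)), 0.005)
})

test_that("group FST rank order reproduces the domestication pattern", {
  sim <- demo_sim()
  gm <- fst_group_means(wc_fst(sim$ds), sim$ds$pop_class)
  v <- stats::setNames(gm$mean_fst, gm$contrast)
  expect_lt(v["wild-wild"], v["wild-selected"])
  expect_lt(v["wild-selected"], v["selected-selected"])
})

test_that("diversity is lower and relatedness higher in bred strains", {
  sim <- demo_sim()
  d <- diversity(sim$ds)
  expect_lt(mean(d$He[d$class == "selected"]),
            mean(d$He[d$class == "wild"]))
  expect_lt(mean(d$Ar[d$class == "selected"]),
            mean(d$Ar[d$class == "wild"]))
  r_wild <- ritland_relatedness(sim$ds, "wild1")$mean
  r_sel <- ritland_relatedness(sim$ds, "selB")$mean
  expect_gt(r_sel, r_wild)
})
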