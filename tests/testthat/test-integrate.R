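fake_annotations <- function(universe, term_map) {
  mg <- data.frame(marker_id = universe,
                   gene_id = paste0("g_", universe))
  gt <- do.call(rbind, lapply(names(term_map), function(tm)
    data.frame(gene_id = paste0("g_", term_map[[tm]]), term_id = tm)))
  list(marker_gene = mg, gene_term = gt)
}

test_that("enrichment p-values match the tail-sum oracle exactly", {
  universe <- sprintf("u%04d", 1:2000)
  in_term <- universe[1:100]
  candidates <- c(universe[1:20], universe[501:530])   # 20 of 50 in term
  ann <- fake_annotations(universe, list(T1 = in_term))
  e <- enrich(candidates, universe, ann)
  expect_equal(e$p_hypergeom[e$term_id == "T1"],
               hyper_tail_oracle(20, 100, 2000, 50), tolerance = 1e-10)
  set.seed(14)
  for (i in 1:10) {
    ku <- sample(20:400, 1)
    term <- sample(universe, ku)
    cand <- sample(universe, sample(20:200, 1))
    ann2 <- fake_annotations(universe, list(TX = term))
    e2 <- enrich(cand, universe, ann2)
    expect_equal(e2$p_hypergeom[e2$term_id == "TX"],
                 hyper_tail_oracle(sum(cand %in% term), ku, 2000,
                                   length(cand)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate enrichment cases behave sensibly", {
  universe <- sprintf("u%03d", 1:200)
  ann <- fake_annotations(universe, list(T1 = universe[1:50]))
  # candidates = universe: p = 1 for every term
  e <- enrich(universe, universe, ann)
  expect_equal(e$p_hypergeom, 1)
  # a term absent from candidates is never flagged
  e2 <- enrich(universe[51:80], universe, ann)
  expect_false(any(e2$enriched))
  expect_gte(e2$p_hypergeom[1], 0.5)
  expect_error(enrich(universe[1:5], character(0), ann), "universe")
})

test_that("ellipse areas converge to the chi-square expectation", {
  set.seed(99)
  # isotropic Gaussian scores with known sigma: area -> pi * 5.991 * sigma^2
  sigma <- 2
  scores <- matrix(stats::rnorm(4000 * 2, 0, sigma), ncol = 2)
  cv <- stats::cov(scores)
  ev <- eigen(cv, symmetric = TRUE)$values
  area <- pi * sqrt(ev[1] * stats::qchisq(0.95, 2)) *
    sqrt(ev[2] * stats::qchisq(0.95, 2))
  expect_equal(area, pi * 5.991 * sigma^2, tolerance = 0.08)
  expect_equal(stats::qchisq(0.95, 2), 5.991, tolerance = 1e-3)
})

test_that("per-population ellipses rank dispersion correctly", {
  sim <- demo_sim()
  cn <- demo_qc()$clumped
  ell <- pca_ellipses(cn)
  expect_true(all(ell$A >= ell$B))
  expect_equal(mean(ell$standardized_area), 0, tolerance = 1e-10)
  # a substructured population disperses more in PC space
  set.seed(2)
  p0 <- stats::runif(80, 0.3, 0.7)
  g <- hwe_geno(60, p0)
  ds <- make_ds(g, pop = rep(c("a", "b"), each = 30),
                class = c(a = "wild", b = "wild"))
  # population b: two internal sub-clusters with shifted frequencies
  ds$geno[31:45, 1:40] <- hwe_geno(15, pmin(p0[1:40] + 0.3, 0.95))
  ds$geno[46:60, 1:40] <- hwe_geno(15, pmax(p0[1:40] - 0.3, 0.05))
  e2 <- pca_ellipses(ds)
  expect_gt(e2$standardized_area[e2$pop == "b"],
            e2$standardized_area[e2$pop == "a"])
})

test_that("Shannon admixture index hits its exact endpoints", {
  q1 <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(shannon_admixture(q1, c("p", "p"))$shannon_H, 0)
  K <- 4
  qu <- matrix(1 / K, 3, K)
  expect_equal(shannon_admixture(qu, rep("p", 3))$shannon_H, log(K))
})

test_that("ellipse ANOVA recovers a constructed admixture effect", {
  set.seed(10)
  rec <- data.frame(shannon_H = stats::runif(16, 0, 1.5),
                    relatedness = stats::runif(16, 0, 0.5))
  rec$standardized_area <- 2 * rec$shannon_H + stats::rnorm(16, 0, 0.05)
  a <- ellipse_anova(rec)
  expect_lt(a["shannon_H", "Pr(>F)"], 1e-6)
  expect_gt(a["relatedness", "Pr(>F)"], 0.01)
  ai <- ellipse_anova(rec, interaction = TRUE)
  expect_gt(ai["shannon_H:relatedness", "Pr(>F)"], 0.001)
  expect_error(ellipse_anova(rec[1:4, ]), ">= 6")
})

test_that("null ellipse ANOVA p-values are uniform", {
  set.seed(60)
  pv <- replicate(400, {
    rec <- data.frame(shannon_H = stats::runif(12),
                      relatedness = stats::runif(12),
                      standardized_area = stats::rnorm(12))
    ellipse_anova(rec)["shannon_H", "Pr(>F)"]
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("report group means recompute from the per-population rows", {
  ref <- reference_diversity_ne()
  gm <- summary_group_means(ref)
  expect_equal(gm$wild_ne_mean, 13616.4, tolerance = 1e-4)
  expect_equal(unname(gm$selected["Ne"]), 46.72, tolerance = 1e-2)
  expect_equal(unname(gm$wild["Ar"]), 1.852, tolerance = 1e-3)
  # means equal hand-computed means of their columns on any input
  sub <- ref[ref$group == "selected", ]
  expect_equal(unname(gm$selected["He"]), mean(sub$He))
})
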