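test_that("window parameters follow the printed formulas", {
  wp <- compute_window_params(141676, 539, 0.24, alpha = 0.05, n_out = 0)
  expect_equal(wp$L, 78L)   # ceil(ln(0.05 / (141676*539)) / ln(0.76))
  expect_equal(wp$t, 0.012) # (0+1)/78 truncated to 3 decimals
  # L is monotone decreasing in mean heterozygosity
  Ls <- vapply(seq(0.05, 0.9, by = 0.05), function(h)
    compute_window_params(1e5, 500, h)$L, integer(1))
  expect_true(all(diff(Ls) <= 0))
  expect_error(compute_window_params(100, 10, 0), "heterozygosity")
})

test_that("trivial individuals: fully homozygous and alternating hets", {
  pos <- sort(sample.int(3e6, 300))
  prm <- roh_params(L = 30L, t = 0.033)
  hom <- domestiscan:::roh_scan_chrom(rep(0L, 300), pos, 30L, 0.033, prm)
  expect_equal(nrow(hom), 1)
  expect_equal(hom$start_bp, pos[1])
  expect_equal(hom$end_bp, pos[300])
  het <- domestiscan:::roh_scan_chrom(rep(c(0L, 1L), 150), pos, 30L, 0.033,
                                      prm)
  expect_equal(nrow(het), 0)
})

test_that("a planted homozygous tract is recovered with its length class", {
  set.seed(77)
  pos <- sort(sample.int(6e6, 600))
  geno <- stats::rbinom(600, 2, 0.5)   # heterozygous background
  tract <- which(pos >= 2e6 & pos <= 5e6)[1:250]
  tract <- tract[!is.na(tract)]
  geno[tract] <- 0L
  geno[tract[120]] <- 1L               # one embedded heterozygote
  prm <- roh_params(L = 40L, t = 0.025)
  segs <- domestiscan:::roh_scan_chrom(geno, pos, 40L, 0.025, prm)
  expect_equal(nrow(segs), 1)
  expect_gte(segs$length_bp, 2e6)
  expect_equal(as.character(roh_length_class(segs$length_bp)), "2-4Mb")
  # boundaries within one window of the truth
  expect_lt(abs(segs$start_bp - pos[tract[1]]), pos[tract[1] + 40] - pos[tract[1]])
  orc <- roh_oracle_chrom(geno, pos, 40L, 0.025, prm)
  expect_equal(segs$start_bp, unname(orc[1, "start"]))
  expect_equal(segs$end_bp, unname(orc[1, "end"]))
})

test_that("the window caller equals the brute-force oracle", {
  set.seed(19)
  for (rep in 1:50) {
    m <- sample(80:400, 1)
    pos <- sort(sample.int(4e6, m))
    # blocky genotypes: alternating homozygous-ish and heterozygous spans
    geno <- integer(m)
    i <- 1
    while (i <= m) {
      k <- min(sample(10:120, 1), m - i + 1)
      geno[i:(i + k - 1)] <- if (stats::runif(1) < 0.5)
        stats::rbinom(k, 1, 0.05) * 2L else stats::rbinom(k, 2, 0.5)
      i <- i + k
    }
    geno[sample(m, round(0.03 * m))] <- NA
    L <- sample(10:40, 1)
    t <- floor(1000 / L) / 1000
    prm <- roh_params(min_len_bp = sample(c(1e5, 2e5, 4e5), 1),
                      max_gap_bp = sample(c(5e5, 1e6), 1),
                      L = L, t = t)
    mine <- domestiscan:::roh_scan_chrom(geno, pos, L, t, prm)
    orc <- roh_oracle_chrom(geno, pos, L, t, prm)
    expect_equal(nrow(mine), nrow(orc))
    if (nrow(mine) && nrow(orc)) {
      expect_equal(mine$start_bp, unname(orc[, "start"]))
      expect_equal(mine$end_bp, unname(orc[, "end"]))
      expect_equal(mine$n_snps, unname(orc[, "n"]))
    }
  }
})

test_that("F_ROH arithmetic and degenerate inputs", {
  segs <- data.frame(sample = c("a", "a", "b"),
                     length_bp = c(50e6, 18.4e6, 0.5e6))
  fr <- froh(segs, samples = c("a", "b", "c"), l_total_bp = 684e6,
             min_len_bp = 1e6)
  expect_equal(fr$f_roh[fr$sample == "a"], 68.4e6 / 684e6)
  expect_equal(fr$f_roh[fr$sample == "b"], 0)   # below the 1 Mb cutoff
  expect_equal(fr$f_roh[fr$sample == "c"], 0)   # no segments at all
  expect_error(froh(segs, c("a"), 0), "positive")
})

test_that("the simulated homozygote bounds every individual's total", {
  sim <- demo_sim()
  full <- demo_qc()$full
  segs <- call_roh(full, "selB", qc = FALSE)
  wp <- attr(segs, "params")
  ltot <- roh_l_total(full$map, wp$L, wp$t)
  expect_gt(ltot, 0)
  if (nrow(segs)) {
    per <- tapply(segs$length_bp, segs$sample, sum)
    expect_true(all(per <= ltot))
  }
})

test_that("captive strains carry more F_ROH than wild populations", {
  sim <- demo_sim()
  full <- demo_qc()$full
  segs <- list(); ids <- character(0)
  for (p in unique(full$pop)) {
    s <- call_roh(full, p, qc = FALSE)
    segs[[p]] <- s
    ids <- c(ids, full$sample_ids[pop_samples(full, p)])
  }
  wp <- attr(segs[[1]], "params")
  all_segs <- do.call(rbind, segs)
  fr <- froh(all_segs, ids, roh_l_total(full$map, wp$L, wp$t))
  cls <- full$pop_class[full$pop[match(fr$sample, full$sample_ids)]]
  kw <- stats::kruskal.test(fr$f_roh, factor(cls))
  expect_lt(kw$p.value, 0.01)
  expect_gt(mean(fr$f_roh[cls == "selected"]),
            mean(fr$f_roh[cls == "wild"]))
})

test_that("F_ROH tracks pedigree inbreeding across strain individuals", {
  sim <- demo_sim()
  full <- demo_qc()$full
  strains <- c("selA", "selB", "selC")   # >= 3 captive generations
  seg_list <- lapply(strains, function(p) call_roh(full, p, qc = FALSE))
  wp <- attr(seg_list[[1]], "params")
  segs <- do.call(rbind, seg_list)
  ids <- unlist(lapply(strains, function(p)
    full$sample_ids[pop_samples(full, p)]))
  fr <- froh(segs, ids, roh_l_total(full$map, wp$L, wp$t))
  truth_f <- unlist(lapply(sim$truth[strains], `[[`, "f_pedigree"))
  names(truth_f) <- unlist(lapply(strains, function(p)
    sim$ds$sample_ids[pop_samples(sim$ds, p)]))
  common <- intersect(fr$sample, names(truth_f))
  # the demo genome is compact (2.5 Morgans), so Mendelian sampling noise
  # caps the attainable correlation with the pedigree expectation; the
  # full-strength check runs on an oyster-scale genome in the acceptance
  # suite
  expect_gt(stats::cor(fr$f_roh[match(common, fr$sample)],
                       truth_f[common]), 0.6)
})

test_that("incidence track flags shared tracts and stays zero without", {
  map <- data.frame(id = paste0("m", 1:100), chrom = "chr1",
                    pos = seq_len(100) * 10000L)
  segs <- data.frame(sample = c("a", "b"), pop = "p", chrom = "chr1",
                     start_bp = 200000L, end_bp = 500000L,
                     n_snps = 31L, length_bp = 300000L)
  inc <- roh_incidence(segs, map, n_individuals = 2)
  inside <- map$pos >= 2e5 & map$pos <= 5e5
  expect_true(all(inc$incidence$incidence[inside] == 1))
  expect_true(all(inc$incidence$incidence[!inside] == 0))
  expect_gte(nrow(inc$islands), 1)
  none <- roh_incidence(segs[0, ], map, n_individuals = 2)
  expect_true(all(none$incidence$incidence == 0))
  expect_equal(nrow(none$islands), 0)
})
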