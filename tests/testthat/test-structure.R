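two_pop_gm <- function(pop1_counts, pop2_counts) {
  # counts: c(n_ref_hom, n_het, n_alt_hom) per population, single locus
  g <- c(rep(0L, pop1_counts[1]), rep(1L, pop1_counts[2]), rep(2L, pop1_counts[3]),
         rep(0L, pop2_counts[1]), rep(1L, pop2_counts[2]), rep(2L, pop2_counts[3]))
  gm <- make_gm(cbind(g))
  pm <- make_popmap(gm$sample_ids, rep(c("p1", "p2"), c(sum(pop1_counts),
                                                        sum(pop2_counts))))
  list(gm = gm, pm = pm)
}

test_that("Weir-Cockerham theta matches an independent evaluation of the 1984 formulas", {
  # fixed difference: theta = 1 exactly
  fx <- two_pop_gm(c(10, 0, 0), c(0, 0, 10))
  wc <- wc_fst_per_locus(fx$gm, fx$pm)
  expect_equal(wc$theta, 1)

  # the 6/3/1 vs 1/3/6 table: frozen value from the scalar oracle (0.36)
  fx <- two_pop_gm(c(6, 3, 1), c(1, 3, 6))
  wc <- wc_fst_per_locus(fx$gm, fx$pm)
  orc <- oracle_wc84(rbind(c(6, 3, 1), c(1, 3, 6)))
  expect_equal(wc$theta, orc$theta)
  expect_equal(wc$theta, 0.36)
  expect_equal(wc$a, orc$a)
  expect_equal(wc$b, orc$b)
  expect_equal(wc$c, orc$c)

  # random multi-population loci against the same oracle
  set.seed(17)
  for (rep_i in 1:5) {
    counts <- matrix(rpois(9, 6) + 1, 3, 3)
    g <- unlist(lapply(1:3, function(i) rep(0:2, counts[i, ])))
    gm <- make_gm(cbind(as.integer(g)))
    pm <- make_popmap(gm$sample_ids, rep(paste0("p", 1:3), rowSums(counts)))
    wc <- wc_fst_per_locus(gm, pm)
    orc <- oracle_wc84(counts)
    expect_equal(wc$theta, orc$theta, tolerance = 1e-12)
  }

  # one panmictic pool split in two, many samples: theta near zero
  set.seed(18)
  g <- matrix(rbinom(400 * 50, 2, 0.3), 400, 50)
  gm <- make_gm(g)
  pm <- make_popmap(gm$sample_ids, rep(c("a", "b"), each = 200))
  expect_lt(abs(multilocus_fst(gm, pm)), 0.01)
})

test_that("undefined loci (single informative population, monomorphic) are flagged", {
  g <- cbind(c(rep(0L, 10), rep(NA_integer_, 9), 1L),   # pop2 has 1 call
             rep(0L, 20),                               # monomorphic
             c(rep(0L, 10), rep(2L, 10)))
  gm <- make_gm(g)
  pm <- make_popmap(gm$sample_ids, rep(c("p1", "p2"), each = 10))
  wc <- wc_fst_per_locus(gm, pm)
  expect_true(is.na(wc$theta[1]))
  expect_true(is.na(wc$theta[2]))
  expect_equal(wc$theta[3], 1)
  expect_error(wc_fst_per_locus(gm, make_popmap(gm$sample_ids,
                                                rep("p1", 20))), "2 populations")
})

test_that("multi-locus theta is a ratio of sums, invariant to locus order", {
  set.seed(19)
  sim <- simulate_island_genotypes(sim_config(
    populations = data.frame(population = c("a", "b", "c"), group = "g",
                             n = c(12L, 15L, 10L)),
    n_loci = 150L, target_fst = 0.1, outlier_fraction = 0,
    missing_rate = 0.05, seed = 41L))
  wc <- wc_fst_per_locus(sim$genotypes, sim$popmap)
  ok <- !is.na(wc$a)
  expect_equal(multilocus_fst(sim$genotypes, sim$popmap),
               sum(wc$a[ok]) / sum(wc$a[ok] + wc$b[ok] + wc$c[ok]))
  perm <- sample(150)
  expect_equal(multilocus_fst(sim$genotypes[, perm], sim$popmap),
               multilocus_fst(sim$genotypes, sim$popmap))
})

test_that("pairwise FST permutation tests behave at the extremes and reproduce by seed", {
  # duplicated population: theta ~ 0, not significant
  set.seed(23)
  half <- matrix(rbinom(12 * 80, 2, 0.4), 12, 80)
  gm <- make_gm(rbind(half, half))
  pm <- make_popmap(gm$sample_ids, rep(c("a", "b"), each = 12))
  f <- suppressWarnings(pairwise_fst(gm, pm, n_perm = 199, seed = 7))
  expect_lt(f$fst["b", "a"], 0.02)
  expect_gt(f$p["b", "a"], 0.05)

  # fully fixed difference: theta = 1 and minimal attainable p
  g <- cbind(rep(c(0L, 2L), each = 10), rep(c(2L, 0L), each = 10))
  gm2 <- make_gm(g)
  pm2 <- make_popmap(gm2$sample_ids, rep(c("a", "b"), each = 10))
  f2 <- suppressWarnings(pairwise_fst(gm2, pm2, n_perm = 999, seed = 11))
  expect_equal(f2$fst["b", "a"], 1)
  expect_equal(f2$p["b", "a"], 1 / 1000)

  f3 <- suppressWarnings(pairwise_fst(gm2, pm2, n_perm = 999, seed = 11))
  expect_identical(f2$fst, f3$fst)
  expect_identical(f2$p, f3$p)
  expect_warning(pairwise_fst(gm2, pm2, n_perm = 50, seed = 1), "100 permutations")
})

test_that("AMOVA partitions sums of squares exactly as the distance-matrix oracle", {
  set.seed(29)
  calls <- matrix(sample(c(0:2, NA), 18 * 20, replace = TRUE,
                         prob = c(.4, .25, .25, .1)), 18, 20)
  gm <- make_gm(calls)
  pop <- rep(c("p1", "p2", "p3"), each = 6)
  pm <- make_popmap(gm$sample_ids, pop, group = rep(c("g1", "g1", "g2"), each = 6))
  am <- amova(gm, pm, n_perm = 49, seed = 3)
  orc <- oracle_amova_ss(calls, pop, c(p1 = "g1", p2 = "g1", p3 = "g2"))
  expect_equal(am$table$SS[1], orc$ss_ag)
  expect_equal(am$table$SS[2], orc$ss_ap)
  expect_equal(am$table$SS[3], orc$ss_wp)
  # SS additivity to machine precision
  expect_equal(am$table$SS[4], sum(am$table$SS[1:3]))
  expect_equal(am$table$SS[4], orc$ss_tot)
  # percentages from the components sum to 100
  expect_equal(sum(am$table$percent[1:3]), 100)
})

test_that("AMOVA null and extreme designs give the expected partitions", {
  # all populations identical copies of one sample set
  set.seed(30)
  block <- matrix(rbinom(6 * 40, 2, 0.5), 6, 40)
  gm <- make_gm(rbind(block, block, block, block))
  pm <- make_popmap(gm$sample_ids, rep(paste0("p", 1:4), each = 6),
                    group = rep(c("g1", "g2"), each = 12))
  am <- amova(gm, pm, n_perm = 49, seed = 5)
  expect_gt(am$table$percent[3], 99)        # essentially all within pops
  expect_lt(am$phi["phi_st"], 0.01)

  # populations fixed for alternative alleles, groups = pops: nothing within
  g <- cbind(rep(c(0L, 2L), each = 8), rep(c(2L, 0L), each = 8))
  gm2 <- make_gm(g)
  pm2 <- make_popmap(gm2$sample_ids, rep(c("a", "b"), each = 8),
                     group = rep(c("ga", "gb"), each = 8))
  am2 <- amova(gm2, pm2, n_perm = 49, seed = 5)
  expect_equal(am2$table$SS[3], 0)
  expect_equal(unname(am2$phi["phi_st"]), 1)
  expect_error(amova(gm2, make_popmap(gm2$sample_ids, rep("a", 16))),
               "2 populations")
})

test_that("outlier scan is one-sided and flags planted high-FST loci", {
  set.seed(33)
  cfg <- sim_config(populations = data.frame(population = paste0("p", 1:4),
                                             group = "g", n = rep(15L, 4)),
                    n_loci = 400L, target_fst = 0.02,
                    outlier_fraction = 0.025, outlier_fst = 0.45,
                    ld_blocks = 0L, missing_rate = 0, seed = 51L)
  sim <- simulate_island_genotypes(cfg)
  ol <- fdist_outliers(sim$genotypes, sim$popmap, n_sim = 8000, seed = 13)
  st <- ol$stats
  # loci below their bin median cannot be flagged and have p > 0.5
  low <- !is.na(st$p) & st$theta < quantile(st$theta, 0.25, na.rm = TRUE)
  expect_true(all(st$p[low] > 0.5))
  expect_false(any(st$significant[low]))
  # planted loci sit at the top of the theta distribution
  planted <- st$locus %in% sim$truth$outlier_loci
  expect_gt(median(rank(st$theta)[planted]), 0.9 * sum(!is.na(st$theta)))
  # and most are recovered
  expect_gt(mean(st$significant[planted]), 0.5)
  expect_equal(ol$n_sim, 8000L)
})
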