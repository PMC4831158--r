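test_that("pairwise differences count genotype mismatches over shared loci", {
  # identical rows differ nowhere
  gm <- make_gm(rbind(rep(1L, 10), rep(1L, 10)))
  expect_equal(pairwise_pi(gm)[1, 2], 0)

  # 3 of 10 shared loci differ -> 0.30
  a <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L)
  b <- a; b[c(1, 5, 9)] <- c(2L, 0L, 0L)
  expect_equal(pairwise_pi(make_gm(rbind(a, b)))[1, 2], 0.3)

  # a pair with no shared loci is flagged undefined
  x <- rbind(c(1L, NA), c(NA, 1L))
  pim <- pairwise_pi(make_gm(x))
  expect_true(is.na(pim[1, 2]))
  expect_equal(attr(pim, "undefined_pairs"), "s1|s2")
})

test_that("pairwise differences equal the double-loop recount and are order-invariant", {
  set.seed(13)
  calls <- matrix(sample(c(0:2, NA), 15 * 40, replace = TRUE,
                         prob = c(.4, .25, .25, .1)), 15, 40)
  gm <- make_gm(calls)
  pim <- pairwise_pi(gm)
  expect_equal(unname(pim), oracle_pairwise_pi(calls))
  expect_equal(pim, t(pim))
  expect_true(all(diag(pim) == 0))
  expect_true(all(pim >= 0 & pim <= 1, na.rm = TRUE))
  # invariant to locus and sample order
  perm_l <- sample(40); perm_s <- sample(15)
  pim2 <- pairwise_pi(gm[perm_s, perm_l])
  expect_equal(pim2, pim[perm_s, perm_s])
})

test_that("pairwise differences agree with ape's gene-distance recount on complete data", {
  skip_if_not_installed("ape")
  set.seed(14)
  calls <- matrix(sample(0:2, 12 * 30, replace = TRUE), 12, 30)
  pim <- pairwise_pi(make_gm(calls))
  d_ape <- as.matrix(ape::dist.gene(calls, method = "pairwise")) / 30
  expect_equal(unname(pim), unname(d_ape))
})

test_that("population summaries split within- and between-population pairs", {
  calls <- rbind(rep(0L, 8), rep(0L, 8),      # pop A: identical pair
                 rep(2L, 8), rep(2L, 8))      # pop B: identical, fixed other allele
  gm <- make_gm(calls)
  pm <- make_popmap(gm$sample_ids, c("A", "A", "B", "B"))
  s <- pi_by_population(pairwise_pi(gm), pm)
  expect_equal(s$within$mean[s$within$population == "A"], 0)
  # two fixed, fully diverged populations: cross-population mean is 1
  expect_equal(s$between["A", "B"], 1)
  expect_equal(s$within$min[s$within$population == "all"], 0)

  # single-sample population is flagged undefined
  pm1 <- make_popmap(gm$sample_ids, c("A", "A", "A", "C"))
  s1 <- pi_by_population(pairwise_pi(gm), pm1)
  expect_true(is.na(s1$within$mean[s1$within$population == "C"]))
})

test_that("tag-length adjustment is the documented linear rescaling", {
  # worked example: overall mean 0.392 at 1.45 SNPs per 64-bp tag -> ~0.9%
  expect_equal(round(100 * adjusted_pi(0.392, 1.45, 64), 1), 0.9)
  expect_equal(adjusted_pi(0.25, 64, 64), 0.25)    # density 1 SNP/bp: identity
  expect_equal(adjusted_pi(0, 1.4, 64), 0)
  # linear in both arguments
  expect_equal(adjusted_pi(0.2, 1.4, 64) * 6, adjusted_pi(0.6, 2.8, 64))
  expect_error(adjusted_pi(0.3, 1.4, 0), "positive")
})

test_that("locus statistics match hand counts and brute-force recomputation", {
  # 5 AA, 10 Aa, 5 aa: p = 0.5, Ho = 0.5, He = 0.5 (exact HWE proportions)
  g <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  st <- locus_stats(make_gm(cbind(g)))
  expect_equal(st$maf, 0.5)
  expect_equal(st$ho, 0.5)
  expect_equal(st$he, 0.5)
  expect_gt(st$hwe_p, 0.5)

  # monomorphic locus: He = Ho = 0 and excluded from percent-polymorphic
  st2 <- locus_stats(make_gm(cbind(rep(0L, 10), c(rep(0L, 5), rep(1L, 5)))))
  expect_equal(st2$ho[1], 0)
  expect_equal(st2$he[1], 0)
  expect_equal(unname(attr(st2, "percent_polymorphic")["overall"]), 50)

  set.seed(15)
  calls <- matrix(sample(c(0:2, NA), 20 * 25, replace = TRUE), 20, 25)
  gm <- make_gm(calls)
  st3 <- locus_stats(gm)
  for (l in sample(25, 6)) {
    g <- calls[, l]; g <- g[!is.na(g)]
    p <- sum(g) / (2 * length(g))
    expect_equal(st3$maf[l], min(p, 1 - p))
    expect_equal(st3$ho[l], mean(g == 1))
    expect_equal(st3$he[l], 2 * p * (1 - p))
    expect_equal(st3$call_rate[l], length(g) / 20)
  }
})

test_that("panmictic simulation reproduces the analytic expected pairwise difference", {
  cfg <- sim_config(populations = data.frame(population = "p1", group = "g",
                                             n = 20L),
                    n_loci = 2000L, target_fst = 0, outlier_fraction = 0,
                    ld_blocks = 0L, missing_rate = 0, seed = 31L)
  sim <- simulate_island_genotypes(cfg)
  p <- sim$truth$ancestral
  expected <- 1 - ((p^2)^2 + (2 * p * (1 - p))^2 + ((1 - p)^2)^2)
  obs <- per_locus_pi(sim$genotypes$calls)
  diff <- obs - expected
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff)))
})
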