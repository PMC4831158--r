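test_that("consensus keeps concordant shared loci only, with an audit of the rest", {
  set.seed(1)
  calls <- matrix(sample(0:2, 80, replace = TRUE), 8, 10)
  gm <- make_gm(calls)
  expect_equal(consensus_intersect(gm, gm)$locus_ids, gm$locus_ids)

  gm_b <- gm[, 1:8]                      # loci 9, 10 in A only
  # make locus 3 discordant: flip everyone in B to alt-hom
  gm_b$calls[, 3] <- 2L
  out <- consensus_intersect(gm, gm_b, af_delta = 0.05)
  expect_equal(out$locus_ids, gm$locus_ids[c(1, 2, 4:8)])
  aud <- attr(out, "consensus")
  expect_equal(aud$n_single_a, 2L)
  expect_equal(aud$n_discordant, 1L)
  expect_equal(aud$discordant_ids, "loc3")
  # calls come from the first matrix
  expect_equal(out$calls[, "loc4"], gm$calls[, "loc4"])
})

test_that("consensus requires matching sample sets", {
  gm <- make_gm(matrix(0:2, 3, 4))
  gm2 <- gm; gm2$sample_ids[1] <- "other"
  rownames(gm2$calls)[1] <- "other"
  expect_error(consensus_intersect(gm, gm2), "sample sets")
})

test_that("depth masking hides exactly the low-depth calls", {
  calls <- matrix(1L, 4, 4)
  depth <- matrix(10L, 4, 4)
  gm <- make_gm(calls, depth = depth)
  expect_equal(depth_mask(gm, 5)$calls, gm$calls)      # all deep: unchanged

  depth[2, 3] <- 4L
  gm <- make_gm(calls, depth = depth)
  out <- depth_mask(gm, 5)
  expect_true(is.na(out$calls[2, 3]))
  expect_equal(sum(is.na(out$calls)), 1L)
  expect_equal(out$locus_ids, gm$locus_ids)
  expect_error(depth_mask(make_gm(calls)), "no depth")

  # stochastic depths: masked fraction equals the empirical P(depth < 5)
  set.seed(7)
  depth <- matrix(rnbinom(400, mu = 6, size = 1), 20, 20)
  gm <- make_gm(matrix(1L, 20, 20), depth = depth)
  out <- depth_mask(gm, 5)
  expect_equal(mean(is.na(out$calls)), mean(depth < 5))
})

test_that("call-rate filter reaches the documented fixpoint", {
  # complete matrix: untouched, no removals logged
  gm <- make_gm(matrix(1L, 5, 5))
  out <- iterative_call_rate_filter(gm)
  expect_equal(dim(out), c(5L, 5L))
  expect_equal(nrow(attr(out, "iterations")), 0L)

  # one half-missing sample, loci otherwise complete: that sample goes
  calls <- matrix(1L, 6, 10)
  calls[2, 1:5] <- NA_integer_
  out <- iterative_call_rate_filter(make_gm(calls), 0.70, 0.60)
  expect_equal(out$sample_ids, paste0("s", c(1, 3:6)))
  expect_equal(length(out$locus_ids), 10L)
})

test_that("adversarial call-rate fixpoint matches the exhaustive-search optimum", {
  # removing the bad sample rescues loci that would otherwise fail
  calls <- matrix(1L, 6, 6)
  calls[1, 1:4] <- NA_integer_    # sample 1 bad AND drags loci 1-4 down
  calls[2, 1] <- NA_integer_
  gm <- make_gm(calls)
  out <- iterative_call_rate_filter(gm, 0.70, 0.85)
  best <- oracle_callrate_fixpoints(calls, 0.70, 0.85)
  expect_equal(length(best), 1L)
  expect_equal(match(out$sample_ids, gm$sample_ids), best[[1]]$samples)
  expect_equal(match(out$locus_ids, gm$locus_ids), best[[1]]$loci)
  # and the result is itself a valid fixpoint
  expect_true(all(rowMeans(!is.na(out$calls)) >= 0.70))
  expect_true(all(colMeans(!is.na(out$calls)) >= 0.85))
})

test_that("MAF filter applies an inclusive 5% threshold over non-missing calls", {
  # 50 samples: 4 alt copies / 100 -> MAF 0.04 (out); 5/100 -> 0.05 (kept)
  calls <- cbind(c(rep(1L, 4), rep(0L, 46)),
                 c(rep(1L, 5), rep(0L, 45)),
                 rep(1L, 50))
  out <- maf_filter(make_gm(calls), 0.05)
  expect_equal(out$locus_ids, c("loc2", "loc3"))
  expect_equal(attr(out, "maf_removed"), "loc1")

  # all-missing locus removed and counted separately
  calls2 <- cbind(rep(NA_integer_, 10), rep(1L, 10))
  out2 <- maf_filter(make_gm(calls2), 0.05)
  expect_equal(attr(out2, "n_all_missing"), 1L)

  # random matrix: retained set equals a direct per-locus recount
  set.seed(11)
  calls3 <- matrix(sample(c(0:2, NA), 600, replace = TRUE,
                          prob = c(.45, .2, .25, .1)), 20, 30)
  gm3 <- make_gm(calls3)
  keep <- vapply(seq_len(30), function(l) {
    g <- calls3[, l]; g <- g[!is.na(g)]
    p <- sum(g) / (2 * length(g))
    length(g) > 0 && min(p, 1 - p) >= 0.05
  }, logical(1))
  expect_equal(maf_filter(gm3, 0.05)$locus_ids, gm3$locus_ids[keep])
})

test_that("exact HWE p-values match a conditional Monte-Carlo oracle", {
  # oracle: shuffle the 2n alleles into random diploid pairings and count
  # heterozygote counts at least as large as observed
  mc_p <- function(n_rr, n_het, n_aa, reps = 40000) {
    n <- n_rr + n_het + n_aa
    alleles <- rep(0:1, c(2 * n_rr + n_het, 2 * n_aa + n_het))
    hits <- 0
    for (i in seq_len(reps)) {
      a <- matrix(sample(alleles), ncol = 2)
      hits <- hits + (sum(a[, 1] != a[, 2]) >= n_het)
    }
    hits / reps
  }
  set.seed(3)
  cases <- list(c(5, 5, 0), c(3, 4, 3), c(8, 2, 2), c(1, 9, 2))
  for (cs in cases) {
    p_exact <- hwe_exact_test(cs[1], cs[2], cs[3], "excess")
    p_mc <- mc_p(cs[1], cs[2], cs[3])
    se <- sqrt(p_mc * (1 - p_mc) / 40000)
    expect_lt(abs(p_exact - p_mc), 4 * se + 1e-4)
  }
})

test_that("heterozygote-excess filter is one-sided", {
  # all-heterozygous locus in 20 samples: removed
  all_het <- matrix(1L, 20, 1)
  expect_lt(hwe_exact_test(0, 20, 0), 1e-4)
  out <- excess_het_filter(make_gm(cbind(all_het, rep(0:1, 10))), 0.01)
  expect_equal(attr(out, "het_removed"), "loc1")

  # exact HWE proportions: retained
  hwe_locus <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  expect_equal(length(excess_het_filter(make_gm(cbind(hwe_locus)))$locus_ids), 1L)

  # strong heterozygote DEFICIT: retained (test is one-sided)
  deficit <- c(rep(0L, 10), rep(2L, 10))
  expect_equal(length(excess_het_filter(make_gm(cbind(deficit)))$locus_ids), 1L)
})

test_that("LD pruning removes one of each linked pair and spares independent loci", {
  set.seed(5)
  base <- matrix(rbinom(40 * 10, 2, 0.4), 40, 10)
  base[, 4] <- base[, 3]          # exact duplicate: r2 = 1
  gm <- make_gm(base)
  out <- ld_prune(gm, ld_window = 10)
  expect_false("loc4" %in% out$locus_ids)   # later member removed
  expect_true("loc3" %in% out$locus_ids)

  # two independent loci at large n: both retained
  set.seed(6)
  ind <- matrix(rbinom(2000, 2, 0.5), 1000, 2)
  expect_equal(length(ld_prune(make_gm(ind))$locus_ids), 2L)

  expect_error(ld_prune(make_gm(matrix(0:2, 4, 3), position = c(300L, 100L, 200L))),
               "sorted")
})

test_that("LD pruning matches brute-force all-pairs pruning on a planted fixture", {
  set.seed(8)
  calls <- matrix(rbinom(60 * 10, 2, 0.5), 60, 10)
  calls[, 2] <- calls[, 1]                          # pair 1-2
  calls[, 7] <- calls[, 5]                          # pair 5-7
  calls[, 10] <- calls[, 9]                         # pair 9-10
  gm <- make_gm(calls)
  out <- ld_prune(gm, ld_window = 10, ld_dprime_alpha = 1e-12, ld_r2_max = 0.2)
  # oracle: independent all-pairs scan on dosage correlation, removing the
  # later locus of every flagged pair
  alive <- rep(TRUE, 10)
  for (i in 1:9) for (j in (i + 1):10) {
    if (alive[i] && alive[j] && cor(calls[, i], calls[, j])^2 > 0.2)
      alive[j] <- FALSE
  }
  expect_equal(out$locus_ids, gm$locus_ids[alive])
})

test_that("every cascade filter is idempotent and the cascade never grows", {
  sim <- simulate_island_genotypes(sim_config(
    populations = data.frame(population = c("a", "b"), group = "g",
                             n = c(10L, 10L)),
    n_loci = 120L, n_scaffolds = 12L, missing_rate = 0.08, seed = 21L))
  gm <- sim$genotypes
  filters <- list(
    function(g) depth_mask(g, 5),
    function(g) iterative_call_rate_filter(g, 0.7, 0.9),
    function(g) maf_filter(g, 0.05),
    function(g) excess_het_filter(g, 0.01),
    function(g) ld_prune(g, 20, 0.01, 0.2))
  for (f in filters) {
    once <- f(gm)
    twice <- f(once)
    expect_equal(twice$calls, once$calls)
    expect_equal(twice$locus_ids, once$locus_ids)
    gm <- once
  }

  pair <- simulate_caller_pair(sim$genotypes, seed = 4)
  res <- run_cascade(pair$gm_a, pair$gm_b)
  rep <- res$report
  expect_true(all(rep$samples_out <= rep$samples_in))
  expect_true(all(rep$loci_out <= rep$loci_in))
})

test_that("a clean matrix passes the cascade untouched; maf_min 0 removes nothing", {
  set.seed(9)
  calls <- matrix(rbinom(200 * 20, 2, 0.5), 200, 20)
  gm <- make_gm(calls, depth = matrix(50L, 200, 20))
  res <- run_cascade(gm, gm, cascade_params(ld_dprime_alpha = 1e-6))
  expect_equal(res$genotypes$calls, gm$calls)
  expect_equal(nrow(res$report), 6L)

  out <- maf_filter(gm, 0)
  expect_equal(out$locus_ids, gm$locus_ids)
})
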