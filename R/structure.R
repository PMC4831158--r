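# Per-pop per-locus genotype summaries: counts of non-missing calls,
# alt-allele copies and heterozygotes, as pops x loci matrices.
pop_counts <- function(calls, pop) {
  pop <- factor(pop)
  M <- (!is.na(calls)) * 1L
  K <- calls; K[is.na(K)] <- 0L
  H <- (calls == 1L & !is.na(calls)) * 1L
  list(n = rowsum(M, pop), k = rowsum(K, pop), h = rowsum(H, pop),
       pops = levels(pop))
}

# Weir-Cockerham (1984) variance components from pops x loci count
# matrices. Pops with fewer than 2 genotyped samples at a locus are
# excluded there; loci left with < 2 such pops, or monomorphic overall,
# get NA components.
wc_components_from_counts <- function(n, k, h) {
  m <- n >= 2
  nm <- n * m
  nsum <- colSums(nm)
  r <- colSums(m)
  valid <- r >= 2
  nbar <- nsum / r
  nc <- (nsum - colSums(nm^2) / nsum) / (r - 1)
  pbar <- colSums(k * m) / (2 * nsum)
  p <- k / (2 * n)
  p0 <- ifelse(m, p, 0)
  s2 <- colSums(nm * sweep(p0, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(h * m) / nsum
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  bad <- !valid | !is.finite(a + b + c) | pbar <= 0 | pbar >= 1
  a[bad] <- b[bad] <- c[bad] <- NA_real_
  list(a = a, b = b, c = c, theta = a / (a + b + c),
       n_pops = r, pbar = pbar, nbar = nbar)
}

#' Per-locus Weir-Cockerham fixation index
#'
#' Estimates the among-population variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) of Weir and Cockerham's 1984 estimator at every locus,
#' with theta = a / (a + b + c). Loci where fewer than two populations
#' have two or more genotyped samples, or that are monomorphic overall,
#' are flagged undefined (`NA`).
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param populations optional subset of populations to use.
#' @return data frame: locus, a, b, c, theta, n_pops, he (expected total
#'   heterozygosity 2 p(1-p) from the weighted mean allele frequency).
#' @export
wc_fst_per_locus <- function(gm, popmap, populations = NULL) {
  pm <- match_popmap(gm, popmap)
  keep <- if (is.null(populations)) rep(TRUE, nrow(pm))
          else pm$population %in% populations
  pop <- pm$population[keep]
  if (length(unique(pop)) < 2) stop("need at least 2 populations")
  pc <- pop_counts(gm$calls[keep, , drop = FALSE], pop)
  wc <- wc_components_from_counts(pc$n, pc$k, pc$h)
  data.frame(locus = gm$locus_ids, a = wc$a, b = wc$b, c = wc$c,
             theta = wc$theta, n_pops = wc$n_pops,
             he = 2 * wc$pbar * (1 - wc$pbar), row.names = NULL)
}

# ratio-of-sums multi-locus theta from component vectors
ratio_of_sums_theta <- function(a, b, c) {
  ok <- is.finite(a + b + c)
  sum(a[ok]) / sum(a[ok] + b[ok] + c[ok])
}

#' Multi-locus Weir-Cockerham theta
#'
#' Combines per-locus variance components as a ratio of sums
#' (sum(a) / sum(a+b+c)), the standard multi-locus estimator; undefined
#' loci are skipped.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param populations optional subset of populations.
#' @return a single theta value.
#' @export
multilocus_fst <- function(gm, popmap, populations = NULL) {
  wc <- wc_fst_per_locus(gm, popmap, populations)
  ratio_of_sums_theta(wc$a, wc$b, wc$c)
}

# multi-locus theta for two populations over permuted memberships.
# calls: samples x loci for the two pops only; in1: logical, observed
# pop-1 membership. Returns c(theta_obs, theta_perm...). Chunked matrix
# products keep memory bounded.
pair_theta_perm <- function(calls, in1, n_perm) {
  n <- nrow(calls); L <- ncol(calls); n1 <- sum(in1)
  M <- t((!is.na(calls)) * 1)
  K <- calls; K[is.na(K)] <- 0L; K <- t(K)
  H <- t((calls == 1L & !is.na(calls)) * 1)
  nt <- rowSums(M); kt <- rowSums(K); ht <- rowSums(H)
  block <- max(1L, min(n_perm + 1L, as.integer(2e6 / max(L, 1))))
  cols <- c(list(as.numeric(in1)),
            replicate(n_perm, {v <- numeric(n); v[sample.int(n, n1)] <- 1; v},
                      simplify = FALSE))
  theta <- numeric(n_perm + 1)
  for (start in seq(1, n_perm + 1, by = block)) {
    idx <- start:min(start + block - 1, n_perm + 1)
    P <- matrix(unlist(cols[idx]), nrow = n)
    N1 <- M %*% P; K1 <- K %*% P; H1 <- H %*% P
    N2 <- nt - N1; K2 <- kt - K1; H2 <- ht - H1
    ok <- N1 >= 2 & N2 >= 2
    nsum <- N1 + N2
    nbar <- nsum / 2
    nc <- nsum - (N1^2 + N2^2) / nsum
    pbar <- (K1 + K2) / (2 * nsum)
    p1 <- K1 / (2 * N1); p2 <- K2 / (2 * N2)
    s2 <- (N1 * (p1 - pbar)^2 + N2 * (p2 - pbar)^2) / nbar
    hbar <- (H1 + H2) / nsum
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    use <- ok & is.finite(a + b + cc) & pbar > 0 & pbar < 1
    a[!use] <- 0; b[!use] <- 0; cc[!use] <- 0
    theta[idx] <- colSums(a) / colSums(a + b + cc)
  }
  theta
}

#' Pairwise population FST with permutation tests
#'
#' Multi-locus Weir-Cockerham theta for every population pair, with
#' significance from permuting individuals between the two populations:
#' p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1). Negative
#' multi-locus estimates are kept as computed in `fst_raw` and shown
#' truncated at zero in `fst` (the conventional reporting).
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param n_perm number of permutations (a value below 100 warns).
#' @param seed RNG seed for reproducible permutations.
#' @return list of class `fst_result`: `fst` and `fst_raw` (population x
#'   population matrices, upper triangle `NA`), `p` (permutation
#'   p-values), `n_perm`, `seed`.
#' @export
pairwise_fst <- function(gm, popmap, n_perm = 10000L, seed = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  pm <- match_popmap(gm, popmap)
  pops <- unique(pm$population)
  if (length(pops) < 2) stop("need at least 2 populations")
  np <- length(pops)
  fst_raw <- p_mat <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  with_seed(seed, {
    for (a in 2:np) for (b in seq_len(a - 1)) {
      sel <- pm$population %in% c(pops[a], pops[b])
      calls <- gm$calls[sel, , drop = FALSE]
      th <- pair_theta_perm(calls, pm$population[sel] == pops[a], n_perm)
      if (!is.finite(th[1])) next   # no shared polymorphic loci
      fst_raw[a, b] <- th[1]
      p_mat[a, b] <- p_mat[b, a] <- perm_p(sum(th[-1] >= th[1]), n_perm)
    }
  })
  fst <- pmax(fst_raw, 0)
  structure(list(fst = fst, fst_raw = fst_raw, p = p_mat,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "fst_result")
}

#' Per-locus FST permutation test
#'
#' Permutes individuals among all populations and computes each locus's
#' theta in every permutation; the per-locus p-value is
#' (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1). Used to flag the
#' "significant FST" loci passed on to isolation-by-distance analysis.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param populations optional subset of populations.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return data frame: locus, theta, he, p.
#' @export
locus_fst_test <- function(gm, popmap, populations = NULL,
                           n_perm = 1000L, seed = NULL) {
  pm <- match_popmap(gm, popmap)
  keep <- if (is.null(populations)) rep(TRUE, nrow(pm))
          else pm$population %in% populations
  pop <- pm$population[keep]
  calls <- gm$calls[keep, , drop = FALSE]
  obs <- wc_components_from_counts_of(calls, pop)
  hits <- numeric(ncol(calls))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- wc_components_from_counts_of(calls, sample(pop))
      hits <- hits + (!is.na(perm$theta) & !is.na(obs$theta) &
                        perm$theta >= obs$theta)
    }
  })
  data.frame(locus = gm$locus_ids, theta = obs$theta,
             he = 2 * obs$pbar * (1 - obs$pbar),
             p = ifelse(is.na(obs$theta), NA_real_, perm_p(hits, n_perm)),
             row.names = NULL)
}

wc_components_from_counts_of <- function(calls, pop) {
  pc <- pop_counts(calls, pop)
  wc_components_from_counts(pc$n, pc$k, pc$h)
}

# Per-locus allele-level sums of squares from 0/1 allele copies:
# for a set with m copies of which k are "1", SS = k - k^2/m.
# Returns summed-over-loci SS for the three strata.
amova_ss <- function(calls, pop, group_of_pop) {
  pc <- pop_counts(calls, pop)
  m_p <- 2 * pc$n                     # copies per pop per locus
  k_p <- pc$k
  grp <- factor(group_of_pop[pc$pops])
  m_g <- rowsum(m_p, grp); k_g <- rowsum(k_p, grp)
  m_t <- colSums(m_p); k_t <- colSums(k_p)
  ss0 <- function(k, m) k - k^2 / ifelse(m > 0, m, NA)
  ss_wp <- sum(ss0(k_p, m_p), na.rm = TRUE)
  ss_wg <- sum(ss0(k_g, m_g), na.rm = TRUE)
  ss_tot <- sum(ss0(k_t, m_t), na.rm = TRUE)
  list(ss_ag = ss_tot - ss_wg, ss_ap = ss_wg - ss_wp, ss_wp = ss_wp,
       ss_tot = ss_tot)
}

amova_phi <- function(calls, pop, group_of_pop) {
  ss <- amova_ss(calls, pop, group_of_pop)
  tab_pop <- table(pop)
  pops <- names(tab_pop)
  grp <- group_of_pop[pops]
  n_pg <- 2 * as.numeric(tab_pop)            # copies per pop (by individuals)
  N_g <- tapply(n_pg, grp, sum)
  N <- sum(n_pg)
  P <- length(pops); G <- length(unique(grp))
  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  ms <- c(ag = ss$ss_ag / df[["ag"]], ap = ss$ss_ap / df[["ap"]],
          wp = ss$ss_wp / df[["wp"]])
  sum_npg2_g <- tapply(n_pg^2, grp, sum)
  sig_c <- unname(ms["wp"])
  # degenerate designs: one population per group leaves no among-pops-
  # within-groups stratum; a single group leaves no among-group stratum
  if (P > G) {
    n_b <- (N - sum(sum_npg2_g / N_g)) / (P - G)
    sig_b <- unname((ms["ap"] - sig_c) / n_b)
  } else sig_b <- 0
  if (G > 1) {
    n_ab <- (sum(sum_npg2_g / N_g) - sum(n_pg^2) / N) / (G - 1)
    n_a <- (N - sum(N_g^2) / N) / (G - 1)
    sig_a <- unname((ms["ag"] - sig_c - n_ab * sig_b) / n_a)
  } else sig_a <- 0
  tot <- sig_a + sig_b + sig_c
  list(ss = ss, df = df, ms = ms,
       sigma = c(a = sig_a, b = sig_b, c = sig_c),
       phi = c(phi_ct = sig_a / tot, phi_sc = sig_b / (sig_b + sig_c),
               phi_st = (sig_a + sig_b) / tot))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Two-level AMOVA on biallelic SNPs: each genotype contributes two
#' allelic observations and the squared distance between two allele
#' copies is 0/1 (mismatch). Sums of squares are partitioned into
#' among-group, among-population-within-group and within-population
#' strata (summed over loci), variance components follow the standard
#' nested-ANOVA coefficients for unequal sizes, and Phi-statistics are
#' tested by permutation: individuals among all populations for Phi_ST,
#' individuals among populations within their group for Phi_SC, and
#' whole populations among groups for Phi_CT.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map` with at least 2 populations (and at
#'   least 2 groups for the among-group stratum to be testable).
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @return list of class `amova_result`: `table` (data frame with source,
#'   df, SS, variance component, percent variation), `phi`, `p`
#'   (permutation p-values for phi_ct, phi_sc, phi_st), `n_perm`, `seed`.
#' @export
amova <- function(gm, popmap, n_perm = 999L, seed = NULL) {
  pm <- match_popmap(gm, popmap)
  pop <- pm$population
  pops <- unique(pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  if (any(table(pop) < 2)) stop("every population needs >= 2 samples")
  group_of_pop <- stats::setNames(
    pm$group[match(pops, pm$population)], pops)
  obs <- amova_phi(gm$calls, pop, group_of_pop)

  hits <- c(phi_ct = 0, phi_sc = 0, phi_st = 0)
  n_done <- c(phi_ct = 0, phi_sc = 0, phi_st = 0)
  groups <- unique(unname(group_of_pop))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      # Phi_ST: individuals among all populations
      perm <- amova_phi(gm$calls, sample(pop), group_of_pop)
      hits["phi_st"] <- hits["phi_st"] + (perm$phi["phi_st"] >= obs$phi["phi_st"])
      n_done["phi_st"] <- n_done["phi_st"] + 1
      # Phi_SC: individuals among pops within their group
      if (length(pops) > length(groups)) {
        p2 <- pop
        for (g in groups) {
          in_g <- group_of_pop[pop] == g
          p2[in_g] <- sample(pop[in_g])
        }
        perm <- amova_phi(gm$calls, p2, group_of_pop)
        hits["phi_sc"] <- hits["phi_sc"] + (perm$phi["phi_sc"] >= obs$phi["phi_sc"])
        n_done["phi_sc"] <- n_done["phi_sc"] + 1
      }
      # Phi_CT: whole populations among groups
      if (length(groups) > 1) {
        gperm <- stats::setNames(sample(unname(group_of_pop)), pops)
        perm <- amova_phi(gm$calls, pop, gperm)
        hits["phi_ct"] <- hits["phi_ct"] + (perm$phi["phi_ct"] >= obs$phi["phi_ct"])
        n_done["phi_ct"] <- n_done["phi_ct"] + 1
      }
    }
  })
  p <- ifelse(n_done > 0, (1 + hits) / (n_done + 1), NA_real_)

  sig <- obs$sigma
  pct <- 100 * sig / sum(sig)
  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(obs$df, sum(obs$df)),
    SS = c(obs$ss$ss_ag, obs$ss$ss_ap, obs$ss$ss_wp, obs$ss$ss_tot),
    variance = c(sig, sum(sig)),
    percent = c(pct, 100), row.names = NULL)
  structure(list(table = tab, phi = obs$phi, p = p,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "amova_result")
}

# simulate per-locus WC theta and total He for n_loci neutral loci under
# a Balding-Nichols island model with divergence F and per-pop sample
# sizes n_i (individuals). Vectorised over loci.
bn_neutral_theta <- function(n_loci, fst, n_i, anc_range = c(0.02, 0.98)) {
  anc <- stats::runif(n_loci, anc_range[1], anc_range[2])
  r <- length(n_i)
  k <- h <- matrix(0, r, n_loci)
  nmat <- matrix(n_i, r, n_loci)
  for (i in seq_len(r)) {
    p <- if (fst <= 0) anc else
      stats::rbeta(n_loci, anc * (1 - fst) / fst, (1 - anc) * (1 - fst) / fst)
    p <- pmin(pmax(p, 0), 1)
    n_alt_hom <- stats::rbinom(n_loci, n_i[i], p^2)
    denom <- 1 - p^2
    phet <- ifelse(denom > 0, 2 * p * (1 - p) / denom, 0)
    n_het <- stats::rbinom(n_loci, n_i[i] - n_alt_hom, pmin(phet, 1))
    k[i, ] <- 2 * n_alt_hom + n_het
    h[i, ] <- n_het
  }
  wc <- wc_components_from_counts(nmat, k, h)
  data.frame(theta = wc$theta, he = 2 * wc$pbar * (1 - wc$pbar))
}

#' FDIST-style FST outlier detection
#'
#' Tests each locus's Weir-Cockerham theta against a neutral envelope
#' simulated under a Balding-Nichols island model calibrated to the
#' data's background differentiation, conditioning on heterozygosity:
#' simulated loci are binned by total expected heterozygosity and each
#' observed locus is compared against its own bin. The per-locus
#' simulation p-value is (1 + #\{theta_sim >= theta_obs\}) / (n_bin + 1);
#' a locus is flagged `significant` at `p_threshold` and `outlier` when
#' theta exceeds the bin's `envelope_q` empirical quantile.
#'
#' When `target_fst` is not supplied it is calibrated from the data:
#' a first ratio-of-sums theta over all loci drives a small provisional
#' simulation, loci falling outside its 1%/99% envelope are set aside as
#' extreme, and the ratio-of-sums is recomputed once on the remainder.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param populations optional subset of populations.
#' @param n_sim number of simulated neutral loci.
#' @param target_fst background FST; `NULL` to calibrate from the data.
#' @param he_bin_width heterozygosity bin width.
#' @param p_threshold threshold for the `significant` flag.
#' @param envelope_q quantile defining the neutral envelope.
#' @param min_bin minimum simulated loci per bin; sparser bins are
#'   widened with a warning.
#' @param seed RNG seed.
#' @return list of class `outlier_result`: `stats` (data frame locus,
#'   theta, he, p, significant, outlier), `envelope` (per-bin quantiles),
#'   `target_fst`, `n_sim`, `seed`.
#' @export
fdist_outliers <- function(gm, popmap, populations = NULL, n_sim = 100000L,
                           target_fst = NULL, he_bin_width = 0.04,
                           p_threshold = 0.01, envelope_q = 0.99,
                           min_bin = 50L, seed = NULL) {
  pm <- match_popmap(gm, popmap)
  keep <- if (is.null(populations)) rep(TRUE, nrow(pm))
          else pm$population %in% populations
  pop <- pm$population[keep]
  if (length(unique(pop)) < 2) stop("need at least 2 populations")
  calls <- gm$calls[keep, , drop = FALSE]
  obs <- wc_components_from_counts_of(calls, pop)
  # matched sample sizes: median genotyped individuals per pop
  pc <- pop_counts(calls, pop)
  n_i <- pmax(2, round(apply(pc$n, 1, stats::median)))

  with_seed(seed, {
    if (is.null(target_fst)) {
      f0 <- max(1e-4, ratio_of_sums_theta(obs$a, obs$b, obs$c))
      prov <- bn_neutral_theta(max(2000L, n_sim %/% 5), f0, n_i)
      prov <- prov[is.finite(prov$theta), ]
      qs <- stats::quantile(prov$theta, c(0.01, 0.99), na.rm = TRUE)
      extreme <- !is.na(obs$theta) & (obs$theta < qs[1] | obs$theta > qs[2])
      target_fst <- max(1e-4, ratio_of_sums_theta(
        obs$a[!extreme], obs$b[!extreme], obs$c[!extreme]))
    }
    sim <- bn_neutral_theta(n_sim, target_fst, n_i)
  })
  sim <- sim[is.finite(sim$theta), ]

  breaks <- seq(0, 0.5 + he_bin_width, by = he_bin_width)
  sim_bin <- findInterval(sim$he, breaks, rightmost.closed = TRUE)
  obs_bin <- findInterval(obs$pbar * (1 - obs$pbar) * 2, breaks,
                          rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  widened <- FALSE
  p_out <- rep(NA_real_, length(obs$theta))
  q_env <- rep(NA_real_, length(obs$theta))
  for (b in unique(obs_bin[!is.na(obs$theta)])) {
    width <- 0
    repeat {
      in_bin <- sim_bin >= b - width & sim_bin <= b + width
      if (sum(in_bin) >= min_bin || width > nb) break
      width <- width + 1; widened <- TRUE
    }
    th_sim <- sim$theta[in_bin]
    sel <- which(obs_bin == b & !is.na(obs$theta))
    for (j in sel) {
      p_out[j] <- (1 + sum(th_sim >= obs$theta[j])) / (length(th_sim) + 1)
      q_env[j] <- stats::quantile(th_sim, envelope_q, names = FALSE)
    }
  }
  if (widened) warning("sparse heterozygosity bin(s) widened")

  env <- do.call(rbind, lapply(sort(unique(sim_bin)), function(b) {
    th <- sim$theta[sim_bin == b]
    data.frame(he_lo = breaks[b], he_hi = breaks[b + 1], n = length(th),
               q50 = stats::median(th),
               q_hi = stats::quantile(th, envelope_q, names = FALSE))
  }))
  stats_df <- data.frame(locus = gm$locus_ids, theta = obs$theta,
                         he = 2 * obs$pbar * (1 - obs$pbar), p = p_out,
                         significant = !is.na(p_out) & p_out < p_threshold,
                         outlier = !is.na(obs$theta) & !is.na(q_env) &
                                   obs$theta > q_env,
                         row.names = NULL)
  structure(list(stats = stats_df, envelope = env, target_fst = target_fst,
                 n_sim = as.integer(n_sim), seed = seed),
            class = "outlier_result")
}
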