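# Small builders and independent brute-force oracles used across tests.

# quick genotype matrix: calls is samples x loci, everything else defaulted
make_gm <- function(calls, scaffold = NULL, position = NULL, depth = NULL,
                    ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  genotype_matrix(calls,
                  scaffold = scaffold %||% rep("sc1", L),
                  position = position %||% seq_len(L) * 100L,
                  ref_allele = ref %||% rep("A", L),
                  alt_allele = alt %||% rep("C", L),
                  sample_ids = paste0("s", seq_len(nrow(calls))),
                  locus_ids = paste0("loc", seq_len(L)),
                  depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simple popmap for samples split into consecutive equal populations
make_popmap <- function(sample_ids, pop, group = NULL, lat = NULL, lon = NULL) {
  population_map(data.frame(
    sample = sample_ids, population = pop,
    group = group %||% rep("g1", length(sample_ids)),
    lat = lat %||% rep(25, length(sample_ids)),
    lon = lon %||% rep(-80, length(sample_ids))))
}

# ---- oracles -------------------------------------------------------------

# double-loop recount of pairwise genotype differences
oracle_pairwise_pi <- function(calls) {
  n <- nrow(calls)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- den <- 0
    for (l in seq_len(ncol(calls))) {
      if (is.na(calls[i, l]) || is.na(calls[j, l])) next
      den <- den + 1
      if (calls[i, l] != calls[j, l]) num <- num + 1
    }
    out[i, j] <- if (den == 0) NA_real_ else num / den
  }
  out
}

# literal scalar transcription of the Weir-Cockerham (1984) formulas for
# one locus, from per-population genotype counts (n_hom_ref, n_het,
# n_hom_alt per row)
oracle_wc84 <- function(counts) {
  r <- nrow(counts)
  n_i <- rowSums(counts)
  p_i <- (2 * counts[, 3] + counts[, 2]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# AMOVA sums of squares from the full allele-copy distance matrix:
# expand every genotype into two 0/1 allele copies per locus and use
# SS(set) = sum of squared pairwise distances / set size.
oracle_amova_ss <- function(calls, pop, group_of_pop) {
  expand <- function(g) switch(as.character(g), "0" = c(0, 0),
                               "1" = c(0, 1), "2" = c(1, 1))
  ss_set <- function(x) {
    if (length(x) < 2) return(0)
    d2 <- outer(x, x, function(a, b) (a - b)^2)
    sum(d2[upper.tri(d2)]) / length(x)
  }
  ss_tot <- ss_wp <- ss_wg <- 0
  grp <- group_of_pop[pop]
  for (l in seq_len(ncol(calls))) {
    copies <- list()
    for (i in seq_len(nrow(calls))) {
      if (is.na(calls[i, l])) next
      copies[[length(copies) + 1]] <-
        list(x = expand(calls[i, l]), pop = pop[i], grp = grp[i])
    }
    x <- unlist(lapply(copies, `[[`, "x"))
    cp <- rep(vapply(copies, `[[`, "", "pop"), each = 2)
    cg <- rep(vapply(copies, `[[`, "", "grp"), each = 2)
    ss_tot <- ss_tot + ss_set(x)
    for (p in unique(cp)) ss_wp <- ss_wp + ss_set(x[cp == p])
    for (g in unique(cg)) ss_wg <- ss_wg + ss_set(x[cg == g])
  }
  list(ss_ag = ss_tot - ss_wg, ss_ap = ss_wg - ss_wp, ss_wp = ss_wp,
       ss_tot = ss_tot)
}

# exhaustive search for call-rate fixpoints on tiny matrices: enumerate
# every (sample subset, locus subset), keep those where all call-rate
# constraints hold, and return the ones maximising retained cells.
oracle_callrate_fixpoints <- function(calls, ind_min, locus_min) {
  ns <- nrow(calls); nl <- ncol(calls)
  best <- list(); best_cells <- -1
  for (smask in 0:(2^ns - 1)) {
    si <- which(bitwAnd(smask, 2^(seq_len(ns) - 1)) > 0)
    if (length(si) == 0) next
    for (lmask in 0:(2^nl - 1)) {
      li <- which(bitwAnd(lmask, 2^(seq_len(nl) - 1)) > 0)
      if (length(li) == 0) next
      sub <- calls[si, li, drop = FALSE]
      ok <- all(rowMeans(!is.na(sub)) >= ind_min) &&
            all(colMeans(!is.na(sub)) >= locus_min)
      if (!ok) next
      cells <- length(si) * length(li)
      if (cells > best_cells) { best <- list(); best_cells <- cells }
      if (cells == best_cells)
        best[[length(best) + 1]] <- list(samples = si, loci = li)
    }
  }
  best
}

# per-locus mean pairwise genotype difference from genotype counts
per_locus_pi <- function(calls) {
  n <- nrow(calls)
  vapply(seq_len(ncol(calls)), function(l) {
    g <- calls[, l]; g <- g[!is.na(g)]
    m <- length(g)
    if (m < 2) return(NA_real_)
    same <- sum(choose(table(factor(g, 0:2)), 2))
    1 - same / choose(m, 2)
  }, numeric(1))
}
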