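#' Exact Hardy-Weinberg test with a heterozygote-excess alternative
#'
#' Conditional exact test on the heterozygote count given the allele
#' counts: under HWE, P(n_het | n, n_A) = n! 2^n_het n_A! n_B! /
#' (n_AA! n_het! n_BB! (2n)!). The one-sided `"excess"` p-value sums the
#' probabilities of heterozygote counts at least as large as observed —
#' the relevant direction for GBS data, where co-aligned paralogous loci
#' masquerade as SNPs with inflated heterozygosity.
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype counts at one biallelic locus.
#' @param alternative `"excess"` (default), `"deficit"` or `"two.sided"`.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom,
                           alternative = c("excess", "deficit", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- n_ref_hom + n_het + n_alt_hom
  if (n == 0) return(1)
  n_a <- 2 * n_ref_hom + n_het          # ref allele count
  n_b <- 2 * n_alt_hom + n_het
  # all heterozygote counts compatible with the allele counts (parity-fixed)
  h_max <- min(n_a, n_b)
  h_all <- seq(h_max %% 2, h_max, by = 2)
  logp <- lfactorial(n) + h_all * log(2) + lfactorial(n_a) + lfactorial(n_b) -
    lfactorial((n_a - h_all) / 2) - lfactorial(h_all) -
    lfactorial((n_b - h_all) / 2) - lfactorial(2 * n)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[h_all == n_het]
  p <- switch(alternative,
    excess    = sum(pr[h_all >= n_het]),
    deficit   = sum(pr[h_all <= n_het]),
    two.sided = sum(pr[pr <= obs + 1e-12]))
  min(1, p)
}

# vectorised over the loci of a genotype matrix
hwe_excess_p <- function(gm) {
  vapply(seq_along(gm$locus_ids), function(j) {
    g <- gm$calls[, j]
    hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 2L, na.rm = TRUE), "excess")
  }, numeric(1))
}
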