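#' Pairwise SNP differences between individuals
#'
#' For each sample pair, the proportion of loci (non-missing in both) at
#' which the genotype calls differ. Any difference between calls
#' (0 vs 1, 1 vs 2, 0 vs 2) counts as one difference; the alternative
#' allele-sharing distance, which scores a hom-het difference as half,
#' is available via `method = "allele_sharing"`.
#'
#' @param gm a `genotype_matrix` with at least 2 samples.
#' @param method `"genotype"` (default: any call difference counts 1) or
#'   `"allele_sharing"` (|dosage difference| / 2).
#' @return symmetric samples x samples matrix with zero diagonal; a pair
#'   sharing no non-missing locus gets `NA` and the pairs are listed in
#'   attribute `"undefined_pairs"`.
#' @export
pairwise_pi <- function(gm, method = c("genotype", "allele_sharing")) {
  method <- match.arg(method)
  ns <- length(gm$sample_ids)
  if (ns < 2) stop("need at least 2 samples")
  calls <- gm$calls
  pi <- matrix(0, ns, ns, dimnames = list(gm$sample_ids, gm$sample_ids))
  undef <- character(0)
  for (i in seq_len(ns - 1)) {
    gi <- calls[i, ]
    for (j in seq(i + 1, ns)) {
      gj <- calls[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      if (!any(ok)) {
        pi[i, j] <- pi[j, i] <- NA_real_
        undef <- c(undef, paste(gm$sample_ids[i], gm$sample_ids[j], sep = "|"))
        next
      }
      d <- if (method == "genotype") mean(gi[ok] != gj[ok])
           else mean(abs(gi[ok] - gj[ok]) / 2)
      pi[i, j] <- pi[j, i] <- d
    }
  }
  if (length(undef)) attr(pi, "undefined_pairs") <- undef
  pi
}

#' Summarise pairwise differences within and between populations
#'
#' @param pi_matrix output of [pairwise_pi()].
#' @param popmap a `population_map` covering all samples.
#' @return list with `within`: data frame (population, n, mean, min, max
#'   over unordered within-population pairs; `NA` and a flag for
#'   single-sample populations) including an `all` row pooling every pair;
#'   and `between`: population x population matrix of cross-pair means
#'   (diagonal = within-population means).
#' @export
pi_by_population <- function(pi_matrix, popmap) {
  ids <- rownames(pi_matrix)
  i <- match(ids, popmap$sample)
  if (anyNA(i)) stop("samples missing from population map: ",
                     paste(ids[is.na(i)], collapse = ", "))
  pop <- popmap$population[i]
  pops <- unique(pop)
  lower <- lower.tri(pi_matrix)

  pair_stats <- function(mask) {
    v <- pi_matrix[mask & lower]
    if (length(v) == 0) c(mean = NA_real_, min = NA_real_, max = NA_real_)
    else c(mean = mean(v, na.rm = TRUE), min = min(v, na.rm = TRUE),
           max = max(v, na.rm = TRUE))
  }
  within <- do.call(rbind, lapply(pops, function(p) {
    m <- outer(pop == p, pop == p, `&`)
    s <- pair_stats(m)
    data.frame(population = p, n = sum(pop == p), mean = s["mean"],
               min = s["min"], max = s["max"], row.names = NULL)
  }))
  all_s <- pair_stats(matrix(TRUE, nrow(pi_matrix), ncol(pi_matrix)))
  within <- rbind(data.frame(population = "all", n = length(ids),
                             mean = all_s["mean"], min = all_s["min"],
                             max = all_s["max"], row.names = NULL), within)

  between <- matrix(NA_real_, length(pops), length(pops),
                    dimnames = list(pops, pops))
  for (a in seq_along(pops)) for (b in seq_len(a)) {
    m <- outer(pop == pops[a], pop == pops[b], `&`) |
         outer(pop == pops[b], pop == pops[a], `&`)
    between[a, b] <- between[b, a] <- mean(pi_matrix[m & lower], na.rm = TRUE)
  }
  list(within = within, between = between)
}

#' Tag-length adjustment of pairwise SNP differences
#'
#' SNP-only pairwise differences overstate per-nucleotide diversity
#' because invariant sites inside each sequence tag are not counted.
#' Scaling by the SNP density per tag recovers a per-base estimate:
#' `pi_mean * snps_per_tag / tag_length`.
#'
#' @param pi_mean mean pairwise difference on the proportion scale.
#' @param snps_per_tag average number of SNPs per sequence tag.
#' @param tag_length tag length in bases (64 for standard GBS tags).
#' @return adjusted diversity, proportion scale.
#' @export
adjusted_pi <- function(pi_mean, snps_per_tag, tag_length = 64) {
  if (tag_length <= 0) stop("tag_length must be positive")
  pi_mean * snps_per_tag / tag_length
}

#' Per-locus summary statistics
#'
#' Minor allele frequency, call rate, observed heterozygosity (fraction
#' of heterozygotes among non-missing calls), expected heterozygosity
#' 2p(1-p) (optionally with the small-sample factor 2n/(2n-1)), and the
#' exact heterozygote-excess HWE p-value. Also reports the percentage of
#' polymorphic loci, overall and per population when a map is given.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap optional `population_map` for per-population summaries.
#' @param unbiased_he use the 2n/(2n-1) correction for He.
#' @return data frame (locus, scaffold, position, maf, call_rate, ho, he,
#'   hwe_p); attribute `"percent_polymorphic"` is a named vector with an
#'   `overall` entry and one per population when mapped.
#' @export
locus_stats <- function(gm, popmap = NULL, unbiased_he = FALSE) {
  p <- alt_freq(gm)
  n_called <- colSums(!is.na(gm$calls))
  ho <- colSums(gm$calls == 1L, na.rm = TRUE) / n_called
  he <- 2 * p * (1 - p)
  if (unbiased_he) he <- he * ifelse(n_called > 0, 2 * n_called / (2 * n_called - 1), NA)
  stats <- data.frame(locus = gm$locus_ids, scaffold = gm$scaffold,
                      position = gm$position,
                      maf = pmin(p, 1 - p), call_rate = n_called / nrow(gm$calls),
                      ho = ho, he = he, hwe_p = hwe_excess_p(gm),
                      row.names = NULL)
  poly <- c(overall = mean(p > 0 & p < 1, na.rm = TRUE) * 100)
  if (!is.null(popmap)) {
    pm <- match_popmap(gm, popmap)
    for (pp in unique(pm$population)) {
      sub <- gm$calls[pm$population == pp, , drop = FALSE]
      f <- colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
      poly[pp] <- mean(f > 0 & f < 1, na.rm = TRUE) * 100
    }
  }
  attr(stats, "percent_polymorphic") <- poly
  stats
}
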