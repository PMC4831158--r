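#' Parameters of the SNP quality-control cascade
#'
#' Defaults follow common GBS practice for dual-caller panels: loci must be
#' called by both aligners with closely matching allele frequencies
#' (`af_delta`), calls need at least 5 supporting reads, individuals must
#' carry at least 70\% of called loci and loci must be present in at least
#' 90\% of individuals (applied to a joint fixpoint), minor allele
#' frequency at least 5\%, heterozygote-excess loci removed at p < 0.01,
#' and one member of each linked pair (D' chi-square p < 0.01 or r^2 >
#' 0.20 within a 100-SNP sliding window) pruned.
#'
#' @param af_delta max |allele-frequency difference| between callers.
#' @param min_depth minimum reads supporting a genotype call.
#' @param ind_min_callrate minimum per-individual call rate.
#' @param locus_min_callrate minimum per-locus call rate.
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param het_alpha one-sided exact-test alpha for heterozygote excess.
#' @param ld_window sliding-window size in loci.
#' @param ld_dprime_alpha alpha for the haplotype-table chi-square.
#' @param ld_r2_max genotypic r^2 above which a pair is pruned.
#' @return a `cascade_params` list.
#' @export
cascade_params <- function(af_delta = 0.05, min_depth = 5L,
                           ind_min_callrate = 0.70, locus_min_callrate = 0.90,
                           maf_min = 0.05, het_alpha = 0.01,
                           ld_window = 100L, ld_dprime_alpha = 0.01,
                           ld_r2_max = 0.20) {
  p <- list(af_delta = af_delta, min_depth = as.integer(min_depth),
            ind_min_callrate = ind_min_callrate,
            locus_min_callrate = locus_min_callrate,
            maf_min = maf_min, het_alpha = het_alpha,
            ld_window = as.integer(ld_window),
            ld_dprime_alpha = ld_dprime_alpha, ld_r2_max = ld_r2_max)
  rates <- c(p$ind_min_callrate, p$locus_min_callrate, p$maf_min)
  stopifnot(all(rates >= 0 & rates <= 1), p$ld_window >= 2,
            p$het_alpha > 0, p$het_alpha < 1,
            p$ld_dprime_alpha > 0, p$ld_dprime_alpha < 1)
  structure(p, class = "cascade_params")
}

#' Dual-caller consensus of two genotype matrices
#'
#' Keeps only loci (keyed by scaffold and position) that both callers
#' report and whose alt-allele frequencies agree to within `af_delta`;
#' calls are taken from `gm_a`. Aligner choice is known to shift allele
#' frequencies at mis-mapped loci, so concordance acts as a technical
#' filter.
#'
#' @param gm_a,gm_b genotype matrices over the same samples.
#' @param af_delta maximum tolerated |AF_a - AF_b|.
#' @return the consensus `genotype_matrix`; attribute `"consensus"` holds
#'   counts of single-caller and discordant loci and their ids.
#' @export
consensus_intersect <- function(gm_a, gm_b, af_delta = 0.05) {
  if (!setequal(gm_a$sample_ids, gm_b$sample_ids))
    stop("sample sets differ between callers")
  gm_b <- gm_b[gm_a$sample_ids, ]
  ka <- locus_keys(gm_a); kb <- locus_keys(gm_b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  af_a <- alt_freq(gm_a)[ia]; af_b <- alt_freq(gm_b)[ib]
  concord <- is.finite(af_a) & is.finite(af_b) & abs(af_a - af_b) <= af_delta
  out <- gm_a[, ia[concord]]
  attr(out, "consensus") <- list(
    n_single_a = sum(!(ka %in% kb)), n_single_b = sum(!(kb %in% ka)),
    n_shared = length(shared), n_discordant = sum(!concord),
    discordant_ids = gm_a$locus_ids[ia[!concord]])
  out
}

#' Mask genotype calls with insufficient read depth
#'
#' Calls supported by fewer than `min_depth` reads are set to missing;
#' the locus set is unchanged and the depth matrix is retained (a masked
#' call keeps its depth).
#'
#' @param gm a `genotype_matrix` with depth.
#' @param min_depth minimum supporting reads per call.
#' @return the masked `genotype_matrix`; attribute `"n_masked"` counts
#'   newly masked calls.
#' @export
depth_mask <- function(gm, min_depth = 5L) {
  if (is.null(gm$depth)) stop("genotype matrix has no depth")
  mask <- gm$depth < min_depth & !is.na(gm$calls)
  gm$calls[mask] <- NA_integer_
  attr(gm, "n_masked") <- sum(mask)
  gm
}

#' Iterative call-rate filter on individuals and loci
#'
#' Finds a joint fixpoint in which every retained individual is called at
#' a fraction of at least `ind_min_callrate` of the retained loci and every
#' retained locus is called in at least `locus_min_callrate` of the
#' retained individuals. Because removing one axis changes the other
#' axis's rates, the filter iterates: at each step the single worst
#' offender (the sample or locus with the lowest call rate among those
#' failing) is removed and all rates are recomputed, until nothing fails.
#' The removal order is recorded so runs are reproducible.
#'
#' @param gm a `genotype_matrix`.
#' @param ind_min_callrate,locus_min_callrate thresholds in [0, 1].
#' @return the filtered `genotype_matrix`; attribute `"iterations"` is a
#'   data frame logging each removal (step, axis, id, call rate).
#' @export
iterative_call_rate_filter <- function(gm, ind_min_callrate = 0.70,
                                       locus_min_callrate = 0.90) {
  if (length(gm$sample_ids) == 0 || length(gm$locus_ids) == 0)
    stop("empty genotype matrix")
  log <- list()
  repeat {
    scr <- sample_call_rate(gm); lcr <- locus_call_rate(gm)
    fs <- which(scr < ind_min_callrate); fl <- which(lcr < locus_min_callrate)
    if (length(fs) == 0 && length(fl) == 0) break
    worst_s <- if (length(fs)) min(scr[fs]) else Inf
    worst_l <- if (length(fl)) min(lcr[fl]) else Inf
    if (worst_s <= worst_l) {
      i <- fs[which.min(scr[fs])]
      log[[length(log) + 1]] <- data.frame(step = length(log) + 1,
        axis = "sample", id = gm$sample_ids[i], call_rate = scr[i])
      if (length(gm$sample_ids) == 1) stop("call-rate filter removed all samples")
      gm <- gm[-i, ]
    } else {
      j <- fl[which.min(lcr[fl])]
      log[[length(log) + 1]] <- data.frame(step = length(log) + 1,
        axis = "locus", id = gm$locus_ids[j], call_rate = lcr[j])
      if (length(gm$locus_ids) == 1) stop("call-rate filter removed all loci")
      gm <- gm[, -j]
    }
  }
  attr(gm, "iterations") <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), axis = character(), id = character(),
               call_rate = numeric())
  gm
}

#' Minor-allele-frequency filter
#'
#' Removes loci whose minor allele frequency, computed over non-missing
#' calls, is below `maf_min` (a locus at exactly the threshold is kept).
#' Loci with no calls at all are removed and counted separately.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minimum MAF, inclusive.
#' @return the filtered matrix; attribute `"maf_removed"` lists removed
#'   locus ids, `"n_all_missing"` the all-missing count among them.
#' @export
maf_filter <- function(gm, maf_min = 0.05) {
  p <- alt_freq(gm)
  maf <- pmin(p, 1 - p)
  all_missing <- !is.finite(maf)
  drop <- all_missing | maf < maf_min
  out <- gm[, !drop]
  attr(out, "maf_removed") <- gm$locus_ids[drop]
  attr(out, "n_all_missing") <- sum(all_missing)
  out
}

#' Remove loci with significant heterozygote excess
#'
#' Applies [hwe_exact_test()] (one-sided, excess) over all samples pooled
#' and removes loci with p below `het_alpha`. Heterozygote deficits are
#' never removed: the target is technical artefacts (paralogous
#' co-alignment), which inflate heterozygosity only.
#'
#' @param gm a `genotype_matrix`.
#' @param het_alpha significance threshold.
#' @return the filtered matrix; attribute `"het_removed"` lists removed
#'   locus ids.
#' @export
excess_het_filter <- function(gm, het_alpha = 0.01) {
  p <- hwe_excess_p(gm)
  drop <- p < het_alpha
  out <- gm[, !drop]
  attr(out, "het_removed") <- gm$locus_ids[drop]
  out
}

# EM estimate of the four haplotype frequencies of a biallelic locus pair
# from unphased dosages (complete cases), assuming HWE. Returns the
# chi-square p-value for D != 0 plus D' for reporting.
ld_pair_stats <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 5) return(list(p_d = 1, dprime = 0, r2 = 0, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(p_d = 1, dprime = 0, r2 = 0, n = n))
  r2 <- stats::cor(x, y)^2
  # unambiguous haplotype counts; double heterozygotes resolved by EM
  tab <- table(factor(x, 0:2), factor(y, 0:2))
  n11k <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]   # alt-alt
  n10k <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]   # alt-ref
  n01k <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  n00k <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  ndh <- tab[2, 2]
  pa <- mean(x) / 2; pb <- mean(y) / 2
  f <- c(f11 = pa * pb, f10 = pa * (1 - pb), f01 = (1 - pa) * pb,
         f00 = (1 - pa) * (1 - pb))
  for (it in 1:100) {
    w <- f["f11"] * f["f00"] / (f["f11"] * f["f00"] + f["f10"] * f["f01"])
    if (!is.finite(w)) w <- 0.5
    new <- c(n11k + ndh * w, n10k + ndh * (1 - w),
             n01k + ndh * w, n00k + ndh * (1 - w)) / (2 * n)
    if (max(abs(new - f)) < 1e-10) { f <- new; break }
    f <- stats::setNames(new, names(f))
  }
  pa <- f[1] + f[2]; pb <- f[1] + f[3]
  D <- f[1] - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  chi2 <- 2 * n * D^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(p_d = stats::pchisq(chi2, 1, lower.tail = FALSE),
       dprime = unname(dprime), r2 = r2, n = n)
}

#' Prune linked loci within a sliding window
#'
#' Loci must be in genome order (by scaffold, then position). For every
#' same-scaffold locus pair within a `ld_window`-locus sliding window
#' (pairs on different scaffolds carry no linkage information and are
#' never tested), a pair is flagged
#' when the haplotype-table chi-square for D (haplotype frequencies from
#' unphased genotypes by EM under HWE) is significant at
#' `ld_dprime_alpha`, or the composite genotypic r^2 exceeds `ld_r2_max`.
#' The later locus of each flagged pair is removed (deterministic
#' tie-break); the output contains no flagged pair.
#'
#' @param gm a `genotype_matrix`, loci sorted by (scaffold, position).
#' @param ld_window window size in loci.
#' @param ld_dprime_alpha significance level for the D chi-square.
#' @param ld_r2_max r^2 threshold.
#' @return the pruned matrix; attribute `"ld_removed"` lists removed ids.
#' @export
ld_prune <- function(gm, ld_window = 100L, ld_dprime_alpha = 0.01,
                     ld_r2_max = 0.20) {
  nl <- length(gm$locus_ids)
  ord <- order(match(gm$scaffold, unique(gm$scaffold)), gm$position)
  if (!identical(ord, seq_len(nl)))
    stop("loci must be sorted by (scaffold, position)")
  alive <- rep(TRUE, nl)
  for (i in seq_len(nl)) {
    if (!alive[i]) next
    for (j in seq(i + 1, length.out = min(ld_window - 1, nl - i))) {
      if (!alive[j] || gm$scaffold[j] != gm$scaffold[i]) next
      s <- ld_pair_stats(gm$calls[, i], gm$calls[, j])
      if (s$p_d < ld_dprime_alpha || s$r2 > ld_r2_max) alive[j] <- FALSE
    }
  }
  out <- gm[, alive]
  attr(out, "ld_removed") <- gm$locus_ids[!alive]
  out
}

#' Run the full SNP QC cascade
#'
#' Applies, in order: dual-caller consensus, depth masking, the iterative
#' call-rate fixpoint, the MAF filter, the heterozygote-excess filter and
#' LD pruning, and returns the filtered matrix together with a
#' [filter_report()] auditing every stage.
#'
#' @param gm_a,gm_b genotype matrices from the two callers (`gm_b = NULL`
#'   skips the consensus stage, e.g. for single-caller panels).
#' @param params a [cascade_params()].
#' @return list with elements `genotypes` (filtered `genotype_matrix`) and
#'   `report` (a `filter_report`).
#' @export
run_cascade <- function(gm_a, gm_b = NULL, params = cascade_params()) {
  stopifnot(inherits(params, "cascade_params"))
  stages <- list()
  note <- function(stage, pars, before, after, rs = character(), rl = NULL) {
    if (is.null(rl)) rl <- setdiff(before$locus_ids, after$locus_ids)
    stages[[length(stages) + 1]] <<- list(stage = stage, params = pars,
      samples_in = length(before$sample_ids), samples_out = length(after$sample_ids),
      loci_in = length(before$locus_ids), loci_out = length(after$locus_ids),
      removed_samples = rs, removed_loci = rl)
  }

  gm <- gm_a
  if (!is.null(gm_b)) {
    out <- consensus_intersect(gm_a, gm_b, params$af_delta)
    note("consensus", list(af_delta = params$af_delta), gm_a, out)
    gm <- out
  }

  if (!is.null(gm$depth)) {
    out <- depth_mask(gm, params$min_depth)
    note("depth_mask", list(min_depth = params$min_depth,
                            n_masked = attr(out, "n_masked")), gm, out)
    gm <- out
  } else {
    warning("no depth present; depth-mask stage skipped")
    note("depth_mask", list(min_depth = params$min_depth, skipped = TRUE), gm, gm)
  }

  out <- iterative_call_rate_filter(gm, params$ind_min_callrate,
                                    params$locus_min_callrate)
  note("call_rate", list(ind_min = params$ind_min_callrate,
                         locus_min = params$locus_min_callrate),
       gm, out, rs = setdiff(gm$sample_ids, out$sample_ids))
  gm <- out

  out <- maf_filter(gm, params$maf_min)
  note("maf", list(maf_min = params$maf_min), gm, out,
       rl = attr(out, "maf_removed"))
  gm <- out

  out <- excess_het_filter(gm, params$het_alpha)
  note("excess_het", list(alpha = params$het_alpha), gm, out,
       rl = attr(out, "het_removed"))
  gm <- out

  out <- ld_prune(gm, params$ld_window, params$ld_dprime_alpha, params$ld_r2_max)
  note("ld_prune", list(window = params$ld_window,
                        dprime_alpha = params$ld_dprime_alpha,
                        r2_max = params$ld_r2_max),
       gm, out, rl = attr(out, "ld_removed"))
  gm <- out

  list(genotypes = gm, report = filter_report(stages))
}
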