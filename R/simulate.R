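#' Simulation configuration
#'
#' Defines the statistical structure of a simulated GBS SNP panel. The
#' defaults emulate a small reef-coral study design: five populations in
#' two groups (sample sizes 23, 10, 10, 23 in one group and 11 in the
#' other), ~4,764 biallelic loci with ancestral minor allele frequencies
#' uniform on [0.05, 0.5], island-model differentiation at background
#' FST 0.05 with 2\% of loci planted at FST 0.4, a few linked blocks,
#' sparse missingness and negative-binomial read depths with mean 411.
#'
#' @param populations data frame with columns `population`, `group`, `n`.
#' @param n_loci number of biallelic loci.
#' @param mode `"island"` (every population drawn around the ancestral
#'   frequency) or `"stepping_stone"` (Beta draws chained along the
#'   population transect; `target_fst` is then the per-step divergence).
#' @param target_fst background Balding-Nichols divergence F.
#' @param anc_maf_range ancestral alt-allele frequency range (uniform).
#' @param outlier_fraction,outlier_fst fraction of loci planted at an
#'   elevated divergence and their F.
#' @param ld_blocks,ld_block_size,ld_strength number of linked blocks of
#'   consecutive loci, loci per block, and per-individual probability
#'   that a block locus copies the block's first locus.
#' @param missing_rate per-call missingness probability.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mean and size).
#' @param n_scaffolds scaffolds the loci are spread over, in order.
#' @param pop_spacing_km,jitter_km transect spacing between consecutive
#'   populations and within-population coordinate jitter.
#' @param seed RNG seed (mandatory: simulations are always reproducible).
#' @return a `sim_config` list.
#' @export
sim_config <- function(populations = data.frame(
                         population = paste0("pop", 1:5),
                         group = c("grp1", "grp1", "grp1", "grp1", "grp2"),
                         n = c(23L, 10L, 10L, 23L, 11L)),
                       n_loci = 4764L, mode = c("island", "stepping_stone"),
                       target_fst = 0.05, anc_maf_range = c(0.05, 0.5),
                       outlier_fraction = 0.02, outlier_fst = 0.4,
                       ld_blocks = 5L, ld_block_size = 3L, ld_strength = 0.9,
                       missing_rate = 0.03,
                       depth_mean = 411, depth_dispersion = 2,
                       n_scaffolds = 500L,
                       pop_spacing_km = 60, jitter_km = 2,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(populations$n >= 2), n_loci >= 1,
            target_fst >= 0, target_fst < 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            outlier_fst >= 0, outlier_fst < 1,
            missing_rate >= 0, missing_rate <= 1,
            !is.null(seed))
  structure(list(populations = populations, n_loci = as.integer(n_loci),
                 mode = mode, target_fst = target_fst,
                 anc_maf_range = anc_maf_range,
                 outlier_fraction = outlier_fraction, outlier_fst = outlier_fst,
                 ld_blocks = as.integer(ld_blocks),
                 ld_block_size = as.integer(ld_block_size),
                 ld_strength = ld_strength, missing_rate = missing_rate,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 n_scaffolds = as.integer(n_scaffolds),
                 pop_spacing_km = pop_spacing_km, jitter_km = jitter_km,
                 seed = seed),
            class = "sim_config")
}

# one Balding-Nichols draw: population frequency around p with divergence f
bn_draw <- function(p, f) {
  out <- p
  pos <- f > 0
  if (any(pos)) {
    pp <- pmin(pmax(p[pos], 1e-6), 1 - 1e-6)
    out[pos] <- stats::rbeta(sum(pos), pp * (1 - f[pos]) / f[pos],
                             (1 - pp) * (1 - f[pos]) / f[pos])
  }
  pmin(pmax(out, 0), 1)
}

#' Simulate an island/stepping-stone GBS genotype panel with ground truth
#'
#' Per locus, an ancestral alt-allele frequency is drawn uniformly from
#' `anc_maf_range`; each population's frequency is a Balding-Nichols
#' Beta draw around it with divergence `target_fst` (`outlier_fst` at
#' planted outlier loci), chained from population to population in
#' stepping-stone mode; genotypes are Binomial(2, p_pop). Linked blocks,
#' missingness and read depths are applied last; every intermediate
#' quantity is recorded in the returned truth object. Population
#' coordinates are spaced along a latitudinal transect with km-scale
#' within-population jitter.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a `genotype_matrix` with depth),
#'   `popmap` (a `population_map`) and `truth` (list: `ancestral`,
#'   `pop_freqs`, `outlier_loci`, `ld_blocks`, `realized_fst` per-locus
#'   WC theta on the complete pre-masking genotypes, `missing_rate`
#'   realized, `seed`, `config`).
#' @export
simulate_island_genotypes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pops <- config$populations
  L <- config$n_loci
  r <- nrow(pops)
  with_seed(config$seed, {
    anc <- stats::runif(L, config$anc_maf_range[1], config$anc_maf_range[2])
    n_out <- round(config$outlier_fraction * L)
    out_idx <- if (n_out > 0) sort(sample.int(L, n_out)) else integer(0)
    f <- rep(config$target_fst, L)
    f[out_idx] <- config$outlier_fst

    pop_freqs <- matrix(NA_real_, r, L,
                        dimnames = list(pops$population, NULL))
    prev <- anc
    for (i in seq_len(r)) {
      pop_freqs[i, ] <- bn_draw(if (config$mode == "island") anc else prev, f)
      if (config$mode == "stepping_stone") prev <- pop_freqs[i, ]
    }

    n_tot <- sum(pops$n)
    calls <- matrix(NA_integer_, n_tot, L)
    pop_of <- rep(pops$population, pops$n)
    row <- 1
    for (i in seq_len(r)) {
      ni <- pops$n[i]
      calls[row:(row + ni - 1), ] <-
        matrix(stats::rbinom(ni * L, 2, rep(pop_freqs[i, ], each = ni)), ni, L)
      row <- row + ni
    }

    # linked blocks: later block loci copy the first locus per individual.
    # Blocks are kept inside one scaffold chunk so downstream LD testing
    # (which never pairs loci across scaffolds) can see them.
    ld_blocks <- list()
    per_scaf <- ceiling(L / config$n_scaffolds)
    if (config$ld_blocks > 0 && config$ld_block_size >= 2) {
      cand <- seq_len(L - config$ld_block_size + 1)
      same_scaf <- (cand - 1) %/% per_scaf ==
        (cand + config$ld_block_size - 2) %/% per_scaf
      cand <- setdiff(cand[same_scaf], out_idx)
      starts <- sort(sample(cand, min(config$ld_blocks, length(cand))))
      for (s in starts) {
        block <- s:(s + config$ld_block_size - 1)
        for (j in block[-1]) {
          copy <- stats::runif(n_tot) < config$ld_strength
          calls[copy, j] <- calls[copy, s]
        }
        ld_blocks[[length(ld_blocks) + 1]] <- block
      }
    }

    # realized per-locus divergence on the complete genotypes
    pc <- pop_counts(calls, pop_of)
    realized <- wc_components_from_counts(pc$n, pc$k, pc$h)$theta

    miss <- matrix(stats::runif(n_tot * L) < config$missing_rate, n_tot, L)
    depth <- matrix(stats::rnbinom(n_tot * L, mu = config$depth_mean,
                                   size = config$depth_dispersion), n_tot, L)
    calls[miss] <- NA_integer_
    depth[miss] <- 0L

    # coordinates: transect along latitude, jitter in both axes
    lat0 <- 25.0; lon0 <- -80.2
    lat_pop <- lat0 + (seq_len(r) - 1) * config$pop_spacing_km / 110.574
    jit <- function(n, km) stats::runif(n, -km, km) / 110.574
    lat <- rep(lat_pop, pops$n) + jit(n_tot, config$jitter_km)
    lon <- rep(lon0, n_tot) + jit(n_tot, config$jitter_km)

    sample_ids <- unlist(lapply(seq_len(r), function(i)
      sprintf("%s_%02d", pops$population[i], seq_len(pops$n[i]))))
    locus_ids <- sprintf("L%05d", seq_len(L))
    scaffold <- sprintf("scaffold%03d", rep(seq_len(config$n_scaffolds),
                                            each = per_scaf)[seq_len(L)])
    position <- unlist(tapply(seq_len(L), scaffold, function(ix)
      cumsum(sample(50:5000, length(ix), replace = TRUE)),
      simplify = FALSE)[unique(scaffold)])
    alleles <- vapply(seq_len(L), function(j)
      sample(c("A", "C", "G", "T"), 2), character(2))

    gm <- genotype_matrix(calls, scaffold = scaffold, position = position,
                          ref_allele = alleles[1, ], alt_allele = alleles[2, ],
                          sample_ids = sample_ids, locus_ids = locus_ids,
                          depth = depth)
    popmap <- population_map(data.frame(
      sample = sample_ids, population = pop_of,
      group = rep(pops$group, pops$n), lat = lat, lon = lon))
    truth <- list(ancestral = anc, pop_freqs = pop_freqs,
                  outlier_loci = locus_ids[out_idx],
                  ld_blocks = lapply(ld_blocks, function(b) locus_ids[b]),
                  realized_fst = realized,
                  missing_rate_realized = mean(miss),
                  seed = config$seed, config = config)
    list(genotypes = gm, popmap = popmap, truth = truth)
  })
}

#' Split a panel into a discordant two-caller pair
#'
#' Emulates the partial overlap between SNP sets called by two different
#' aligners: a `overlap_fraction` share of loci is present in both
#' outputs (the rest split between the two), and a `discordant_fraction`
#' of the shared loci have their genotypes resampled in the second copy
#' at an allele frequency shifted by N(0, `af_perturb_sd`), emulating
#' aligner disagreement.
#'
#' @param gm a `genotype_matrix`.
#' @param overlap_fraction fraction of loci called by both (in (0, 1]).
#' @param af_perturb_sd standard deviation of the frequency shift.
#' @param discordant_fraction fraction of shared loci perturbed.
#' @param seed RNG seed.
#' @return list: `gm_a`, `gm_b`, `truth` (ids of shared, a-only, b-only,
#'   perturbed loci and the realized frequency shifts).
#' @export
simulate_caller_pair <- function(gm, overlap_fraction = 0.6,
                                 af_perturb_sd = 0.1,
                                 discordant_fraction = 0.1, seed = NULL) {
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in (0, 1]")
  L <- length(gm$locus_ids)
  with_seed(seed, {
    shared <- sort(sample.int(L, round(overlap_fraction * L)))
    rest <- setdiff(seq_len(L), shared)
    a_only <- rest[seq_along(rest) %% 2 == 1]
    b_only <- setdiff(rest, a_only)
    gm_a <- gm[, sort(c(shared, a_only))]
    gm_b <- gm[, sort(c(shared, b_only))]
    n_pert <- round(discordant_fraction * length(shared))
    pert <- if (n_pert > 0) sort(sample(shared, n_pert)) else integer(0)
    shifts <- numeric(0)
    if (n_pert > 0) {
      jb <- match(gm$locus_ids[pert], gm_b$locus_ids)
      p0 <- alt_freq(gm)[pert]
      shifts <- stats::rnorm(n_pert, 0, af_perturb_sd)
      p1 <- pmin(pmax(p0 + shifts, 0.01), 0.99)
      for (t in seq_along(jb)) {
        ok <- !is.na(gm_b$calls[, jb[t]])
        gm_b$calls[ok, jb[t]] <- stats::rbinom(sum(ok), 2, p1[t])
      }
    }
    list(gm_a = gm_a, gm_b = gm_b,
         truth = list(shared = gm$locus_ids[shared],
                      a_only = gm$locus_ids[a_only],
                      b_only = gm$locus_ids[b_only],
                      perturbed = gm$locus_ids[pert], shifts = shifts))
  })
}

#' Simulate barcoded single-end GBS reads
#'
#' Writes a FASTQ in which a `valid_fraction` share of reads begin with a
#' registered barcode followed by a cut-site remnant (and are long
#' enough to trim); the remainder are corrupted either in the barcode or
#' in the remnant. Per-read truth labels are returned.
#'
#' @param scheme a [barcode_scheme()].
#' @param n_reads number of reads to write.
#' @param valid_fraction expected fraction of valid reads.
#' @param path output FASTQ path.
#' @param seed RNG seed.
#' @return list: `path`, `truth` (data frame read, sample, valid).
#' @export
simulate_gbs_reads <- function(scheme, n_reads, valid_fraction = 0.574,
                               path = tempfile(fileext = ".fastq"),
                               seed = NULL) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (n_reads <= 0) stop("n_reads must be positive")
  bc <- names(scheme$barcodes)
  rl <- nchar(scheme$cut_remnant[1])
  body_len <- scheme$trim_length - rl
  rand_dna <- function(n, len)
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
  # a remnant-length motif guaranteed outside the remnant set
  bad_remnant <- strrep("G", rl)
  if (bad_remnant %in% scheme$cut_remnant) bad_remnant <- strrep("A", rl)
  with_seed(seed, {
    valid <- stats::runif(n_reads) < valid_fraction
    which_bc <- sample(seq_along(bc), n_reads, replace = TRUE)
    remn <- sample(scheme$cut_remnant, n_reads, replace = TRUE)
    barcode <- bc[which_bc]
    # corruption: half bad barcode (leading N), half bad remnant
    bad_bc <- !valid & stats::runif(n_reads) < 0.5
    barcode[bad_bc] <- vapply(nchar(barcode[bad_bc]), function(l)
      paste0("N", strrep("A", l - 1)), character(1))
    remn[!valid & !bad_bc] <- bad_remnant
    seqs <- paste0(barcode, remn, rand_dna(n_reads, body_len))
    qual <- vapply(nchar(seqs), function(l) strrep("I", l), character(1))
    con <- file(path, "w")
    writeLines(paste0("@read", seq_len(n_reads), "\n", seqs, "\n+\n", qual), con)
    close(con)
    list(path = path,
         truth = data.frame(read = seq_len(n_reads),
                            sample = unname(scheme$barcodes[which_bc]),
                            valid = valid))
  })
}
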