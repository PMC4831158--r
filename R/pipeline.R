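#' Assemble a pipeline configuration
#'
#' Collects everything one end-to-end run needs: either a simulation
#' config or paths to input files, the QC cascade parameters, analysis
#' settings and a master seed from which every stochastic stage derives
#' its own seed (no stage touches the global RNG stream implicitly).
#' A YAML file with the same nested structure can be given instead of a
#' list.
#'
#' @param input either `list(sim = sim_config(...))` or
#'   `list(vcf_a = path, vcf_b = path or NULL, popmap = path)`.
#' @param cascade a [cascade_params()].
#' @param analysis named list; recognised entries (with defaults):
#'   `fst_n_perm` (999), `locus_fst_n_perm` (499), `amova_n_perm` (499),
#'   `outlier_n_sim` (20000), `mantel_n_perm` (999), `mantel_loci`
#'   (`"significant"` or `"all"`), `locus_p_threshold` (0.01),
#'   `snps_per_tag` (1.45), `tag_length` (64).
#' @param seed master seed (mandatory).
#' @param outdir output directory (created if absent).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, cascade = cascade_params(),
                            analysis = list(), seed, outdir) {
  defaults <- list(fst_n_perm = 999L, locus_fst_n_perm = 499L,
                   amova_n_perm = 499L, outlier_n_sim = 20000L,
                   mantel_n_perm = 999L, mantel_loci = "significant",
                   locus_p_threshold = 0.01,
                   snps_per_tag = 1.45, tag_length = 64)
  analysis <- utils::modifyList(defaults, analysis)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(input = input, cascade = cascade, analysis = analysis,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys `input`, `cascade`, `analysis`,
#'   `seed`, `outdir`.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (!is.null(input$sim)) input$sim <- do.call(sim_config, input$sim)
  pipeline_config(input = input,
                  cascade = do.call(cascade_params, y$cascade %||% list()),
                  analysis = y$analysis %||% list(),
                  seed = y$seed, outdir = y$outdir)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, the QC cascade, diversity, population
#' structure (pairwise and per-locus FST, AMOVA, outlier scan) and the
#' Mantel isolation-by-distance test, writing every result table, a
#' timestamped log, a machine-readable stage-status file and run
#' metadata into `config$outdir`. Reruns with the same config reproduce
#' every result table (the log carries wall-clock timestamps).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "log.txt")
  status <- list()
  say <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                           sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  stage <- function(name, expr) {
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      status[[name]] <<- "error"
      write_status()
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    status[[name]] <<- "ok"
    say("stage %s: done", name)
    res
  }
  write_status <- function() {
    utils::write.table(
      data.frame(stage = names(status), status = unlist(status)),
      file.path(config$outdir, "stage_status.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  an <- config$analysis
  seeds <- lapply(stats::setNames(1:6, c("sim", "caller", "fst", "amova",
                                         "outlier", "mantel")),
                  function(k) derive_seed(config$seed, k))

  dat <- stage("input", {
    if (!is.null(config$input$sim)) {
      cfg <- config$input$sim
      cfg$seed <- seeds$sim
      sim <- simulate_island_genotypes(cfg)
      pair <- simulate_caller_pair(sim$genotypes, seed = seeds$caller)
      list(gm_a = pair$gm_a, gm_b = pair$gm_b, popmap = sim$popmap,
           truth = sim$truth)
    } else {
      list(gm_a = load_genotypes(config$input$vcf_a),
           gm_b = if (!is.null(config$input$vcf_b))
                    load_genotypes(config$input$vcf_b),
           popmap = load_population_map(config$input$popmap), truth = NULL)
    }
  })

  filt <- stage("filter", {
    out <- run_cascade(dat$gm_a, dat$gm_b, config$cascade)
    save_genotypes(out$genotypes, file.path(config$outdir, "filtered.vcf"))
    write_report(out$report, file.path(config$outdir, "filter_report.tsv"))
    out
  })
  gm <- filt$genotypes
  popmap <- dat$popmap[dat$popmap$sample %in% gm$sample_ids, ]

  div <- stage("diversity", {
    pim <- pairwise_pi(gm)
    pops <- pi_by_population(pim, popmap)
    pops$within$adjusted <- adjusted_pi(pops$within$mean, an$snps_per_tag,
                                        an$tag_length)
    write_report(pops$within, file.path(config$outdir, "pi_within.tsv"))
    utils::write.table(pops$between, file.path(config$outdir, "pi_between.tsv"),
                       sep = "\t", quote = FALSE)
    list(pi_matrix = pim, summary = pops,
         locus_stats = locus_stats(gm, popmap))
  })

  struct <- stage("structure", {
    fst <- pairwise_fst(gm, popmap, n_perm = an$fst_n_perm, seed = seeds$fst)
    utils::write.table(fst$fst, file.path(config$outdir, "fst_pairwise.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(fst$p, file.path(config$outdir, "fst_pairwise_p.tsv"),
                       sep = "\t", quote = FALSE)
    lf <- locus_fst_test(gm, popmap, n_perm = an$locus_fst_n_perm,
                         seed = seeds$fst)
    am <- amova(gm, popmap, n_perm = an$amova_n_perm, seed = seeds$amova)
    write_report(am$table, file.path(config$outdir, "amova.tsv"))
    outl <- fdist_outliers(gm, popmap, n_sim = an$outlier_n_sim,
                           seed = seeds$outlier)
    write_report(outl$stats, file.path(config$outdir, "outliers.tsv"))
    write_report(lf, file.path(config$outdir, "locus_fst.tsv"))
    list(fst = fst, locus_fst = lf, amova = am, outliers = outl)
  })

  mant <- stage("mantel", {
    loci <- if (identical(an$mantel_loci, "significant")) {
      sig <- struct$locus_fst$locus[!is.na(struct$locus_fst$p) &
                                      struct$locus_fst$p < an$locus_p_threshold]
      if (length(sig) == 0) gm$locus_ids else sig
    } else gm$locus_ids
    gd <- genetic_distance_matrix(gm, loci)
    geod <- geo_distance_matrix(match_popmap(gm, popmap))
    mt <- mantel_test(gd, geod, n_perm = an$mantel_n_perm, seed = seeds$mantel)
    mt$n_loci_used <- length(loci)
    jsonlite::write_json(mt[c("r", "r2", "p", "n_perm", "n_loci_used")],
                         file.path(config$outdir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)
    mt
  })

  meta <- list(package_version = as.character(utils::packageVersion("acropipe")),
               r_version = R.version.string, seed = config$seed,
               derived_seeds = seeds, analysis = an,
               cascade = unclass(config$cascade))
  jsonlite::write_json(meta, file.path(config$outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_status()
  say("pipeline complete")
  invisible(list(data = dat, filter = filt, diversity = div,
                 structure = struct, mantel = mant, metadata = meta))
}
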