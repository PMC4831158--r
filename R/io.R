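# IUPAC ambiguity codes for the ten unordered nucleotide pairs
IUPAC_HET <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_code <- function(a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))
  unname(IUPAC_HET[key])
}

#' Load a genotype matrix from VCF or HapMap
#'
#' Reads biallelic SNPs into a [genotype_matrix()]. Multi-allelic records,
#' indels and records with non-ACGT alleles are dropped with a warning that
#' reports how many; nothing is dropped silently. VCF per-genotype depth
#' (`DP`) is carried into the depth slot when present. HapMap genotypes are
#' single IUPAC letters; heterozygote codes decode to dosage 1 and unknown
#' letters become missing calls (with a warning), mirroring how tolerant
#' TASSEL-era tooling treats dirty cells.
#'
#' @param path file to read.
#' @param format `"vcf"`, `"hapmap"`, or `"auto"` (sniff the header:
#'   `##fileformat=VCF` vs. a leading `rs#` column).
#' @return a validated `genotype_matrix`.
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L)
    format <- if (startsWith(head1, "##fileformat=VCF")) "vcf"
      else if (startsWith(head1, "rs#") || startsWith(head1, "\"rs#\"")) "hapmap"
      else stop("cannot detect format from header of ", path)
  }
  switch(format, vcf = load_vcf(path), hapmap = load_hapmap(path))
}

load_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    warning(n_drop, " non-biallelic/non-SNP record(s) dropped on load")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate locus ids in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- gt_to_dosage(gt)            # loci x samples
  if (anyDuplicated(colnames(gt))) stop("duplicate sample ids in ", path)
  depth <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (all(grepl("DP", fmt))) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    depth <- t(dp)
    depth[is.na(depth)] <- 0L
  }
  genotype_matrix(t(dose),
                  scaffold = fix[, "CHROM"], position = as.integer(fix[, "POS"]),
                  ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
                  sample_ids = colnames(gt), locus_ids = ids, depth = depth)
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  core <- sub(":.*$", "", gt)
  core <- gsub("|", "/", core, fixed = TRUE)
  d[core %in% c("0/0")] <- 0L
  d[core %in% c("0/1", "1/0")] <- 1L
  d[core %in% c("1/1")] <- 2L
  d
}

HAPMAP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

load_hapmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(colnames(tab)[1:11], HAPMAP_META))
    stop("not a TASSEL-style HapMap header in ", path)
  n_samp <- ncol(tab) - 11L
  if (n_samp < 1) stop("HapMap file has no sample columns")
  alle <- strsplit(tab$alleles, "/", fixed = TRUE)
  ref <- vapply(alle, `[`, "", 1L); alt <- vapply(alle, `[`, "", 2L)
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep)) warning(sum(!keep), " non-biallelic-SNP HapMap row(s) dropped on load")
  tab <- tab[keep, , drop = FALSE]; ref <- ref[keep]; alt <- alt[keep]
  cells <- as.matrix(tab[, -(1:11), drop = FALSE])   # loci x samples
  het <- iupac_code(ref, alt)
  dose <- matrix(NA_integer_, nrow(cells), ncol(cells))
  dose[cells == ref[row(cells)]] <- 0L
  dose[cells == het[row(cells)]] <- 1L
  dose[cells == alt[row(cells)]] <- 2L
  unknown <- !(cells %in% c("N", "-")) & is.na(dose)
  if (any(unknown))
    warning(sum(unknown), " unrecognised HapMap genotype letter(s) set to missing")
  ids <- tab[["rs#"]]
  if (anyDuplicated(ids)) stop("duplicate locus ids in ", path)
  if (anyDuplicated(colnames(cells))) stop("duplicate sample ids in ", path)
  genotype_matrix(t(dose),
                  scaffold = tab$chrom, position = as.integer(tab$pos),
                  ref_allele = ref, alt_allele = alt,
                  sample_ids = colnames(cells), locus_ids = ids)
}

#' Write a genotype matrix to VCF or HapMap
#'
#' The emitted file reloads (via [load_genotypes()]) to an equal matrix.
#' VCF output carries per-genotype depth as the `DP` FORMAT field when the
#' matrix has depth; the HapMap format cannot represent depth and drops it
#' with a warning.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @param format `"vcf"` or `"hapmap"`.
#' @return `path`, invisibly.
#' @export
save_genotypes <- function(gm, path, format = c("vcf", "hapmap")) {
  format <- match.arg(format)
  validate_genotype_matrix(gm)
  if (format == "vcf") save_vcf(gm, path) else save_hapmap(gm, path)
  invisible(path)
}

save_vcf <- function(gm, path) {
  has_dp <- !is.null(gm$depth)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=acropipe",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", gm$sample_ids), collapse = "\t"))
  gtxt <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L], nrow = nrow(gm$calls))
  gtxt[is.na(gm$calls)] <- "./."
  if (has_dp) gtxt <- matrix(paste(gtxt, gm$depth, sep = ":"), nrow = nrow(gtxt))
  body <- vapply(seq_along(gm$locus_ids), function(j) {
    paste(c(gm$scaffold[j], gm$position[j], gm$locus_ids[j],
            gm$ref_allele[j], gm$alt_allele[j], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", gtxt[, j]), collapse = "\t")
  }, character(1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, body), con)
}

save_hapmap <- function(gm, path) {
  if (!is.null(gm$depth))
    warning("HapMap format cannot carry depth; depth dropped")
  het <- iupac_code(gm$ref_allele, gm$alt_allele)
  cells <- vapply(seq_along(gm$locus_ids), function(j) {
    v <- c(gm$ref_allele[j], het[j], gm$alt_allele[j])[gm$calls[, j] + 1L]
    v[is.na(gm$calls[, j])] <- "N"
    v
  }, character(length(gm$sample_ids)))
  cells <- matrix(cells, ncol = length(gm$locus_ids))
  tab <- data.frame(gm$locus_ids, paste(gm$ref_allele, gm$alt_allele, sep = "/"),
                    gm$scaffold, gm$position, "+", "NA", "NA", "NA", "NA", "NA", "NA",
                    t(cells), check.names = FALSE)
  colnames(tab) <- c(HAPMAP_META, gm$sample_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load a population map
#'
#' A TSV with header `sample population group lat lon` giving, for every
#' sample, its population, the group the population belongs to (e.g. a
#' region), and the collection coordinates in decimal degrees.
#'
#' @param path TSV file.
#' @return a `population_map`: a data frame with those five columns.
#' @export
load_population_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  population_map(tab)
}

#' Construct/validate a population map from a data frame
#'
#' @param df data frame with columns `sample`, `population`, `group`,
#'   `lat`, `lon`.
#' @return a validated `population_map`.
#' @export
population_map <- function(df) {
  need <- c("sample", "population", "group", "lat", "lon")
  if (!all(need %in% colnames(df)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$sample)) stop("duplicate sample id in population map")
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude out of [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude out of [-180, 180]")
  pg <- unique(df[, c("population", "group")])
  if (anyDuplicated(pg$population)) stop("a population is assigned to two groups")
  class(df) <- c("population_map", "data.frame")
  df
}

# check a popmap covers every sample of gm, returning the map ordered as gm
match_popmap <- function(gm, popmap) {
  i <- match(gm$sample_ids, popmap$sample)
  if (anyNA(i))
    stop("samples missing from population map: ",
         paste(gm$sample_ids[is.na(i)], collapse = ", "))
  popmap[i, , drop = FALSE]
}

#' Build a filter report
#'
#' An ordered audit trail of a QC cascade: one row per stage with the
#' parameters used, sample/locus counts in and out, and the identifiers
#' removed. Counts must chain (the out-counts of a stage are the in-counts
#' of the next) and never increase.
#'
#' @param stages a list of stage records, each a list with elements
#'   `stage`, `params` (named list), `samples_in`, `samples_out`,
#'   `loci_in`, `loci_out`, `removed_samples`, `removed_loci`.
#' @return a `filter_report` data frame.
#' @export
filter_report <- function(stages) {
  if (length(stages) == 0) stop("empty filter cascade")
  rows <- lapply(stages, function(s) {
    data.frame(stage = s$stage,
               params = paste(names(s$params), unlist(s$params),
                              sep = "=", collapse = ";"),
               samples_in = s$samples_in, samples_out = s$samples_out,
               loci_in = s$loci_in, loci_out = s$loci_out,
               removed_samples = paste(s$removed_samples, collapse = ","),
               removed_loci = paste(s$removed_loci, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (any(rep$samples_out > rep$samples_in) || any(rep$loci_out > rep$loci_in))
    stop("filter stage increased a count")
  n <- nrow(rep)
  if (n > 1 && (any(rep$samples_in[-1] != rep$samples_out[-n]) ||
                any(rep$loci_in[-1] != rep$loci_out[-n])))
    stop("stage counts do not chain")
  class(rep) <- c("filter_report", "data.frame")
  rep
}

#' Write a filter report (or any summary data frame) as TSV
#'
#' @param report a non-empty `filter_report` or data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (NROW(report) == 0) stop("empty report")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# acropipe report (", NROW(report), " rows)"), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
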