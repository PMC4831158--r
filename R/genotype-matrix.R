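#' Genotype matrix container
#'
#' The central data structure of the pipeline: a samples x loci matrix of
#' biallelic SNP genotypes coded as alt-allele dosage (0, 1, 2; `NA` =
#' missing), together with locus coordinates, alleles and (optionally) the
#' per-call read depth supporting each genotype.
#'
#' @param calls integer matrix, samples x loci, entries in \{0, 1, 2, NA\}.
#'   Row names are taken as sample ids and column names as locus ids when
#'   `sample_ids`/`locus_ids` are not given.
#' @param scaffold character vector, one scaffold/chromosome name per locus.
#' @param position integer vector of 1-based positions, one per locus.
#' @param ref_allele,alt_allele single-nucleotide alleles per locus; the
#'   dosage counts copies of `alt_allele`.
#' @param sample_ids,locus_ids unique labels; defaults to `dimnames(calls)`.
#' @param depth optional non-negative integer matrix with the same
#'   dimensions as `calls`: reads supporting each call. Depth 0 together
#'   with a missing call is the usual convention, but positive depth under
#'   a missing call is legal (a masked call keeps its depth).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, scaffold, position, ref_allele, alt_allele,
                            sample_ids = rownames(calls),
                            locus_ids = colnames(calls),
                            depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(locus_ids))  locus_ids  <- paste0("L", seq_len(ncol(calls)))
  dimnames(calls) <- list(sample_ids, locus_ids)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    dimnames(depth) <- dimnames(calls)
  }
  gm <- structure(
    list(sample_ids = as.character(sample_ids),
         locus_ids  = as.character(locus_ids),
         scaffold   = as.character(scaffold),
         position   = as.integer(position),
         ref_allele = as.character(ref_allele),
         alt_allele = as.character(alt_allele),
         calls = calls, depth = depth),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks every structural invariant: dimensions, the 4-symbol call
#' alphabet, distinct ref/alt alleles, positive positions, unique ids and
#' (when present) a depth matrix of matching shape.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; stops on the first violated invariant.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- length(gm$sample_ids); nl <- length(gm$locus_ids)
  if (anyDuplicated(gm$sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(gm$locus_ids))  stop("duplicate locus ids")
  if (!identical(dim(gm$calls), c(ns, nl)))
    stop("calls must be ", ns, " x ", nl)
  bad <- !(gm$calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls outside {0,1,2,NA}")
  if (length(gm$scaffold) != nl || length(gm$position) != nl ||
      length(gm$ref_allele) != nl || length(gm$alt_allele) != nl)
    stop("per-locus fields must have length ", nl)
  if (nl > 0 && any(gm$position < 1L, na.rm = FALSE)) stop("positions must be >= 1")
  if (any(gm$ref_allele == gm$alt_allele)) stop("ref and alt allele identical at some locus")
  if (!is.null(gm$depth)) {
    if (!identical(dim(gm$depth), dim(gm$calls))) stop("depth dimensions differ from calls")
    if (any(gm$depth < 0L, na.rm = TRUE)) stop("negative depth")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%s depth)\n",
              length(x$sample_ids), length(x$locus_ids),
              if (is.null(x$depth)) "no" else "with"))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (logical, integer or character).
#' @param j locus index (logical, integer or character).
#' @param ... ignored.
#' @return the subset, still a valid `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$locus_ids)
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$locus_ids)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  scaffold = x$scaffold[j], position = x$position[j],
                  ref_allele = x$ref_allele[j], alt_allele = x$alt_allele[j],
                  sample_ids = x$sample_ids[i], locus_ids = x$locus_ids[j],
                  depth = if (is.null(x$depth)) NULL else x$depth[i, j, drop = FALSE])
}

#' Dimensions of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return `c(n_samples, n_loci)`.
#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# locus keys used to match loci across callers
locus_keys <- function(gm) paste(gm$scaffold, gm$position, sep = ":")

# alt-allele frequency per locus over non-missing calls (NaN when all missing)
alt_freq <- function(gm) {
  colSums(gm$calls, na.rm = TRUE) / (2 * colSums(!is.na(gm$calls)))
}

# per-locus call rate
locus_call_rate <- function(gm) colMeans(!is.na(gm$calls))

# per-sample call rate
sample_call_rate <- function(gm) rowMeans(!is.na(gm$calls))
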