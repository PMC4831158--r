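#' Barcode scheme for GBS demultiplexing
#'
#' Maps inline DNA barcodes to sample ids and records the restriction
#' cut-site remnant that must follow the barcode. For ApeKI (G^CWGC) the
#' remnant at the read 5' end is `CAGC` or `CTGC`. Barcodes must be
#' prefix-free so that a read identifies at most one sample.
#'
#' @param barcodes named character vector: `names` are barcode sequences
#'   (4-8 nt typical), values are sample ids.
#' @param cut_remnant character vector of remnant motifs, all same length.
#' @param trim_length tag length after trimming (the remnant is the first
#'   part of the tag); 64 by default.
#' @return a `barcode_scheme`.
#' @export
barcode_scheme <- function(barcodes,
                           cut_remnant = c("CAGC", "CTGC"),
                           trim_length = 64L) {
  if (length(barcodes) == 0) stop("empty barcode scheme")
  bc <- names(barcodes)
  if (is.null(bc) || any(bc == "")) stop("barcodes must be the names of the vector")
  if (anyDuplicated(bc)) stop("duplicate barcode")
  if (length(unique(nchar(cut_remnant))) != 1) stop("cut remnants must share one length")
  if (trim_length <= 0) stop("trim_length must be positive")
  for (i in seq_along(bc)) for (j in seq_along(bc))
    if (i != j && startsWith(bc[j], bc[i]))
      stop("barcodes not prefix-free: ", bc[i], " prefixes ", bc[j])
  structure(list(barcodes = barcodes, cut_remnant = toupper(cut_remnant),
                 trim_length = as.integer(trim_length)),
            class = "barcode_scheme")
}

#' Read a barcode scheme from a TSV (`barcode sample`)
#' @param path TSV with header `barcode` and `sample`.
#' @inheritParams barcode_scheme
#' @return a `barcode_scheme`.
#' @export
load_barcode_scheme <- function(path, cut_remnant = c("CAGC", "CTGC"),
                                trim_length = 64L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  barcode_scheme(stats::setNames(tab$sample, tab$barcode),
                 cut_remnant, trim_length)
}

#' Demultiplex and trim single-end GBS reads
#'
#' Emulates the read-retention step of GBS tag pipelines: a read is kept
#' iff it starts with a known barcode immediately followed by a cut-site
#' remnant, and is long enough to yield a full tag. Retained reads are
#' trimmed to `trim_length` bases starting at the remnant (the barcode is
#' removed; the remnant stays at the tag 5' end). Matching is exact and
#' the whole stage is deterministic.
#'
#' @param fastq path to a FASTQ file (Phred scores are ignored).
#' @param scheme a [barcode_scheme()].
#' @param return_tags if `TRUE`, also return the trimmed tag sequences per
#'   sample (memory-heavy on large inputs).
#' @return a list: `counts` (named integer, retained reads per sample),
#'   `n_total`, `retained`, `discarded`, `short` (reads with valid
#'   barcode+remnant but too short to trim; included in `discarded`),
#'   `retained_fraction`, and optionally `tags`.
#' @export
demultiplex_trim <- function(fastq, scheme, return_tags = FALSE) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  lines <- readLines(fastq)
  if (length(lines) == 0) stop("empty FASTQ: ", fastq)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ record ", length(lines) %/% 4 + 1, ": truncated record")
  hdr <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[hdr], "@") | !startsWith(lines[hdr + 2], "+"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1])
  reads <- toupper(lines[hdr + 1])
  n_total <- length(reads)

  bc <- names(scheme$barcodes)
  rl <- nchar(scheme$cut_remnant[1])
  tl <- scheme$trim_length
  sample_of <- rep(NA_character_, n_total)
  bc_len <- rep(NA_integer_, n_total)
  for (L in sort(unique(nchar(bc)))) {
    hit <- match(substr(reads, 1, L), bc[nchar(bc) == L])
    found <- !is.na(hit) & is.na(sample_of)
    sample_of[found] <- scheme$barcodes[nchar(bc) == L][hit[found]]
    bc_len[found] <- L
  }
  has_remnant <- !is.na(sample_of) &
    substr(reads, bc_len + 1, bc_len + rl) %in% scheme$cut_remnant
  long_enough <- nchar(reads) >= ifelse(is.na(bc_len), Inf, bc_len) + tl
  keep <- has_remnant & long_enough
  short <- sum(has_remnant & !long_enough)

  counts <- table(factor(sample_of[keep], levels = unique(scheme$barcodes)))
  out <- list(counts = stats::setNames(as.integer(counts), names(counts)),
              n_total = n_total,
              retained = sum(keep), discarded = n_total - sum(keep),
              short = short,
              retained_fraction = sum(keep) / n_total)
  if (return_tags) {
    tags <- substr(reads[keep], bc_len[keep] + 1, bc_len[keep] + tl)
    out$tags <- split(Biostrings::DNAStringSet(tags), sample_of[keep])
  }
  out
}
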