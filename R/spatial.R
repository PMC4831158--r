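#' Great-circle distance matrix from collection coordinates
#'
#' Haversine distances (Earth radius 6371.0 km) between every pair of
#' samples in a population map.
#'
#' @param popmap a `population_map` with complete `lat`/`lon`.
#' @return symmetric sample x sample matrix of distances in km.
#' @export
geo_distance_matrix <- function(popmap) {
  miss <- is.na(popmap$lat) | is.na(popmap$lon)
  if (any(miss))
    stop("missing coordinates for: ", paste(popmap$sample[miss], collapse = ", "))
  xy <- cbind(popmap$lon, popmap$lat)
  d <- geosphere::distm(xy, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(d) <- list(popmap$sample, popmap$sample)
  d
}

#' Genetic distance matrix on allele dosages
#'
#' Euclidean distance between the alt-allele dosage vectors of each
#' sample pair over the loci non-missing in both, divided by the square
#' root of the number of loci used so that pairs with different amounts
#' of missing data stay comparable (i.e. the root-mean-square dosage
#' difference; set `scale = FALSE` for the raw Euclidean distance).
#'
#' @param gm a `genotype_matrix`.
#' @param loci subset of locus ids (or indices) to use; defaults to all.
#' @param scale divide by sqrt(number of loci used per pair).
#' @return symmetric sample x sample distance matrix.
#' @export
genetic_distance_matrix <- function(gm, loci = NULL, scale = TRUE) {
  if (!is.null(loci)) gm <- gm[, loci]
  if (length(gm$locus_ids) == 0) stop("empty locus subset")
  ns <- length(gm$sample_ids)
  d <- matrix(0, ns, ns, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(ns - 1)) {
    gi <- gm$calls[i, ]
    for (j in seq(i + 1, ns)) {
      gj <- gm$calls[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      n_ok <- sum(ok)
      v <- sum((gi[ok] - gj[ok])^2)
      d[i, j] <- d[j, i] <- if (n_ok == 0) NA_real_
        else if (scale) sqrt(v) / sqrt(n_ok) else sqrt(v)
    }
  }
  d
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from jointly permuting the rows and columns of one matrix. The
#' default p-value is two-sided: p = (1 + #\{|r_perm| >= |r|\}) /
#' (n_perm + 1).
#'
#' @param gd,geod symmetric distance matrices with zero diagonal, same
#'   sample order.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return list of class `mantel_result`: `r`, `r2`, `p`, `n_perm`,
#'   `seed`, `n`.
#' @export
mantel_test <- function(gd, geod, n_perm = 9999L, seed = NULL,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(identical(dim(gd), dim(geod)))
  if (!isTRUE(all.equal(gd, t(gd))) || !isTRUE(all.equal(geod, t(geod))))
    stop("matrices must be symmetric")
  if (any(diag(gd) != 0) || any(diag(geod) != 0))
    stop("matrices must have zero diagonal")
  lt <- lower.tri(gd)
  x <- gd[lt]; y <- geod[lt]
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
    stop("constant distance matrix; Mantel r undefined")
  r_obs <- stats::cor(x, y, use = "complete.obs")
  n <- nrow(gd)
  hits <- 0L
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      r_perm <- stats::cor(gd[idx, idx][lt], y, use = "complete.obs")
      hit <- if (alternative == "two.sided") abs(r_perm) >= abs(r_obs)
             else r_perm >= r_obs
      hits <- hits + hit
    }
  })
  structure(list(r = r_obs, r2 = r_obs^2, p = perm_p(hits, n_perm),
                 n_perm = as.integer(n_perm), seed = seed, n = n),
            class = "mantel_result")
}
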