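#' Jaccard genetic distance between accessions
#'
#' Each locus expands to two presence bits mirroring the two-row report:
#' reference present for calls \{0, 1\}, alternate present for calls
#' \{1, 2\}. For a pair of accessions the distance is
#' 1 - shared bits / union bits over loci non-missing in both, so a
#' heterozygote shares one bit with either homozygote (0 vs 1 gives 0.5, not
#' 1).
#'
#' @param gm a [genotype_matrix()] with at least 2 accessions.
#' @return symmetric matrix of class `dist_matrix` with zero diagonal;
#'   `NA` (with a warning) for pairs with no jointly non-missing informative
#'   loci.
#' @export
jaccard_distance <- function(gm) {
  g <- unclass(gm)
  if (nrow(g) < 2L) stop("need at least 2 accessions")
  M <- (!is.na(g)) * 1                       # validity mask
  R <- (!is.na(g) & g <= 1L) * 1             # ref-allele present
  A <- (!is.na(g) & g >= 1L) * 1             # alt-allele present
  shared <- R %*% t(R) + A %*% t(A)
  union_ <- R %*% t(M) + M %*% t(R) - R %*% t(R) +
    A %*% t(M) + M %*% t(A) - A %*% t(A)
  d <- 1 - shared / union_
  if (any(union_ == 0)) {
    warning("accession pair(s) with no jointly scored loci; distance NA")
    d[union_ == 0] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  attr(d, "metric") <- "jaccard"
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Per-group summary of a distance matrix
#'
#' Mirrors a min/max table per breeding-period group and overall, naming the
#' accession pairs attaining each extreme (ties broken by lexicographic
#' accession id).
#'
#' @param D symmetric distance matrix with accession dimnames.
#' @param meta an [accession_meta()] table.
#' @return data.frame (group, n, min, min_pair, max, max_pair); singleton
#'   groups carry `NA` extremes.
#' @export
group_distance_summary <- function(D, meta) {
  groups <- period_split(meta)
  groups$total <- meta$accession_id
  rows <- lapply(names(groups), function(gname) {
    acc <- sort(groups[[gname]])
    if (length(acc) < 2L) {
      return(data.frame(group = gname, n = length(acc), min = NA_real_,
                        min_pair = NA_character_, max = NA_real_,
                        max_pair = NA_character_, stringsAsFactors = FALSE))
    }
    sub <- D[acc, acc, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    pick <- function(target) {
      hit <- which(sub == target, arr.ind = TRUE)
      hit <- hit[order(rownames(sub)[hit[, 1]], colnames(sub)[hit[, 2]]),
                 , drop = FALSE]
      paste(rownames(sub)[hit[1, 1]], colnames(sub)[hit[1, 2]], sep = "--")
    }
    lo <- min(sub, na.rm = TRUE)
    hi <- max(sub, na.rm = TRUE)
    data.frame(group = gname, n = length(acc), min = lo,
               min_pair = pick(lo), max = hi, max_pair = pick(hi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, keeps positive eigenvalues and
#' scales eigenvectors by the square root of their eigenvalue. Negative
#' eigenvalues (non-Euclidean distances) are dropped without correction;
#' percent variance is relative to the positive-eigenvalue total.
#'
#' @param D symmetric distance matrix without missing entries.
#' @param n_axes number of axes to return (default 3, capped at the number
#'   of positive eigenvalues).
#' @return list with `coordinates` (accessions x axes), `eigenvalues`
#'   (positive ones) and `pct_variance`.
#' @export
pcoa <- function(D, n_axes = 3) {
  D <- as.matrix(D)
  if (any(is.na(D))) {
    stop("distance matrix has missing entries; impute or subset first")
  }
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values), 1)
  lambda <- e$values[pos]
  vec <- e$vectors[, pos, drop = FALSE]
  k <- min(n_axes, length(lambda))
  coords <- sweep(vec[, seq_len(k), drop = FALSE], 2,
                  sqrt(lambda[seq_len(k)]), `*`)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = lambda,
       pct_variance = 100 * lambda / sum(lambda))
}
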