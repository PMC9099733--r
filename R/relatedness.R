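#' Method-of-moments identity-by-descent (PI-HAT) matrix
#'
#' PLINK-style moments estimator: for every accession pair the observed
#' identity-by-state class counts (IBS 0/1/2) over jointly non-missing,
#' polymorphic loci are compared with their expectations under the panel
#' allele frequencies to estimate P(IBD = 0/1/2); negative components are
#' truncated at 0 and the triple renormalised. PI-HAT = P(IBD=2) +
#' P(IBD=1)/2, clipped to \[0, 1\].
#'
#' @param gm a [genotype_matrix()].
#' @param allele_freqs optional per-locus alternate frequencies (default:
#'   estimated from the full panel). Monomorphic loci are excluded.
#' @param min_loci pairs with fewer jointly non-missing loci are flagged
#'   low-confidence (default 50).
#' @return list with `pihat` (symmetric matrix, unit diagonal, class
#'   `ibd_matrix`), `n_loci` (jointly scored loci per pair) and
#'   `low_confidence` (logical matrix).
#' @export
ibd_pihat <- function(gm, allele_freqs = NULL, min_loci = 50) {
  g <- unclass(gm)
  p <- if (is.null(allele_freqs)) allele_freq(gm)$p else allele_freqs
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  M <- (!is.na(g)) * 1
  I0 <- (!is.na(g) & g == 0L) * 1
  I1 <- (!is.na(g) & g == 1L) * 1
  I2 <- (!is.na(g) & g == 2L) * 1
  n_joint <- M %*% t(M)
  ibs2 <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)
  ibs0 <- I0 %*% t(I2) + I2 %*% t(I0)
  ibs1 <- n_joint - ibs2 - ibs0
  # per-locus IBS-class expectations given IBD state (random union of gametes)
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e1_z1 <- 2 * p^2 * q + 2 * p * q^2
  e2_z0 <- p^4 + q^4 + 4 * p^2 * q^2
  e2_z1 <- p^3 + q^3 + p^2 * q + p * q^2
  pairsum <- function(e) (M * rep(e, each = nrow(M))) %*% t(M)
  E0z0 <- pairsum(e0_z0)
  E1z0 <- pairsum(e1_z0)
  E1z1 <- pairsum(e1_z1)
  E2z0 <- pairsum(e2_z0)
  E2z1 <- pairsum(e2_z1)
  z0 <- ibs0 / E0z0
  z1 <- (ibs1 - z0 * E1z0) / E1z1
  z2 <- (ibs2 - z0 * E2z0 - z1 * E2z1) / n_joint
  z0 <- pmax(z0, 0); z1 <- pmax(z1, 0); z2 <- pmax(z2, 0)
  tot <- z0 + z1 + z2
  tot[tot == 0] <- 1
  pihat <- (z2 + z1 / 2) / tot
  pihat <- pmin(pmax(pihat, 0), 1)
  diag(pihat) <- 1
  dimnames(pihat) <- list(rownames(g), rownames(g))
  class(pihat) <- c("ibd_matrix", class(pihat))
  low <- n_joint < min_loci
  diag(low) <- FALSE
  list(pihat = pihat, n_loci = n_joint, low_confidence = low)
}

#' Cluster duplicate accessions from an IBD matrix
#'
#' Connected components of the graph joining pairs with PI-HAT above the
#' cutoff (single-link / transitive closure); components of size >= 2 are
#' reported as duplicate groups.
#'
#' @param ibd PI-HAT matrix from [ibd_pihat()].
#' @param cutoff duplicates defined as PI-HAT > cutoff (default 0.95,
#'   strict).
#' @return list of character vectors of accession ids (sorted within and
#'   between clusters); empty list when no pair exceeds the cutoff.
#' @export
duplicate_clusters <- function(ibd, cutoff = 0.95) {
  pm <- unclass(ibd)
  n <- nrow(pm)
  adj <- pm > cutoff
  diag(adj) <- FALSE
  comp <- seq_len(n)
  # union-find by repeated label propagation (n is small)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cl <- split(rownames(pm), comp)
  cl <- cl[lengths(cl) >= 2L]
  cl <- lapply(cl, sort)
  names(cl) <- NULL
  cl[order(vapply(cl, `[`, character(1), 1L))]
}

#' Multi-evidence duplicate verdict table
#'
#' Combines passport flags, genetic distance, admixture structure and IBD
#' into one verdict per candidate duplicate group (passport-flagged groups
#' and IBD clusters). The final verdict requires low distance, identical
#' dominant gene pool and high IBD; the passport column is informative only.
#'
#' @param meta an [accession_meta()] table.
#' @param D distance matrix over the same accessions.
#' @param Q admixture membership matrix (accessions x pools, rownames set).
#' @param clusters IBD clusters from [duplicate_clusters()].
#' @param d_low pairwise-distance ceiling for "genetically identical"
#'   (default 0.05).
#' @return data.frame (group_id, accessions, passport_says, distance_low,
#'   structure_same, ibd_high, verdict).
#' @export
duplicate_verdict <- function(meta, D, Q, clusters, d_low = 0.05) {
  acc_all <- meta$accession_id
  if (!all(acc_all %in% rownames(D)) || !all(acc_all %in% rownames(Q))) {
    stop("accession missing from distance or membership input")
  }
  passport <- split(meta$accession_id, meta$passport_duplicate_group)
  passport <- lapply(passport[lengths(passport) >= 2L], sort)
  cand <- c(passport, clusters)
  keys <- vapply(cand, paste, character(1), collapse = "|")
  cand <- cand[!duplicated(keys)]
  if (!length(cand)) {
    return(data.frame(group_id = character(), accessions = character(),
                      passport_says = logical(), distance_low = logical(),
                      structure_same = logical(), ibd_high = logical(),
                      verdict = logical(), stringsAsFactors = FALSE))
  }
  in_cluster <- function(acc) {
    any(vapply(clusters, function(cl) all(acc %in% cl), logical(1)))
  }
  pass_flag <- function(acc) {
    pg <- meta$passport_duplicate_group[match(acc, meta$accession_id)]
    !any(is.na(pg)) && length(unique(pg)) == 1L
  }
  dominant_pool <- function(a) which.max(Q[a, ])
  rows <- lapply(seq_along(cand), function(i) {
    acc <- cand[[i]]
    dl <- all(D[acc, acc][upper.tri(D[acc, acc])] < d_low)
    ss <- length(unique(vapply(acc, dominant_pool, integer(1)))) == 1L
    ih <- in_cluster(acc)
    data.frame(group_id = paste0("dup", i),
               accessions = paste(acc, collapse = ";"),
               passport_says = pass_flag(acc), distance_low = dl,
               structure_same = ss, ibd_high = ih,
               verdict = dl && ss && ih, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
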