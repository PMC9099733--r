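# Independent brute-force oracles used across test files.

# expected distinct-allele count in a subsample of g copies, by enumeration
# of all C(N, g) subsets (N <= 8 in tests)
brute_rarefied_richness <- function(n_ref, n_alt, g) {
  copies <- c(rep(0L, n_ref), rep(1L, n_alt))
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# two-population FST by explicit allele counting, no shared code with
# fst_per_locus()
brute_fst <- function(calls_a, calls_b) {
  count_p <- function(calls) {
    calls <- calls[!is.na(calls)]
    alt <- sum(calls == 2L) * 2L + sum(calls == 1L)
    alt / (2 * length(calls))
  }
  pa <- count_p(calls_a)
  pb <- count_p(calls_b)
  ht <- 2 * mean(c(pa, pb)) * (1 - mean(c(pa, pb)))
  hs <- mean(c(2 * pa * (1 - pa), 2 * pb * (1 - pb)))
  if (ht == 0) 0 else (ht - hs) / ht
}

# pairwise Jaccard distance for two call vectors via explicit bit sets
brute_jaccard <- function(a, b) {
  shared <- 0L
  union_ <- 0L
  for (l in seq_along(a)) {
    if (is.na(a[l]) || is.na(b[l])) next
    bits_a <- c(a[l] <= 1L, a[l] >= 1L)
    bits_b <- c(b[l] <= 1L, b[l] >= 1L)
    shared <- shared + sum(bits_a & bits_b)
    union_ <- union_ + sum(bits_a | bits_b)
  }
  if (union_ == 0L) NA_real_ else 1 - shared / union_
}

# orthogonal Procrustes residual after centering and optimal rotation
procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(t(Y) %*% X)
  R <- s$u %*% t(s$v)
  sqrt(sum((X - Y %*% R)^2))
}

# exhaustive minimum allele-class cover over all accession subsets
brute_min_cover_size <- function(gm) {
  bits <- dartpool:::allele_class_bits(gm)
  bits <- bits[, colSums(bits) > 0, drop = FALSE]
  n <- nrow(bits)
  for (size in 1:n) {
    subs <- utils::combn(n, size)
    for (j in seq_len(ncol(subs))) {
      if (all(colSums(bits[subs[, j], , drop = FALSE]) > 0)) return(size)
    }
  }
  n
}

# align an estimated Q to a reference Q* over column permutations, return MAE
aligned_q_mae <- function(Q_hat, Q_star) {
  K <- ncol(Q_star)
  perms <- dartpool:::permutations_of(K)
  best <- Inf
  for (pp in perms) {
    best <- min(best, mean(abs(Q_hat[, pp, drop = FALSE] - Q_star)))
  }
  best
}

# small deterministic panel builder for targeted cases
tiny_gm <- function(calls, ids = NULL) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("M%02d", seq_len(ncol(calls)))
  }
  genotype_matrix(calls)
}

# printed substitution-type count matrix (12 ordered changes x columns),
# used as an input table in SNP-type arithmetic tests
printed_snp_counts <- function() {
  m <- rbind(
    `A>G` = c(1910, 186, 263, 235, 206, 278, 183, 245, 314),
    `G>A` = c(1752, 178, 254, 211, 168, 249, 193, 228, 271),
    `C>T` = c(1754, 184, 248, 252, 165, 240, 169, 243, 253),
    `T>C` = c(1604, 160, 222, 244, 145, 207, 151, 237, 238),
    `A>C` = c(522, 33, 70, 75, 47, 70, 56, 70, 101),
    `A>T` = c(292, 37, 44, 24, 34, 45, 33, 32, 43),
    `G>C` = c(890, 101, 119, 107, 90, 116, 80, 125, 152),
    `G>T` = c(525, 56, 95, 65, 45, 72, 52, 72, 68),
    `C>A` = c(533, 45, 79, 67, 44, 72, 47, 91, 88),
    `C>G` = c(1027, 89, 170, 146, 86, 118, 103, 128, 187),
    `T>A` = c(291, 28, 45, 39, 23, 48, 32, 36, 40),
    `T>G` = c(555, 53, 86, 76, 56, 59, 59, 64, 102)
  )
  colnames(m) <- c("Total", paste0(1:7, "H"), "Un")
  m
}

# published per-chromosome locus counts for the spacing arithmetic
printed_locus_counts <- function() {
  c(`1H` = 1150, `2H` = 1695, `3H` = 1541, `4H` = 1109, `5H` = 1574,
    `6H` = 1158, `7H` = 1571, Un = 1857)
}
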