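#' Maximum-likelihood admixture fit (EM)
#'
#' Fits the binomial admixture model: each accession i has membership
#' proportions q_i over K ancestral pools with pool allele frequencies p_k,
#' and its alternate-allele dosage g_il is Binomial(2, sum_k q_ik p_kl).
#' The log-likelihood is maximised by the standard multiplicative EM updates
#' from a seeded random start; missing calls are skipped. This is the same
#' likelihood the Bayesian admixture programs sample from, maximised instead
#' of integrated.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of ancestral pools (>= 1).
#' @param seed RNG seed for the random start.
#' @param max_iter maximum EM iterations (default 2000).
#' @param tol stop when the log-likelihood gain drops below `tol`
#'   (default 1e-6).
#' @return list of class `admixture_fit`: `K`, `Q` (accessions x K,
#'   row-stochastic), `P` (K x loci in \[1e-6, 1-1e-6\]), `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `seed`.
#' @export
fit_admixture <- function(gm, K, seed = NULL, max_iter = 2000, tol = 1e-6) {
  g <- unclass(gm)
  n <- nrow(g)
  L <- ncol(g)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of accessions")
  A <- ifelse(is.na(g), 0, g)                # alt-allele count
  B <- ifelse(is.na(g), 0, 2 - g)            # ref-allele count
  Lw <- rowSums(!is.na(g))                   # scored loci per accession
  eps <- 1e-6
  if (K == 1L) {
    P <- matrix(clip01(allele_freq(gm)$p, eps), nrow = 1)
    P[is.na(P)] <- 0.5
    Q <- matrix(1, n, 1, dimnames = list(rownames(g), NULL))
    ll <- admixture_loglik(A, B, Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, loglik = ll,
                          loglik_trace = ll, iterations = 0L,
                          converged = TRUE, seed = seed),
                     class = "admixture_fit"))
  }
  if (!is.null(seed)) set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    FM <- Q %*% P                            # n x L mixture frequency
    FM <- pmin(pmax(FM, eps), 1 - eps)
    T1 <- A / FM
    T2 <- B / (1 - FM)
    Qn <- Q * (T1 %*% t(P) + T2 %*% t(1 - P)) / (2 * pmax(Lw, 1))
    Qn <- Qn / rowSums(Qn)
    num <- P * (t(Q) %*% T1)
    den <- num + (1 - P) * (t(Q) %*% T2)
    Pn <- clip01(ifelse(den > 0, num / den, P), eps)
    Q <- Qn
    P <- Pn
    ll <- admixture_loglik(A, B, Q, P)
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  rownames(Q) <- rownames(g)
  structure(list(K = as.integer(K), Q = Q, P = P, loglik = trace[length(trace)],
                 loglik_trace = trace, iterations = length(trace),
                 converged = converged, seed = seed),
            class = "admixture_fit")
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

admixture_loglik <- function(A, B, Q, P) {
  FM <- Q %*% P
  eps <- 1e-12
  FM <- pmin(pmax(FM, eps), 1 - eps)
  sum(A * log(FM) + B * log(1 - FM))
}

#' Fit admixture replicates over a range of K
#'
#' @param gm a [genotype_matrix()].
#' @param k_range integer vector of K values (default 1:16).
#' @param n_replicates independent starts per K (default 6).
#' @param seed base seed; replicate r of K uses seed + 1000 * K + r.
#' @param ... passed to [fit_admixture()].
#' @return list with `fits` (list over K of replicate lists), `loglik`
#'   (K x replicate matrix, rownames = K).
#' @export
fit_admixture_series <- function(gm, k_range = 1:16, n_replicates = 6,
                                 seed = 1, ...) {
  fits <- lapply(k_range, function(K) {
    lapply(seq_len(n_replicates), function(r) {
      fit_admixture(gm, K, seed = seed + 1000L * K + r, ...)
    })
  })
  names(fits) <- as.character(k_range)
  ll <- t(vapply(fits, function(fk) {
    vapply(fk, function(f) f$loglik, numeric(1))
  }, numeric(n_replicates)))
  if (n_replicates == 1L) ll <- matrix(ll, ncol = 1,
                                       dimnames = list(as.character(k_range)))
  rownames(ll) <- as.character(k_range)
  list(fits = fits, loglik = ll)
}

#' Align admixture replicates across label switching
#'
#' Finds, for every replicate, the pool-column permutation minimising the
#' total absolute difference to the first replicate's Q: exhaustive search
#' over all K! permutations for K <= 8, otherwise an optimal
#' assignment-problem (Hungarian) match on the column-wise L1 cost.
#'
#' @param fits list of `admixture_fit` objects with equal K (>= 2
#'   replicates).
#' @return list with `permutations` (list of integer vectors; aligned column
#'   j of replicate r is original column `permutations[[r]][j]`),
#'   `consensus_q` (mean aligned Q, rows re-normalised), `aligned_q` (list)
#'   and `distance` (per replicate, L1 distance to the reference).
#' @export
align_replicates <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 replicates")
  Ks <- vapply(fits, function(f) f$K, integer(1))
  if (length(unique(Ks)) != 1L) stop("replicates have mixed K")
  K <- Ks[1]
  ref <- fits[[1]]$Q
  perms <- vector("list", length(fits))
  aligned <- vector("list", length(fits))
  dist <- numeric(length(fits))
  for (r in seq_along(fits)) {
    Qr <- fits[[r]]$Q
    # cost[j, k] = L1 distance between ref column j and replicate column k
    cost <- vapply(seq_len(K), function(k) {
      colSums(abs(ref - Qr[, k]))
    }, numeric(K))
    if (is.null(dim(cost))) cost <- matrix(cost, 1, 1)
    perm <- if (K <= 8L) best_permutation(cost) else hungarian(cost)
    perms[[r]] <- perm
    aligned[[r]] <- Qr[, perm, drop = FALSE]
    dist[r] <- sum(abs(ref - aligned[[r]]))
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  consensus <- consensus / rowSums(consensus)
  list(permutations = perms, consensus_q = consensus, aligned_q = aligned,
       distance = dist)
}

# exhaustive minimum-cost assignment (cost[j, k]: ref column j vs column k)
best_permutation <- function(cost) {
  K <- nrow(cost)
  perms <- permutations_of(K)
  costs <- vapply(perms, function(pp) {
    sum(cost[cbind(seq_len(K), pp)])
  }, numeric(1))
  perms[[which.min(costs)]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[s])
    }
  }
  out
}

# Hungarian algorithm (shortest augmenting path, O(n^3)); returns perm with
# perm[j] = column assigned to row j
hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)                        # p[j]: row assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) perm[p[j]] <- j - 1L
  perm
}

#' Evanno delta-K table from replicate log-likelihoods
#'
#' Second-order rate of change of the model log-likelihood across K,
#' normalised by the replicate spread: delta-K(K) =
#' mean|L(K+1) - 2 L(K) + L(K-1)| / sd(L(K)). The chosen K maximises
#' delta-K over interior K values.
#'
#' @param loglik matrix of log-likelihoods, rows = consecutive K values
#'   (rownames numeric), columns = replicates (>= 2).
#' @return list with `table` (K, mean_loglik, sd_loglik, abs_l2, delta_k)
#'   and `chosen_k`. A zero replicate sd yields an infinite delta-K with a
#'   warning.
#' @export
evanno_delta_k <- function(loglik) {
  if (nrow(loglik) < 3L) stop("need >= 3 consecutive K values")
  if (ncol(loglik) < 2L) stop("need >= 2 replicates")
  Ks <- as.numeric(rownames(loglik))
  if (any(diff(Ks) != 1)) stop("K values must be consecutive")
  mu <- rowMeans(loglik)
  sdv <- apply(loglik, 1, stats::sd)
  n <- nrow(loglik)
  abs_l2 <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    # |L''| averaged over replicates
    abs_l2[i] <- mean(abs(loglik[i + 1, ] - 2 * loglik[i, ] +
                            loglik[i - 1, ]))
  }
  dk <- abs_l2 / sdv
  if (any(is.infinite(dk), na.rm = TRUE)) {
    warning("zero replicate sd at some K; delta-K infinite there")
  }
  interior <- which(!is.na(abs_l2))
  chosen <- if (all(dk[interior] == 0)) {
    warning("delta-K has no peak (flat second differences)")
    NA_integer_
  } else {
    as.integer(Ks[interior[which.max(dk[interior])]])
  }
  list(table = data.frame(K = Ks, mean_loglik = mu, sd_loglik = sdv,
                          abs_l2 = abs_l2, delta_k = dk),
       chosen_k = chosen)
}

#' Threshold-based pool assignment
#'
#' @param Q row-stochastic membership matrix.
#' @param threshold membership needed to call an accession pure
#'   (default 0.8, inclusive).
#' @return data.frame (accession_id, pool, membership, label) where `pool`
#'   is the argmax pool and `label` is "pool<k>" or "admixed".
#' @export
assign_memberships <- function(Q, threshold = 0.8) {
  pool <- apply(Q, 1, which.max)
  memb <- Q[cbind(seq_len(nrow(Q)), pool)]
  data.frame(
    accession_id = rownames(Q),
    pool = pool,
    membership = memb,
    label = ifelse(memb >= threshold, paste0("pool", pool), "admixed"),
    stringsAsFactors = FALSE
  )
}

#' Mean pool membership per breeding-period group
#'
#' @param Q row-stochastic membership matrix with accession rownames.
#' @param meta an [accession_meta()] table.
#' @return matrix (groups x pools) of mean memberships; rows sum to 1.
#' @export
pool_proportions_by_group <- function(Q, meta) {
  groups <- period_split(meta)
  out <- t(vapply(groups, function(acc) {
    colMeans(Q[acc, , drop = FALSE])
  }, numeric(ncol(Q))))
  colnames(out) <- paste0("pool", seq_len(ncol(Q)))
  out
}
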