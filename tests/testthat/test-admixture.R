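# small simulated admixture panel drawn directly from the binomial model
admix_panel <- function(n_per_pool, L, K, divergence = 0.4, admixed = 0,
                        seed = 1) {
  set.seed(seed)
  p0 <- runif(L, 0.1, 0.9)
  shape <- (1 - divergence) / divergence
  P <- matrix(rbeta(K * L, rep(p0, each = K) * shape,
                    rep(1 - p0, each = K) * shape), K, L)
  Q <- do.call(rbind, lapply(seq_len(K), function(k) {
    q <- matrix(0, n_per_pool, K)
    q[, k] <- 1
    q
  }))
  if (admixed > 0) {
    mix <- matrix(rgamma(admixed * K, 1), admixed, K)
    Q <- rbind(Q, mix / rowSums(mix))
  }
  FM <- Q %*% P
  calls <- matrix(rbinom(length(FM), 2, FM), nrow(FM), ncol(FM))
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  colnames(calls) <- sprintf("M%04d", seq_len(L))
  list(gm = genotype_matrix(calls), Q = Q, P = P)
}

test_that("K = 1 reduces to panel allele frequencies in closed form", {
  tp <- toy_panel()
  fit <- fit_admixture(tp$genotypes, K = 1)
  p <- allele_freq(tp$genotypes)$p
  expect_equal(as.vector(fit$P), unname(p), tolerance = 1e-5)
  expect_equal(unname(fit$Q[, 1]), rep(1, 6))
  g <- unclass(tp$genotypes)
  ll <- sum(g * log(pmax(rep(p, each = 6), 1e-12)) +
              (2 - g) * log(pmax(1 - rep(p, each = 6), 1e-12)), na.rm = TRUE)
  expect_equal(fit$loglik, ll, tolerance = 1e-3)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  pan <- admix_panel(12, 150, 2, seed = 5)
  fit <- fit_admixture(pan$gm, K = 2, seed = 2, max_iter = 150)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_error(fit_admixture(pan$gm, K = 100), "exceeds")
})

test_that("two fixed divergent pools are recovered almost exactly", {
  pan <- admix_panel(15, 300, 2, divergence = 0.45, seed = 9)
  fit <- fit_admixture(pan$gm, K = 2, seed = 3, max_iter = 500)
  expect_lt(aligned_q_mae(fit$Q, pan$Q), 0.02)
})

test_that("admixed memberships are recovered with small error", {
  pan <- admix_panel(12, 500, 3, divergence = 0.3, admixed = 12, seed = 15)
  fits <- lapply(1:3, function(r) {
    fit_admixture(pan$gm, K = 3, seed = 10 + r, max_iter = 400)
  })
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  expect_lt(aligned_q_mae(best$Q, pan$Q), 0.05)
  # pool frequency recovery after the same alignment
  perm <- dartpool:::permutations_of(3)[[
    which.min(vapply(dartpool:::permutations_of(3), function(pp) {
      mean(abs(best$Q[, pp] - pan$Q))
    }, numeric(1)))]]
  expect_lt(sqrt(mean((best$P[perm, ] - pan$P)^2)), 0.08)
})

test_that("replicate alignment undoes label switching exactly", {
  pan <- admix_panel(10, 120, 3, seed = 21)
  fit <- fit_admixture(pan$gm, K = 3, seed = 4, max_iter = 200)
  swapped <- fit
  swapped$Q <- fit$Q[, c(3, 1, 2)]
  swapped$P <- fit$P[c(3, 1, 2), ]
  al <- align_replicates(list(fit, swapped))
  expect_equal(al$permutations[[2]], c(2L, 3L, 1L))
  expect_equal(al$distance[2], 0)
  expect_equal(unname(rowSums(al$consensus_q)), rep(1, nrow(fit$Q)))
})

test_that("Hungarian matching equals exhaustive search on random costs", {
  set.seed(33)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    cost <- matrix(runif(K * K), K, K)
    exh <- dartpool:::best_permutation(cost)
    hun <- dartpool:::hungarian(cost)
    expect_equal(sum(cost[cbind(1:K, hun)]), sum(cost[cbind(1:K, exh)]),
                 tolerance = 1e-12)
  }
})

test_that("Evanno delta-K reproduces hand arithmetic and flags flat traces", {
  mu <- c(-100, -50, -49, -48)
  d <- 1 / sqrt(2)
  ll <- cbind(mu - d, mu + d)                # per-K sd exactly 1
  rownames(ll) <- 1:4
  ev <- evanno_delta_k(ll)
  expect_equal(ev$table$sd_loglik, rep(1, 4))
  expect_equal(ev$table$delta_k[2], 49)
  expect_equal(ev$table$delta_k[3], 0)
  expect_equal(ev$chosen_k, 2L)

  lin <- cbind(c(-30, -20, -10), c(-31, -21, -11))
  rownames(lin) <- 1:3
  expect_warning(ev2 <- evanno_delta_k(lin), "no peak")
  expect_true(is.na(ev2$chosen_k))
})

test_that("delta-K selects the true number of pools on simulation", {
  pan <- admix_panel(12, 250, 3, divergence = 0.35, seed = 27)
  series <- fit_admixture_series(pan$gm, k_range = 1:5, n_replicates = 3,
                                 seed = 7, max_iter = 250)
  ev <- evanno_delta_k(series$loglik)
  expect_equal(ev$chosen_k, 3L)
})

test_that("membership assignment uses an inclusive 0.8 threshold", {
  Q <- rbind(a = c(0.85, 0.15), b = c(0.5, 0.5), c = c(0.8, 0.2))
  asg <- assign_memberships(Q)
  expect_equal(asg$label, c("pool1", "admixed", "pool1"))
  props <- pool_proportions_by_group(
    Q, accession_meta(data.frame(
      accession_id = rownames(Q), name = rownames(Q),
      period_group = c("g1", "g1", "g2"),
      passport_duplicate_group = NA, stringsAsFactors = FALSE)))
  expect_equal(unname(rowSums(props)), c(1, 1))
  expect_equal(props["g1", "pool1"], 0.675)
})
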