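#' Distance-based analysis of molecular variance
#'
#' Excoffier-style partition of squared distances into among- and
#' within-group sums of squares: SS_total = sum of squared pairwise
#' distances / N, SS_within the analogous per-group sums, SS_among the
#' difference. Variance components use the standard unequal-sample-size
#' coefficient n0 = (N - sum(n_g^2)/N) / (k - 1); a negative among-group
#' component is truncated at 0. Significance is assessed by permuting group
#' labels and recomputing Phi_ST, with p = (b + 1) / (m + 1).
#'
#' @param D symmetric distance matrix with accession dimnames.
#' @param groups factor/character of group labels (aligned with rows of `D`)
#'   or a named list of accession ids.
#' @param n_permutations number of label permutations (default 999; 0 skips
#'   the test).
#' @param seed RNG seed for the permutations.
#' @return list of class `amova_result`: `table` (source, df, SS, variance,
#'   pct), `phi_st`, `p_value`, `n_permutations`, `seed`.
#' @export
amova <- function(D, groups, n_permutations = 999, seed = NULL) {
  D <- as.matrix(D)
  if (is.list(groups)) {
    lab <- rep(names(groups), lengths(groups))
    ids <- unlist(groups, use.names = FALSE)
    groups <- factor(lab, levels = names(groups))[match(rownames(D), ids)]
  }
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(D))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group not allowed")
  obs <- amova_components(D, groups)
  p_value <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      phi <- amova_components(D, sample(groups))$phi_st
      if (phi >= obs$phi_st) hits <- hits + 1L
    }
    p_value <- (hits + 1) / (n_permutations + 1)
  }
  tab <- data.frame(
    source = c("among_groups", "within_groups", "total"),
    df = c(obs$df_a, obs$df_w, obs$df_a + obs$df_w),
    SS = c(obs$ss_a, obs$ss_w, obs$ss_a + obs$ss_w),
    variance = c(obs$sigma_a, obs$sigma_w, obs$sigma_a + obs$sigma_w),
    pct = c(obs$pct_a, obs$pct_w, 100),
    stringsAsFactors = FALSE
  )
  out <- list(table = tab, phi_st = obs$phi_st, p_value = p_value,
              n_permutations = n_permutations, seed = seed)
  class(out) <- "amova_result"
  out
}

amova_components <- function(D, groups) {
  n <- nrow(D)
  k <- nlevels(groups)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  sizes <- tabulate(groups, nbins = k)
  for (lev in seq_len(k)) {
    idx <- which(as.integer(groups) == lev)
    sub <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_a <- k - 1L
  df_w <- n - k
  sigma_w <- ss_within / df_w
  n0 <- (n - sum(sizes^2) / n) / df_a
  sigma_a <- max((ss_among / df_a - sigma_w) / n0, 0)
  tot <- sigma_a + sigma_w
  phi <- if (tot > 0) sigma_a / tot else 0
  list(ss_a = ss_among, ss_w = ss_within, df_a = df_a, df_w = df_w,
       sigma_a = sigma_a, sigma_w = sigma_w,
       pct_a = 100 * sigma_a / tot, pct_w = 100 * sigma_w / tot,
       phi_st = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (distance-based)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f, p = %s (%d permutations)\n", x$phi_st,
              format(x$p_value), x$n_permutations))
  invisible(x)
}
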