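#' Configuration for the synthetic DArTseq panel generator
#'
#' Defaults emulate a gene-bank survey of 83 pooled spring-barley cultivar
#' samples in five breeding-period groups genotyped at biallelic SNPs on
#' chromosomes 1H-7H plus unplaced loci, with 11 ancestral gene pools,
#' planted near-identical duplicates and localized allele-frequency sweeps.
#'
#' @param n_pools number of ancestral gene pools (default 11).
#' @param group_sizes accessions per breeding-period group (default
#'   13, 14, 18, 26, 12).
#' @param loci_per_chromosome named counts; default 200 on each of 1H-7H and
#'   50 unplaced ("Un").
#' @param pool_divergence Balding-Nichols drift parameter in (0, 1)
#'   controlling between-pool allele-frequency spread (default 0.15).
#' @param heterogeneity_by_group per-group probability that a cultivar's
#'   seed lot is mixed at a locus (default 0.10, 0.08, 0.06, 0.04, 0.02:
#'   internal heterogeneity decaying with breeding progress).
#' @param n_duplicate_pairs near-identical accession pairs to plant
#'   (default 2).
#' @param sweep_spec list of sweeps, each a list(chromosome, center_bp,
#'   width_bp, groups) driving the alternate allele to fixation in the given
#'   period groups (indices). Default: one sweep each on 5H and 3H affecting
#'   the two most recent groups.
#' @param seedlings_per_pool seedlings pooled per accession (default 8).
#' @param frac_fail_rep,frac_fail_callrate fractions of loci drawn with
#'   sub-threshold RepAvg / CallRate metadata (defaults 0.05 each).
#' @param missing_rate per-call missing probability (default 0.01).
#' @param rare_locus_frac fraction of loci drawn with ancestral frequency
#'   near 0 so some fail the MAF filter (default 0.03).
#' @param seed RNG seed (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pools = 11,
                       group_sizes = c(13, 14, 18, 26, 12),
                       loci_per_chromosome = NULL,
                       pool_divergence = 0.15,
                       heterogeneity_by_group = c(0.10, 0.08, 0.06,
                                                  0.04, 0.02),
                       n_duplicate_pairs = 2,
                       sweep_spec = NULL,
                       seedlings_per_pool = 8,
                       frac_fail_rep = 0.05,
                       frac_fail_callrate = 0.05,
                       missing_rate = 0.01,
                       rare_locus_frac = 0.03,
                       seed = 1) {
  if (is.null(loci_per_chromosome)) {
    loci_per_chromosome <- c(stats::setNames(rep(200L, 7), chromosome_names()),
                             Un = 50L)
  }
  if (is.null(sweep_spec)) {
    sweep_spec <- list(
      list(chromosome = "5H", center_bp = 120e6, width_bp = 40e6,
           groups = c(4L, 5L)),
      list(chromosome = "3H", center_bp = 250e6, width_bp = 30e6,
           groups = c(5L))
    )
  }
  stopifnot(all(group_sizes >= 1), seedlings_per_pool >= 1,
            pool_divergence > 0, pool_divergence < 1,
            length(heterogeneity_by_group) == length(group_sizes))
  for (sw in sweep_spec) {
    if (!sw$chromosome %in% names(loci_per_chromosome)) {
      stop("sweep on unsimulated chromosome: ", sw$chromosome)
    }
  }
  structure(list(n_pools = n_pools, group_sizes = group_sizes,
                 loci_per_chromosome = loci_per_chromosome,
                 pool_divergence = pool_divergence,
                 heterogeneity_by_group = heterogeneity_by_group,
                 n_duplicate_pairs = n_duplicate_pairs,
                 sweep_spec = sweep_spec,
                 seedlings_per_pool = seedlings_per_pool,
                 frac_fail_rep = frac_fail_rep,
                 frac_fail_callrate = frac_fail_callrate,
                 missing_rate = missing_rate,
                 rare_locus_frac = rare_locus_frac,
                 seed = seed),
            class = "sim_config")
}

#' Generate a synthetic DArTseq-style panel
#'
#' Generative model: each locus draws an ancestral frequency p0 ~ U(0.05,
#' 0.95) (a small fraction near 0 to exercise the MAF filter); pool
#' frequencies follow a Balding-Nichols beta around p0 with spread
#' `pool_divergence`; each accession draws pool memberships Q* from a
#' Dirichlet biased toward its period group's home pools; a cultivar's seed
#' lot is mixed at a locus with its group's heterogeneity probability, in
#' which case each pooled (fully inbred) seedling carries an independent
#' allele draw from the accession's mixture frequency and the pooled call is
#' heterozygous when the seedlings disagree; otherwise all seedlings share
#' one allele. Duplicates are copies of a source accession with 0.5% of
#' calls re-drawn from the same pooled-call model (the same lot re-assayed,
#' so a redraw differs only where the lot segregates); sweep loci
#' are fixed for the alternate allele in the affected groups; RepAvg /
#' CallRate metadata and missing calls are drawn so a configurable fraction
#' of loci fails each filter.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes`, `info`, `meta` and `truth` (pool
#'   frequencies `P`, memberships `q_star`, `duplicate_pairs`,
#'   `sweep_loci`, ancestral `p0`).
#' @export
generate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_groups <- length(cfg$group_sizes)
  n_acc <- sum(cfg$group_sizes)
  L <- sum(cfg$loci_per_chromosome)
  K <- cfg$n_pools

  chrom <- rep(names(cfg$loci_per_chromosome), cfg$loci_per_chromosome)
  pos <- draw_positions(cfg$loci_per_chromosome)
  locus_ids <- sprintf("L%05d", seq_len(L))

  # ancestral and pool allele frequencies
  p0 <- stats::runif(L, 0.05, 0.95)
  n_rare <- round(cfg$rare_locus_frac * L)
  if (n_rare > 0) {
    rare <- sample.int(L, n_rare)
    p0[rare] <- stats::runif(n_rare, 0.0005, 0.008)
  }
  FST <- cfg$pool_divergence
  shape <- (1 - FST) / FST
  P <- matrix(stats::rbeta(K * L, rep(p0, each = K) * shape,
                           rep(1 - p0, each = K) * shape), K, L)
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

  # period-biased memberships: each group is anchored on a sliding window of
  # "home" pools so consecutive periods share part of their gene pool
  home <- lapply(seq_len(n_groups), function(gidx) {
    start <- 1L + (gidx - 1L) * max(1L, (K - 2L) %/% max(n_groups - 1L, 1L))
    unique(pmin(seq(start, start + 2L), K))
  })
  group_of <- rep(seq_len(n_groups), cfg$group_sizes)
  alpha_base <- 0.05
  q_star <- t(vapply(seq_len(n_acc), function(i) {
    a <- rep(alpha_base, K)
    a[home[[group_of[i]]]] <- 2
    gam <- stats::rgamma(K, a)
    gam / sum(gam)
  }, numeric(K)))

  # pooled calls
  s <- cfg$seedlings_per_pool
  het_p <- cfg$heterogeneity_by_group[group_of]
  calls <- matrix(NA_integer_, n_acc, L)
  for (i in seq_len(n_acc)) {
    pi_l <- as.vector(q_star[i, ] %*% P)     # mixture allele frequency
    mixed <- stats::runif(L) < het_p[i]
    # uniform seed lot: one shared allele
    allele <- stats::rbinom(L, 1L, pi_l)
    call <- 2L * allele
    if (any(mixed) && s > 1L) {
      nm <- sum(mixed)
      alt_seedlings <- stats::rbinom(nm, s, pi_l[mixed])
      call[mixed] <- ifelse(alt_seedlings == 0L, 0L,
                            ifelse(alt_seedlings == s, 2L, 1L))
    }
    calls[i, ] <- call
  }

  meta <- data.frame(
    accession_id = sprintf("ACC%03d", seq_len(n_acc)),
    name = sprintf("Cultivar_%03d", seq_len(n_acc)),
    period_group = factor(breeding_periods()[group_of],
                          levels = breeding_periods()[seq_len(n_groups)]),
    passport_duplicate_group = NA_character_,
    stringsAsFactors = FALSE
  )

  # planted near-identical duplicates: later accession becomes a copy of an
  # earlier one from the same group with 0.5% of calls re-drawn
  dup_pairs <- list()
  if (cfg$n_duplicate_pairs > 0) {
    for (d in seq_len(cfg$n_duplicate_pairs)) {
      gidx <- 1L + (d - 1L) %% n_groups
      members <- which(group_of == gidx)
      src <- members[1L + 2L * (d - 1L) %/% n_groups]
      dst <- members[length(members) - (d - 1L) %/% n_groups]
      calls[dst, ] <- calls[src, ]
      q_star[dst, ] <- q_star[src, ]
      # re-draw 0.5% of calls from the same pooled-call model: the duplicate
      # is the same seed lot re-assayed, so a re-drawn call can only differ
      # where the lot segregates (never flips to the opposite homozygote)
      n_flip <- max(1L, round(0.005 * L))
      at <- sample.int(L, n_flip)
      pi_at <- as.vector(q_star[src, ] %*% P[, at, drop = FALSE])
      mixed <- stats::runif(n_flip) < cfg$heterogeneity_by_group[gidx]
      if (any(mixed) && s > 1L) {
        alt_seedlings <- stats::rbinom(sum(mixed), s, pi_at[mixed])
        calls[dst, at[mixed]] <- ifelse(alt_seedlings == 0L, 0L,
                                        ifelse(alt_seedlings == s, 2L, 1L))
      }
      meta$passport_duplicate_group[c(src, dst)] <- sprintf("dupgrp%d", d)
      dup_pairs[[d]] <- meta$accession_id[c(src, dst)]
    }
  }

  # sweeps: alternate allele fixed in affected groups
  sweep_loci <- character(0)
  for (sw in cfg$sweep_spec) {
    inx <- which(chrom == sw$chromosome &
                   !is.na(pos) &
                   abs(pos - sw$center_bp) <= sw$width_bp / 2)
    if (length(inx)) {
      affected <- which(group_of %in% sw$groups)
      calls[affected, inx] <- 2L
      sweep_loci <- c(sweep_loci, locus_ids[inx])
    }
  }

  # missingness and filter metadata
  drop <- matrix(stats::runif(n_acc * L) < cfg$missing_rate, n_acc, L)
  calls[drop] <- NA_integer_
  rep_avg <- stats::runif(L, 0.96, 1)
  fail_rep <- stats::runif(L) < cfg$frac_fail_rep
  rep_avg[fail_rep] <- stats::runif(sum(fail_rep), 0.80, 0.949)
  call_rate <- 1 - colMeans(is.na(calls))
  fail_cr <- stats::runif(L) < cfg$frac_fail_callrate
  if (any(fail_cr)) {
    for (l in which(fail_cr)) {
      extra <- sample.int(n_acc, ceiling(0.07 * n_acc))
      calls[extra, l] <- NA_integer_
    }
    call_rate <- 1 - colMeans(is.na(calls))
  }

  changes <- sample(snp_change_levels(), L, replace = TRUE,
                    prob = c(rep(1.5, 4), rep(0.5, 8)))
  info <- locus_info(data.frame(
    locus_id = locus_ids, chromosome = chrom, position_bp = pos,
    change = changes, rep_avg = rep_avg, call_rate = call_rate,
    stringsAsFactors = FALSE
  ))
  gm <- genotype_matrix(calls, accession_ids = meta$accession_id,
                        locus_ids = locus_ids)
  truth <- list(P = P, q_star = q_star, duplicate_pairs = dup_pairs,
                sweep_loci = sweep_loci, p0 = p0, group_of = group_of)
  list(genotypes = gm, info = info, meta = accession_meta(meta),
       truth = truth)
}

# positions denser toward chromosome ends (mixture of two edge betas);
# unplaced ("Un") loci carry no position
draw_positions <- function(loci_per_chromosome) {
  lens <- barley_chromosome_lengths() * 1e6
  unlist(lapply(names(loci_per_chromosome), function(ch) {
    n <- loci_per_chromosome[[ch]]
    if (ch == "Un") return(rep(NA_real_, n))
    u <- ifelse(stats::runif(n) < 0.5, stats::rbeta(n, 0.7, 3),
                stats::rbeta(n, 3, 0.7))
    sort(pmax(1, round(u * lens[[ch]])))
  }), use.names = FALSE)
}

#' Fixed 6-accession, 12-locus toy panel
#'
#' A hand-written panel with known per-locus statistics used throughout the
#' unit tests: locus L01 has calls (0, 0, 2, 2, 1, 1) (alt frequency 0.5,
#' Ho 1/3), accessions A5 and A6 are identical, and locus L12 is the only
#' heterozygote-free polymorphic column shared by all chromosome groups.
#'
#' @return list with `genotypes`, `info` and `meta`.
#' @export
toy_panel <- function() {
  calls <- rbind(
    #      L01 L02 L03 L04 L05 L06 L07 L08 L09 L10 L11 L12
    A1 = c(0L, 0L, 2L, 1L, 0L, 2L, 0L, 1L, 0L, 2L, NA, 0L),
    A2 = c(0L, 2L, 2L, 1L, 0L, 0L, 1L, 1L, 0L, 2L, 1L, 0L),
    A3 = c(2L, 0L, 2L, 0L, 1L, 0L, 2L, 1L, 0L, 0L, 1L, 2L),
    A4 = c(2L, 2L, 2L, 0L, 1L, 2L, 2L, 1L, 1L, 0L, 0L, 2L),
    A5 = c(1L, 0L, 2L, 2L, 0L, 1L, 0L, 1L, 0L, 1L, 2L, 0L),
    A6 = c(1L, 0L, 2L, 2L, 0L, 1L, 0L, 1L, 0L, 1L, 2L, 0L)
  )
  colnames(calls) <- sprintf("L%02d", 1:12)
  info <- locus_info(data.frame(
    locus_id = colnames(calls),
    chromosome = c("1H", "1H", "2H", "2H", "3H", "3H", "4H", "5H", "5H",
                   "6H", "7H", "Un"),
    position_bp = c(1e6, 5e7, 2e6, 3e8, 1e7, 2e8, 5e7, 1e6, 9e7, 4e7,
                    6e7, NA),
    change = c("A>G", "C>T", "G>A", "T>C", "A>C", "C>G", "G>T", "T>A",
               "A>T", "C>A", "T>G", "G>C"),
    rep_avg = rep(0.99, 12),
    call_rate = c(rep(1, 10), 5 / 6, 1),
    stringsAsFactors = FALSE
  ))
  meta <- accession_meta(data.frame(
    accession_id = rownames(calls),
    name = paste0("Toy", 1:6),
    period_group = factor(rep(breeding_periods()[c(1, 3, 5)], each = 2),
                          levels = breeding_periods()[c(1, 3, 5)]),
    passport_duplicate_group = c(NA, NA, NA, NA, "dupA", "dupA"),
    stringsAsFactors = FALSE
  ))
  list(genotypes = genotype_matrix(calls), info = info, meta = meta)
}
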