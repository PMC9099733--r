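#' Per-locus alternate-allele frequency
#'
#' @param gm a [genotype_matrix()].
#' @param accession_subset optional character vector of accession ids (or
#'   logical/integer row index); defaults to all accessions.
#' @return list with per-locus vectors `p` (alternate-allele frequency,
#'   `NA` where every call is missing), `n` (number of non-missing
#'   accessions) and `n_copies` (= 2n allele copies).
#' @export
allele_freq <- function(gm, accession_subset = NULL) {
  g <- subset_gm(gm, accession_subset)
  nonmiss <- colSums(!is.na(g))
  alt_copies <- colSums(g, na.rm = TRUE)     # dosage coding: het adds 1
  p <- ifelse(nonmiss > 0, alt_copies / (2 * nonmiss), NA_real_)
  list(p = p, n = nonmiss, n_copies = 2 * nonmiss)
}

subset_gm <- function(gm, accession_subset) {
  g <- unclass(gm)
  if (is.null(accession_subset)) return(g)
  g <- g[accession_subset, , drop = FALSE]
  if (nrow(g) == 0L) stop("empty accession subset")
  g
}

#' Polymorphism information content
#'
#' The diversity form PIC = 1 - p^2 - (1-p)^2 (= 2p(1-p) for a biallelic
#' locus, maximum 0.5), not Botstein's index.
#'
#' @param p alternate-allele frequency vector in \[0, 1\] (`NA` propagated).
#' @return per-locus PIC values.
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  1 - p^2 - (1 - p)^2
}

#' Per-locus observed heterozygosity
#'
#' For pooled samples of a selfing crop a heterozygous call reflects a
#' mixture of genotypes within the pool, so Ho measures cultivar
#' heterogeneity rather than individual heterozygosity.
#'
#' @inheritParams allele_freq
#' @return list with per-locus vector `ho` (share of non-missing calls equal
#'   to 1; `NA` for all-missing loci) and scalar `mean` (over defined loci).
#' @export
observed_het <- function(gm, accession_subset = NULL) {
  g <- subset_gm(gm, accession_subset)
  nonmiss <- colSums(!is.na(g))
  het <- colSums(g == 1L, na.rm = TRUE)
  ho <- ifelse(nonmiss > 0, het / nonmiss, NA_real_)
  list(ho = ho, mean = mean(ho, na.rm = TRUE))
}

#' Unbiased expected heterozygosity
#'
#' Nei's gene diversity with the small-sample correction 2n/(2n-1), n being
#' the number of (diploid-coded) samples with non-missing calls.
#'
#' @param p alternate-allele frequency.
#' @param n number of non-missing samples per locus.
#' @return per-locus uHe; `NA` where n < 1.
#' @export
unbiased_he <- function(p, n) {
  he <- 1 - p^2 - (1 - p)^2
  ifelse(n >= 1, 2 * n / (2 * n - 1) * he, NA_real_)
}

#' Fixation index
#'
#' F = (uHe - Ho) / uHe, the deficit of heterozygous calls relative to the
#' unbiased expectation; by convention F = 0 for a monomorphic locus
#' (uHe = 0). Accepts per-locus vectors or group means.
#'
#' @param ho observed heterozygosity (value or vector).
#' @param uhe unbiased expected heterozygosity (same length).
#' @return F values.
#' @export
fixation_index <- function(ho, uhe) {
  stopifnot(all(uhe >= 0, na.rm = TRUE))
  ifelse(!is.na(uhe) & uhe == 0, 0, (uhe - ho) / uhe)
}

#' Rarefied allelic richness
#'
#' Hurlbert rarefaction to a common sample of `g` allele copies:
#' AR = sum over alleles of 1 - C(N - N_a, g) / C(N, g), averaged over loci
#' per group. For biallelic loci AR lies in \[1, 2\].
#'
#' @param gm a [genotype_matrix()].
#' @param groups named list of accession-id vectors (or a factor over
#'   accessions).
#' @param g rarefaction size in allele copies; default 2 x smallest group
#'   size. Loci with fewer than `g` copies in a group are dropped from that
#'   group's mean.
#' @return named numeric vector of per-group mean AR.
#' @export
allelic_richness <- function(gm, groups, g = NULL) {
  groups <- as_group_list(gm, groups)
  if (is.null(g)) g <- 2L * min(lengths(groups))
  if (g < 2) stop("rarefaction size g must be >= 2")
  vapply(groups, function(acc) {
    f <- allele_freq(gm, acc)
    N <- f$n_copies
    Na <- round(f$p * N)                     # alt copies; ref = N - Na
    ok <- !is.na(f$p) & N >= g
    if (!any(ok)) return(NA_real_)
    ar <- rarefied_allele_count(N[ok], Na[ok], g)
    mean(ar)
  }, numeric(1))
}

# closed-form Hurlbert expected allele count for biallelic loci (vectorised)
rarefied_allele_count <- function(N, Na, g) {
  term <- function(copies) {
    # P(allele absent from a draw of g) = C(N - copies, g) / C(N, g)
    absent <- exp(lchoose(N - copies, g) - lchoose(N, g))
    absent[copies > N - g] <- 0              # cannot avoid the allele
    1 - absent
  }
  term(Na) + term(N - Na)
}

as_group_list <- function(gm, groups) {
  if (is.factor(groups) || is.character(groups)) {
    stopifnot(length(groups) == nrow(gm))
    groups <- split(rownames(gm), groups)
  }
  if (!length(groups) || any(lengths(groups) == 0L)) {
    stop("every group must be non-empty")
  }
  groups
}

#' Per-accession heterogeneity
#'
#' Fraction of an accession's non-missing calls that are heterozygous: the
#' internal (seed-lot) heterogeneity of a pooled cultivar sample.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame (accession_id, n_calls, ho) sorted by descending ho;
#'   accessions with no non-missing calls carry `NA` and a warning.
#' @export
cultivar_heterogeneity <- function(gm) {
  g <- unclass(gm)
  nonmiss <- rowSums(!is.na(g))
  if (any(nonmiss == 0L)) warning("accession(s) with all calls missing")
  ho <- ifelse(nonmiss > 0, rowSums(g == 1L, na.rm = TRUE) / nonmiss,
               NA_real_)
  out <- data.frame(accession_id = rownames(g), n_calls = nonmiss, ho = ho,
                    stringsAsFactors = FALSE)
  out[order(-out$ho, out$accession_id), , drop = FALSE]
}

# ---- SNP-type (transition/transversion) accounting ----------------------

snp_change_levels <- function() {
  c("A>G", "G>A", "C>T", "T>C",              # transitions
    "A>C", "A>T", "G>C", "G>T", "C>A", "C>G", "T>A", "T>G")
}

parse_snp_change <- function(change, locus_id = NULL) {
  ok <- change %in% snp_change_levels()
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    lab <- if (!is.null(locus_id)) locus_id[bad] else change[bad]
    stop("malformed SNP change at locus ", lab, ": '", change[bad], "'")
  }
  factor(change, levels = snp_change_levels())
}

#' Tabulate SNP substitution types
#'
#' Counts the 12 ordered base changes per chromosome and in total, with
#' transition/transversion percentages and the Ts/Tv ratio.
#'
#' @param info a [locus_info()] table.
#' @return list with `counts` (12 x chromosomes+Total integer matrix) and
#'   `stats` (from [snp_type_stats()]).
#' @export
snp_type_table <- function(info) {
  change <- parse_snp_change(info$change, info$locus_id)
  chrom <- factor(info$chromosome, levels = c(chromosome_names(), "Un"))
  counts <- table(change, chrom)
  counts <- cbind(Total = rowSums(counts), counts)
  list(counts = counts, stats = snp_type_stats(counts))
}

#' Transition/transversion statistics from substitution counts
#'
#' @param counts numeric matrix (or vector) of counts for the 12 ordered
#'   changes in the order of `snp_change_levels()` (A>G, G>A, C>T, T>C then
#'   the eight transversions); columns are chromosomes or totals.
#' @return data.frame with one row per column: n_loci, n_ts, n_tv, pct_ts,
#'   pct_tv, ts_tv_ratio.
#' @export
snp_type_stats <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                             dimnames = list(NULL, "Total"))
  stopifnot(nrow(counts) == 12L)
  ts <- colSums(counts[1:4, , drop = FALSE])
  tv <- colSums(counts[5:12, , drop = FALSE])
  tot <- ts + tv
  data.frame(
    scope = colnames(counts),
    n_loci = as.integer(tot),
    n_ts = as.integer(ts),
    n_tv = as.integer(tv),
    pct_ts = 100 * ts / tot,
    pct_tv = 100 * tv / tot,
    ts_tv_ratio = ts / tv,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Fraction of loci without heterozygous calls
#'
#' @param gm a [genotype_matrix()].
#' @param info optional [locus_info()] table; when given the fraction is also
#'   reported per chromosome.
#' @return data.frame (scope, n_loci, fraction_homozygous).
#' @export
homozygous_locus_fraction <- function(gm, info = NULL) {
  g <- unclass(gm)
  het_free <- colSums(g == 1L, na.rm = TRUE) == 0L
  out <- data.frame(scope = "overall", n_loci = ncol(g),
                    fraction_homozygous = mean(het_free),
                    stringsAsFactors = FALSE)
  if (!is.null(info)) {
    stopifnot(identical(colnames(gm), info$locus_id))
    chrom <- factor(info$chromosome, levels = c(chromosome_names(), "Un"))
    per <- tapply(het_free, chrom, mean)
    out <- rbind(out, data.frame(scope = names(per),
                                 n_loci = as.integer(table(chrom)),
                                 fraction_homozygous = as.numeric(per),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Diversity summaries by chromosome, period group and group x chromosome
#'
#' For each scope: mean PIC, mean Ho, mean uHe and F computed both from the
#' scope means (`f_from_means`) and as the mean of per-locus F
#' (`f_mean_locus`).
#'
#' @param gm a [genotype_matrix()].
#' @param info matching [locus_info()] table.
#' @param meta an [accession_meta()] table; `NULL` drops the group scopes.
#' @return tidy data.frame (scope, chromosome, group, n_loci, n_accessions,
#'   pic_mean, ho_mean, uhe_mean, f_from_means, f_mean_locus). Cells with no
#'   loci are reported with `NA` statistics.
#' @export
group_summaries <- function(gm, info, meta = NULL) {
  stopifnot(identical(colnames(gm), info$locus_id))
  chroms <- c(chromosome_names(), "Un")
  groups <- if (is.null(meta)) list() else period_split(meta)
  if (!is.null(meta) && !all(meta$accession_id %in% rownames(gm))) {
    stop("unknown accession id in metadata")
  }
  if (any(lengths(groups) == 0L)) stop("every period group must be non-empty")

  one <- function(acc, loci, scope, chromosome, group) {
    if (!length(loci)) {
      return(data.frame(scope = scope, chromosome = chromosome,
                        group = group, n_loci = 0L,
                        n_accessions = length(acc), pic_mean = NA_real_,
                        ho_mean = NA_real_, uhe_mean = NA_real_,
                        f_from_means = NA_real_, f_mean_locus = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sub <- genotype_matrix(unclass(gm)[acc, loci, drop = FALSE])
    f <- allele_freq(sub)
    ho <- observed_het(sub)$ho
    uhe <- unbiased_he(f$p, f$n)
    fl <- fixation_index(ho, uhe)
    data.frame(scope = scope, chromosome = chromosome, group = group,
               n_loci = length(loci), n_accessions = length(acc),
               pic_mean = mean(pic(f$p), na.rm = TRUE),
               ho_mean = mean(ho, na.rm = TRUE),
               uhe_mean = mean(uhe, na.rm = TRUE),
               f_from_means = fixation_index(mean(ho, na.rm = TRUE),
                                             mean(uhe, na.rm = TRUE)),
               f_mean_locus = mean(fl, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }

  all_acc <- rownames(gm)
  res <- list(one(all_acc, info$locus_id, "panel", NA, NA))
  for (ch in chroms) {
    res[[length(res) + 1L]] <-
      one(all_acc, info$locus_id[info$chromosome == ch], "chromosome", ch, NA)
  }
  for (gname in names(groups)) {
    res[[length(res) + 1L]] <-
      one(groups[[gname]], info$locus_id, "group", NA, gname)
    for (ch in chromosome_names()) {
      res[[length(res) + 1L]] <-
        one(groups[[gname]], info$locus_id[info$chromosome == ch],
            "group_x_chromosome", ch, gname)
    }
  }
  do.call(rbind, res)
}

#' Mean inter-locus spacing and genome-wide marker density
#'
#' @param n_loci named integer vector of locus counts per chromosome
#'   ("1H".."7H"; an "Un" entry is ignored for density).
#' @param lengths_mbp named numeric chromosome lengths in Mbp (default
#'   [barley_chromosome_lengths()]).
#' @return list with `per_chromosome` (chromosome, length_mbp, n_loci,
#'   mean_distance_mbp) and `density_kbp_per_locus` (genome-wide bp spacing,
#'   in Kbp, over chromosome-assigned loci).
#' @export
locus_spacing_summary <- function(n_loci,
                                  lengths_mbp = barley_chromosome_lengths()) {
  chroms <- names(lengths_mbp)
  n <- n_loci[chroms]
  per <- data.frame(chromosome = chroms,
                    length_mbp = as.numeric(lengths_mbp),
                    n_loci = as.integer(n),
                    mean_distance_mbp = as.numeric(lengths_mbp) / as.numeric(n),
                    stringsAsFactors = FALSE)
  list(per_chromosome = per,
       density_kbp_per_locus = 1000 * sum(lengths_mbp) / sum(n))
}
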