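#' Build a sliding-window skeleton along a chromosome
#'
#' Windows sample the chromosome rather than tile it: `n_positions` centers
#' are spread evenly from width/2 to length - width/2 and each window covers
#' the half-open interval \[center - width/2, center + width/2).
#'
#' @param chromosome_length_bp chromosome length in bp.
#' @param n_positions number of window centers (default 250).
#' @param width_bp window width in bp (default 500 kb).
#' @param chromosome optional chromosome label carried into the track.
#' @return data.frame of class `window_track` (chromosome, center_bp,
#'   half_width_bp, value, n_loci) with `value` `NA` and `n_loci` 0.
#' @export
make_windows <- function(chromosome_length_bp, n_positions = 250,
                         width_bp = 5e5, chromosome = NA_character_) {
  if (chromosome_length_bp <= width_bp) {
    stop("chromosome length must exceed window width")
  }
  centers <- seq(width_bp / 2, chromosome_length_bp - width_bp / 2,
                 length.out = n_positions)
  out <- data.frame(chromosome = chromosome, center_bp = centers,
                    half_width_bp = width_bp / 2, value = NA_real_,
                    n_loci = 0L, stringsAsFactors = FALSE)
  class(out) <- c("window_track", class(out))
  out
}

#' Reduce per-locus values into windows
#'
#' @param track a skeleton from [make_windows()].
#' @param positions locus positions (bp) on the track's chromosome.
#' @param values per-locus values (ignored for `reducer = "count"`).
#' @param reducer "mean" or "count".
#' @return the track with `value` and `n_loci` filled; empty windows keep
#'   `NA` values.
#' @export
window_reduce <- function(track, positions, values = NULL,
                          reducer = c("mean", "count")) {
  reducer <- match.arg(reducer)
  if (reducer == "mean") {
    if (is.null(values) || length(values) != length(positions)) {
      stop("values must match positions in length")
    }
  }
  lo <- track$center_bp - track$half_width_bp
  hi <- track$center_bp + track$half_width_bp
  for (w in seq_len(nrow(track))) {
    inw <- which(positions >= lo[w] & positions < hi[w])
    track$n_loci[w] <- length(inw)
    track$value[w] <- if (reducer == "count") {
      length(inw)
    } else if (length(inw)) {
      mean(values[inw], na.rm = TRUE)
    } else {
      NA_real_
    }
  }
  track
}

#' Per-locus Wright's FST between two groups
#'
#' Two-population Wright/Nei form: FST = (HT - mean(HS)) / HT with
#' HT = 2 p_bar (1 - p_bar), p_bar the unweighted mean of the two group
#' frequencies. FST is 0 where HT = 0 and is clipped to \[0, 1\].
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b accession-id vectors.
#' @return per-locus FST; `NA` where a group has no non-missing calls.
#' @export
fst_per_locus <- function(gm, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  pa <- allele_freq(gm, group_a)$p
  pb <- allele_freq(gm, group_b)$p
  pbar <- (pa + pb) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  pmin(pmax(fst, 0), 1)
}

#' Power transform of FST values
#'
#' Raising FST to a high power (default 10) suppresses background
#' differentiation and sharpens genome-scan plots.
#'
#' @param fst_values values in \[0, 1\].
#' @param power exponent (default 10).
#' @return transformed values.
#' @export
fst_transform <- function(fst_values, power = 10) {
  stopifnot(all(fst_values >= 0 & fst_values <= 1, na.rm = TRUE))
  fst_values^power
}

#' Unique-allele turnover between two breeding-period groups
#'
#' An allele (reference or alternate, per locus) is LOST when its frequency
#' is >= `threshold` in the earlier group and exactly 0 among the later
#' group's non-missing calls; GAINED is symmetric. Counts are aggregated by
#' chromosome ("Un" included).
#'
#' @param gm a [genotype_matrix()].
#' @param info matching [locus_info()] table.
#' @param group_earlier,group_later disjoint accession-id vectors.
#' @param threshold minimum frequency for a unique variant (default 0.25;
#'   0.05 for rare variants).
#' @return list with `by_chromosome` (chromosome, n_lost, n_gained,
#'   threshold), `lost_loci` and `gained_loci` (locus-id character vectors).
#' @export
unique_alleles <- function(gm, info, group_earlier, group_later,
                           threshold = 0.25) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (length(intersect(group_earlier, group_later))) {
    stop("groups must be disjoint")
  }
  if (!length(group_earlier) || !length(group_later)) stop("empty group")
  stopifnot(identical(colnames(gm), info$locus_id))
  pe <- allele_freq(gm, group_earlier)$p
  pl <- allele_freq(gm, group_later)$p
  lost_gained <- function(p_from, p_to) {
    # alt allele unique to "from", plus ref allele unique to "from"
    (p_from >= threshold & p_to == 0) |
      ((1 - p_from) >= threshold & p_to == 1)
  }
  lost <- lost_gained(pe, pl) & !is.na(pe) & !is.na(pl)
  gained <- lost_gained(pl, pe) & !is.na(pe) & !is.na(pl)
  chrom <- factor(info$chromosome, levels = c(chromosome_names(), "Un"))
  by_chrom <- data.frame(
    chromosome = levels(chrom),
    n_lost = as.integer(tapply(lost, chrom, sum, default = 0L)),
    n_gained = as.integer(tapply(gained, chrom, sum, default = 0L)),
    threshold = threshold,
    stringsAsFactors = FALSE
  )
  list(by_chromosome = by_chrom,
       lost_loci = info$locus_id[which(lost)],
       gained_loci = info$locus_id[which(gained)])
}

#' Unique-allele turnover across consecutive period groups
#'
#' @param gm a [genotype_matrix()].
#' @param info matching [locus_info()] table.
#' @param meta an [accession_meta()] table (period levels in chronological
#'   order).
#' @param threshold passed to [unique_alleles()].
#' @return data.frame with one row per chromosome x consecutive period pair.
#' @export
unique_allele_timeline <- function(gm, info, meta, threshold = 0.25) {
  groups <- period_split(meta)
  out <- list()
  for (i in seq_len(length(groups) - 1L)) {
    ua <- unique_alleles(gm, info, groups[[i]], groups[[i + 1L]], threshold)
    tab <- ua$by_chromosome
    tab$period_pair <- paste(names(groups)[i], "vs", names(groups)[i + 1L])
    out[[i]] <- tab
  }
  do.call(rbind, out)
}

#' Genome-scan bundle contrasting two period groups
#'
#' Builds, per chromosome, windowed tracks of FST^power between the two
#' groups, mean PIC within each group, and counts of loci carrying alleles
#' unique to each group.
#'
#' @param gm a [genotype_matrix()].
#' @param info matching [locus_info()] table.
#' @param group_a,group_b accession-id vectors (e.g. earliest and latest
#'   breeding periods).
#' @param lengths_mbp chromosome lengths in Mbp (default
#'   [barley_chromosome_lengths()]).
#' @param n_positions,width_bp window geometry (defaults 250 and 500 kb).
#' @param power FST transform exponent (default 10).
#' @param unique_threshold threshold for [unique_alleles()] (default 0.25).
#' @return named list of data.frames `fst_pow`, `pic_a`, `pic_b`,
#'   `unique_a`, `unique_b`, each a stacked [make_windows()] track over all
#'   placed chromosomes.
#' @export
selection_scan_report <- function(gm, info, group_a, group_b,
                                  lengths_mbp = barley_chromosome_lengths(),
                                  n_positions = 250, width_bp = 5e5,
                                  power = 10, unique_threshold = 0.25) {
  stopifnot(identical(colnames(gm), info$locus_id))
  fst <- fst_transform(fst_per_locus(gm, group_a, group_b), power)
  pic_a <- pic(allele_freq(gm, group_a)$p)
  pic_b <- pic(allele_freq(gm, group_b)$p)
  ua <- unique_alleles(gm, info, group_a, group_b, unique_threshold)
  uniq_a <- as.numeric(info$locus_id %in% ua$lost_loci)
  uniq_b <- as.numeric(info$locus_id %in% ua$gained_loci)

  stack_track <- function(values, reducer = "mean") {
    parts <- lapply(names(lengths_mbp), function(ch) {
      onch <- info$chromosome == ch
      if (!any(onch)) return(NULL)
      tr <- make_windows(lengths_mbp[[ch]] * 1e6, n_positions, width_bp,
                         chromosome = ch)
      window_reduce(tr, info$position_bp[onch], values[onch], reducer)
    })
    do.call(rbind, parts)
  }
  sum_track <- function(values) {
    tr <- stack_track(values, "mean")
    tr$value <- ifelse(tr$n_loci > 0, tr$value * tr$n_loci, NA_real_)
    tr
  }
  list(fst_pow = stack_track(fst),
       pic_a = stack_track(pic_a),
       pic_b = stack_track(pic_b),
       unique_a = sum_track(uniq_a),
       unique_b = sum_track(uniq_b))
}

#' Export a window track as BedGraph
#'
#' @param track a stacked window track.
#' @param path output path.
#' @return `path`, invisibly. Intervals are 0-based half-open; windows with
#'   no loci are skipped.
#' @export
write_bedgraph <- function(track, path) {
  keep <- !is.na(track$value)
  df <- data.frame(
    chrom = track$chromosome[keep],
    start = as.integer(pmax(track$center_bp[keep] -
                              track$half_width_bp[keep], 0)),
    end = as.integer(track$center_bp[keep] + track$half_width_bp[keep]),
    value = signif(track$value[keep], 12)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
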