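#' Read a two-row DArTseq SNP report
#'
#' Parses the codominant two-row dialect in which every locus occupies two
#' consecutive rows of 0/1 presence scores: the first row scores the
#' reference allele, the second the alternate allele. The pair collapses to a
#' single dosage call per accession: (1,0) -> 0, (0,1) -> 2, (1,1) -> 1
#' (both alleles in the pool), (0,0) -> missing.
#'
#' Expected columns: `locus_id`, `chromosome`, `position_bp`, `change`,
#' `rep_avg`, `call_rate`, then one 0/1 column per accession.
#'
#' @param path CSV file path.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `info` (a [locus_info()] table), loci in file order.
#' @export
read_dartseq_tworow <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta_cols <- c("locus_id", "chromosome", "position_bp", "change",
                 "rep_avg", "call_rate")
  miss <- setdiff(meta_cols, names(raw))
  if (length(miss)) stop("malformed DArTseq file, missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(raw) %% 2L != 0L) {
    stop("malformed DArTseq file: odd number of locus rows")
  }
  acc <- setdiff(names(raw), meta_cols)
  if (!length(acc)) stop("no accession columns found")
  ref_rows <- seq(1L, nrow(raw), by = 2L)
  alt_rows <- ref_rows + 1L
  ids <- raw$locus_id[ref_rows]
  if (any(ids != raw$locus_id[alt_rows])) {
    stop("malformed DArTseq file: row pair with mismatched locus ids")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate locus id: ", ids[duplicated(ids)][1L])
  }
  ref <- as.matrix(raw[ref_rows, acc, drop = FALSE])
  alt <- as.matrix(raw[alt_rows, acc, drop = FALSE])
  if (!all(ref %in% c(0, 1)) || !all(alt %in% c(0, 1))) {
    stop("malformed DArTseq file: presence scores must be 0 or 1")
  }
  # (ref, alt) presence -> dosage; (0,0) is a failed call
  calls <- ref * 0L + alt * 2L
  calls[ref == 1 & alt == 1] <- 1L
  calls[ref == 0 & alt == 0] <- NA_integer_
  gm <- genotype_matrix(t(calls), accession_ids = acc, locus_ids = ids)
  info <- locus_info(data.frame(
    locus_id = ids,
    chromosome = raw$chromosome[ref_rows],
    position_bp = as.numeric(raw$position_bp[ref_rows]),
    change = raw$change[ref_rows],
    rep_avg = as.numeric(raw$rep_avg[ref_rows]),
    call_rate = as.numeric(raw$call_rate[ref_rows]),
    stringsAsFactors = FALSE
  ))
  list(genotypes = gm, info = info)
}

#' Write a genotype panel in the two-row DArTseq dialect
#'
#' Inverse of [read_dartseq_tworow()]; used by the synthetic generator so the
#' whole pipeline can be exercised from file.
#'
#' @param gm a [genotype_matrix()].
#' @param info matching [locus_info()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dartseq_tworow <- function(gm, info, path) {
  stopifnot(identical(colnames(gm), info$locus_id))
  calls <- t(unclass(gm))                     # loci x accessions
  ref <- ifelse(is.na(calls), 0L, as.integer(calls <= 1L))
  alt <- ifelse(is.na(calls), 0L, as.integer(calls >= 1L))
  n <- nrow(info)
  idx <- rep(seq_len(n), each = 2L)
  out <- data.frame(
    locus_id = info$locus_id[idx],
    chromosome = info$chromosome[idx],
    position_bp = info$position_bp[idx],
    change = info$change[idx],
    rep_avg = info$rep_avg[idx],
    call_rate = info$call_rate[idx],
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  scores <- matrix(0L, nrow = 2L * n, ncol = ncol(calls))
  scores[seq(1L, 2L * n, by = 2L), ] <- ref
  scores[seq(2L, 2L * n, by = 2L), ] <- alt
  colnames(scores) <- colnames(calls)
  out <- cbind(out, as.data.frame(scores, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-filter loci
#'
#' Removes loci in a single pass in the order reproducibility, call rate,
#' minor allele frequency; each removed locus is attributed to the first
#' criterion it fails. Thresholds are inclusive on the kept side: a locus is
#' removed when its value is strictly below the minimum, so boundary values
#' (e.g. MAF exactly 0.01) are kept. MAF is computed on non-missing calls
#' across all accessions, a heterozygote contributing one copy of each
#' allele.
#'
#' @param gm a [genotype_matrix()].
#' @param info matching [locus_info()] table.
#' @param cfg list from [filter_config()].
#' @return list with `genotypes`, `info` (filtered, original order) and
#'   `report` (a `filter_report` data.frame; see Details).
#' @details The report has one row per criterion (`input`, `removed_rep_avg`,
#'   `removed_call_rate`, `removed_maf`, `kept`) and an attribute
#'   `kept_by_chromosome` with per-chromosome kept counts.
#' @export
filter_loci <- function(gm, info, cfg = filter_config()) {
  stopifnot(identical(colnames(gm), info$locus_id))
  n_input <- ncol(gm)
  fail_rep <- info$rep_avg < cfg$min_rep_avg
  fail_cr <- !fail_rep & info$call_rate < cfg$min_call_rate
  p <- allele_freq(gm)$p
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0                       # all-missing locus: uninformative
  fail_maf <- !fail_rep & !fail_cr & maf < cfg$min_maf
  keep <- !(fail_rep | fail_cr | fail_maf)
  if (!any(keep)) warning("all loci removed by filtering; empty panel")
  gm2 <- genotype_matrix(unclass(gm)[, keep, drop = FALSE],
                         accession_ids = rownames(gm),
                         locus_ids = colnames(gm)[keep])
  info2 <- info[keep, , drop = FALSE]
  rownames(info2) <- NULL
  report <- data.frame(
    criterion = c("input", "removed_rep_avg", "removed_call_rate",
                  "removed_maf", "kept"),
    n_loci = c(n_input, sum(fail_rep), sum(fail_cr), sum(fail_maf),
               sum(keep)),
    stringsAsFactors = FALSE
  )
  attr(report, "kept_by_chromosome") <-
    table(factor(info2$chromosome, levels = c(chromosome_names(), "Un")))
  class(report) <- c("filter_report", class(report))
  list(genotypes = gm2, info = info2, report = report)
}

#' Locus filter configuration
#'
#' @param min_rep_avg minimum reproducibility kept (default 0.95).
#' @param min_call_rate minimum call rate kept (default 0.95).
#' @param min_maf minimum minor allele frequency kept (default 0.01).
#' @return list of validated thresholds.
#' @export
filter_config <- function(min_rep_avg = 0.95, min_call_rate = 0.95,
                          min_maf = 0.01) {
  v <- c(min_rep_avg, min_call_rate, min_maf)
  if (any(v < 0 | v > 1)) stop("filter thresholds must lie in [0, 1]")
  list(min_rep_avg = min_rep_avg, min_call_rate = min_call_rate,
       min_maf = min_maf)
}

#' Write a result table as CSV or JSON
#'
#' @param obj a data.frame (or coercible) pipeline result.
#' @param path output path.
#' @param format "csv" (default) or "json".
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(obj)
  if (format == "csv") {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = 12, na = "null")
  }
  invisible(path)
}
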