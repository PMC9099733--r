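#' Construct a genotype matrix
#'
#' The internal genotype container is an integer matrix with accessions in
#' rows and loci in columns. Calls are coded as alternate-allele dosage of the
#' pooled sample: 0 (reference homozygote), 1 (heterozygous, i.e. both alleles
#' present in the pool), 2 (alternate homozygote), `NA` (missing).
#'
#' @param calls integer matrix (accessions x loci) with values in
#'   \{0, 1, 2, NA\}.
#' @param accession_ids character vector of unique accession identifiers
#'   (defaults to existing rownames).
#' @param locus_ids character vector of unique locus identifiers (defaults to
#'   existing colnames).
#' @return An integer matrix of class `genotype_matrix` with dimnames set.
#' @export
genotype_matrix <- function(calls, accession_ids = rownames(calls),
                            locus_ids = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(accession_ids) || is.null(locus_ids)) {
    stop("accession and locus identifiers are required")
  }
  accession_ids <- as.character(accession_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(accession_ids)) stop("duplicate accession ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  if (length(accession_ids) != nrow(calls) ||
      length(locus_ids) != ncol(calls)) {
    stop("dimnames do not match call matrix dimensions")
  }
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(accession_ids, locus_ids)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Validate a locus information table
#'
#' @param info data.frame with columns `locus_id`, `chromosome` (one of
#'   "1H".."7H" or "Un"), `position_bp` (1-based, `NA` iff chromosome is
#'   "Un"), `change` (ordered base pair such as "A>G"), `rep_avg` and
#'   `call_rate` (fractions in \[0, 1\]).
#' @return The validated data.frame with chromosome normalised ("", NA and
#'   "unknown" map to "Un").
#' @export
locus_info <- function(info) {
  req <- c("locus_id", "chromosome", "position_bp", "change",
           "rep_avg", "call_rate")
  miss <- setdiff(req, names(info))
  if (length(miss)) stop("locus_info missing columns: ",
                         paste(miss, collapse = ", "))
  info$locus_id <- as.character(info$locus_id)
  if (anyDuplicated(info$locus_id)) stop("duplicate locus ids in locus_info")
  info$chromosome <- normalize_chromosome(info$chromosome)
  bad <- !(info$chromosome %in% c(chromosome_names(), "Un"))
  if (any(bad)) {
    stop("unknown chromosome label: ",
         paste(unique(info$chromosome[bad]), collapse = ", "))
  }
  un <- info$chromosome == "Un"
  info$position_bp[un] <- NA_real_
  if (any(!un & is.na(info$position_bp))) {
    stop("position_bp missing for chromosome-assigned loci")
  }
  if (any(info$position_bp < 1, na.rm = TRUE)) stop("position_bp must be >= 1")
  chk01 <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0 | x > 1)) {
      stop(nm, " must lie in [0, 1]")
    }
  }
  chk01(info$rep_avg, "rep_avg")
  chk01(info$call_rate, "call_rate")
  parse_snp_change(info$change, info$locus_id)  # errors on malformed strings
  info
}

normalize_chromosome <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | tolower(x) %in% c("un", "unknown", "na")] <- "Un"
  x
}

#' Chromosome names of the barley nuclear genome
#' @return Character vector "1H".."7H".
#' @export
chromosome_names <- function() paste0(1:7, "H")

#' Barley chromosome lengths (Morex reference assembly)
#'
#' Named numeric vector of chromosome lengths in Mbp used for window geometry
#' and the synthetic-panel generator.
#' @return Named numeric vector over "1H".."7H".
#' @export
barley_chromosome_lengths <- function() {
  c(`1H` = 558.54, `2H` = 768.08, `3H` = 699.71, `4H` = 647.06,
    `5H` = 670.03, `6H` = 583.38, `7H` = 657.22)
}

#' Validate an accession metadata table
#'
#' @param meta data.frame with columns `accession_id`, `name`,
#'   `period_group` (breeding-period label, 5 levels in chronological order
#'   when a factor), and `passport_duplicate_group` (shared id for accessions
#'   whose passports flag them as duplicates; `NA` otherwise).
#' @return The validated data.frame; `period_group` is made a factor keeping
#'   its existing level order.
#' @export
accession_meta <- function(meta) {
  req <- c("accession_id", "name", "period_group", "passport_duplicate_group")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("accession_meta missing columns: ",
                         paste(miss, collapse = ", "))
  meta$accession_id <- as.character(meta$accession_id)
  if (anyDuplicated(meta$accession_id)) stop("duplicate accession ids")
  if (!is.factor(meta$period_group)) {
    meta$period_group <- factor(meta$period_group,
                                levels = unique(meta$period_group))
  }
  meta
}

#' Default breeding-period labels
#' @return Character vector of the five breeding-period group labels.
#' @export
breeding_periods <- function() {
  c("before 1945", "1945-1969", "1970-1989", "1990-1999", "after 2000")
}

# split accession ids by period group, in level order
period_split <- function(meta) {
  split(meta$accession_id, meta$period_group, drop = FALSE)
}
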