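#' Allele-class coverage of an accession subset
#'
#' Allele classes are (locus, allele) pairs observed in the panel, a
#' heterozygous call carrying both alleles. Coverage is the fraction of the
#' panel's classes present in the subset.
#'
#' @param gm a [genotype_matrix()].
#' @param subset character vector of accession ids (may be empty).
#' @return fraction in \[0, 1\]; 1 iff every class is covered.
#' @export
coverage <- function(gm, subset) {
  bits <- allele_class_bits(gm)
  panel <- colSums(bits) > 0
  if (!length(subset)) return(0)
  sub <- colSums(bits[subset, , drop = FALSE]) > 0
  sum(sub & panel) / sum(panel)
}

# accessions x (2 * loci) logical matrix of allele-class presence
allele_class_bits <- function(gm) {
  g <- unclass(gm)
  ref <- !is.na(g) & g <= 1L
  alt <- !is.na(g) & g >= 1L
  bits <- cbind(ref, alt)
  colnames(bits) <- c(paste0(colnames(g), ":ref"), paste0(colnames(g), ":alt"))
  bits
}

#' Extract a minimal core collection (M-strategy)
#'
#' Finds a smallest accession subset covering every observed allele class.
#' Search is best-first (A*-style) over partial selections with priority
#' g + h, where g is the number of accessions chosen and h the admissible
#' bound ceiling(uncovered classes / largest per-accession class count); a
#' greedy seed solution prunes the frontier. When the frontier exceeds
#' `max_nodes` the search degrades to the greedy solution and records the
#' mode. Ties are broken by lexicographic accession id.
#'
#' @param gm a [genotype_matrix()].
#' @param max_nodes frontier-expansion budget for the exact search
#'   (default 20000).
#' @return list of class `core_set`: `selected` (accession ids in selection
#'   order), `coverage` (always 1 on success), `mode` ("exact" or
#'   "greedy"), `n_classes`.
#' @export
extract_core <- function(gm, max_nodes = 20000) {
  bits <- allele_class_bits(gm)
  bits <- bits[, colSums(bits) > 0, drop = FALSE]     # realised classes only
  acc <- sort(rownames(bits))
  bits <- bits[acc, , drop = FALSE]
  n <- length(acc)
  n_classes <- ncol(bits)

  greedy <- greedy_cover(bits)
  if (n == 1L || length(greedy) <= 1L) {
    return(core_result(acc[greedy], gm, "exact", n_classes))
  }

  # forced picks: classes carried by a single accession
  carriers <- colSums(bits)
  forced <- sort(unique(unlist(apply(bits[, carriers == 1L, drop = FALSE],
                                     2, which))))
  base_sel <- forced
  base_cov <- if (length(base_sel)) {
    colSums(bits[base_sel, , drop = FALSE]) > 0
  } else {
    rep(FALSE, n_classes)
  }

  best_size <- length(greedy)
  best_sel <- greedy
  max_gain <- max(rowSums(bits))
  # frontier nodes: list(sel = indices, cov = logical, next_i = candidate ptr)
  h0 <- ceiling(sum(!base_cov) / max_gain)
  frontier <- list(list(sel = base_sel, cov = base_cov))
  prio <- length(base_sel) + h0
  expanded <- 0L
  mode <- "exact"
  while (length(frontier)) {
    at <- which.min(prio)
    node <- frontier[[at]]
    frontier[[at]] <- NULL
    prio <- prio[-at]
    expanded <- expanded + 1L
    if (expanded > max_nodes || length(frontier) > max_nodes) {
      mode <- "greedy"
      best_sel <- greedy
      break
    }
    uncovered <- sum(!node$cov)
    if (uncovered == 0L) {
      best_sel <- node$sel
      break                                   # best-first: first goal optimal
    }
    if (length(node$sel) + ceiling(uncovered / max_gain) >= best_size) next
    # branch on accessions that add something, highest gain first
    gains <- rowSums(bits[, !node$cov, drop = FALSE])
    gains[node$sel] <- 0L
    cands <- which(gains > 0L)
    cands <- cands[order(-gains[cands], acc[cands])]
    for (ci in cands) {
      sel2 <- c(node$sel, ci)
      cov2 <- node$cov | bits[ci, ]
      h <- ceiling(sum(!cov2) / max_gain)
      if (length(sel2) + h >= best_size) next
      frontier[[length(frontier) + 1L]] <- list(sel = sel2, cov = cov2)
      prio <- c(prio, length(sel2) + h)
    }
  }
  core_result(acc[sort(best_sel)], gm, mode, n_classes)
}

greedy_cover <- function(bits) {
  n <- nrow(bits)
  covered <- rep(FALSE, ncol(bits))
  sel <- integer(0)
  while (any(!covered)) {
    gains <- rowSums(bits[, !covered, drop = FALSE])
    gains[sel] <- -1L
    top <- which(gains == max(gains))
    pick <- top[order(rownames(bits)[top])][1L]
    sel <- c(sel, pick)
    covered <- covered | bits[pick, ]
  }
  sel
}

core_result <- function(selected, gm, mode, n_classes) {
  structure(list(selected = selected,
                 coverage = coverage(gm, selected),
                 mode = mode, n_classes = n_classes),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d accessions, coverage %.3f (%s search, %d classes)\n",
              length(x$selected), x$coverage, x$mode, x$n_classes))
  invisible(x)
}
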