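#' popANI / conANI strain-identity comparison of two pileups
#'
#' Positions covered at \code{min_cov} or more in both samples are
#' compared. At each compared position a sample's detected allele set is
#' the bases with count >= \code{allele_min_count} and frequency >=
#' \code{allele_min_freq}. A \emph{popANI substitution} is a position where
#' the two allele sets are disjoint (the samples share no detected
#' allele); a \emph{conANI substitution} is a position where the consensus
#' bases differ (consensus = max count, ties broken A<C<G<T). Then
#' \deqn{popANI = 100 (1 - popANI\ subs / compared)} and likewise for
#' conANI. Because shared minor alleles rescue a position from being a
#' popANI substitution, popANI >= conANI always; popANI is the statistic
#' robust to residual ancient-DNA damage, and popANI > 99.999 is the
#' working definition of "identical strains" while values <= 99.99
#' indicate shared but non-identical strains.
#'
#' @param pileupA,pileupB \code{calc_pileup} objects on the same reference.
#' @param min_cov minimum depth in both samples for a position to be
#'   compared (default 5).
#' @param allele_min_freq minimum within-sample frequency for allele
#'   detection (default 0.05).
#' @param allele_min_count minimum count for allele detection (default 2).
#' @return a \code{popani_comparison}: list with \code{compared_positions},
#'   \code{popani_substitutions}, \code{conani_substitutions},
#'   \code{popANI}, \code{conANI} (percent; NA with \code{reason} when no
#'   positions are compared), \code{coverage_overlap}.
#' @export
compare_popani <- function(pileupA, pileupB, min_cov = 5,
                           allele_min_freq = 0.05, allele_min_count = 2) {
  stopifnot(inherits(pileupA, "calc_pileup"), inherits(pileupB, "calc_pileup"))
  ## same coordinate system: identical length; ids may differ for
  ## coordinate-compatible synthetic genome pairs
  if (nrow(pileupA$counts) != nrow(pileupB$counts))
    stop("pileups must be on the same reference coordinates")
  ca <- pileupA$counts; cb <- pileupB$counts
  da <- rowSums(ca); db <- rowSums(cb)
  cmp <- da >= min_cov & db >= min_cov
  covered_either <- da >= min_cov | db >= min_cov
  compared <- sum(cmp)
  if (compared == 0)
    return(structure(list(compared_positions = 0L,
                          popani_substitutions = NA_integer_,
                          conani_substitutions = NA_integer_,
                          popANI = NA_real_, conANI = NA_real_,
                          coverage_overlap = 0,
                          reason = "no jointly covered positions"),
                     class = "popani_comparison"))
  ia <- ca[cmp, , drop = FALSE]; ib <- cb[cmp, , drop = FALSE]
  dia <- da[cmp]; dib <- db[cmp]
  allowA <- ia >= allele_min_count & ia / dia >= allele_min_freq
  allowB <- ib >= allele_min_count & ib / dib >= allele_min_freq
  shared <- rowSums(allowA & allowB)
  pop_sub <- sum(shared == 0)
  consA <- max.col(ia, ties.method = "first")
  consB <- max.col(ib, ties.method = "first")
  con_sub <- sum(consA != consB)
  structure(list(compared_positions = compared,
                 popani_substitutions = pop_sub,
                 conani_substitutions = con_sub,
                 popANI = 100 * (1 - pop_sub / compared),
                 conANI = 100 * (1 - con_sub / compared),
                 coverage_overlap = compared / sum(covered_either),
                 reason = NA_character_),
            class = "popani_comparison")
}

#' @export
print.popani_comparison <- function(x, ...) {
  if (is.na(x$popANI)) {
    cat("popANI comparison undefined:", x$reason, "\n")
  } else {
    cat(sprintf(
      "compared %d positions: popANI %.5f%% (%d subs), conANI %.5f%% (%d subs), overlap %.3f\n",
      x$compared_positions, x$popANI, x$popani_substitutions,
      x$conANI, x$conani_substitutions, x$coverage_overlap))
  }
  invisible(x)
}

#' Mask-length x minimum-insert calibration sweep
#'
#' Re-runs the masking, pileup and popANI comparison of two read sets over
#' a grid of mask lengths and minimum insert sizes, reporting popANI, mean
#' depth and compared positions per cell. The selected cell codifies
#' "maximum popANI with minimal loss of coverage": among cells whose
#' popANI is within \code{tol} percentage points of the grid maximum, the
#' smallest mask and then the smallest insert is chosen. The grid defaults
#' include the untreated-library mask candidates (9/11/13/15, plus 0 and
#' the UDG-half value 1) and insert cutoffs 12/24/36/48.
#'
#' @param alnA,alnB alignments of the two samples (same reference).
#' @param mask_grid mask lengths to evaluate.
#' @param insert_grid minimum insert sizes to evaluate.
#' @param min_cov minimum compared-position depth (default 5).
#' @param min_base_quality phred threshold for pileup bases.
#' @param tol popANI tolerance (percentage points) for the selection rule.
#' @return a \code{calibration_result}: list with \code{grid} (data.frame:
#'   mask, min_insert, popANI, conANI, mean_depth, compared) and
#'   \code{selected} (row of the chosen cell).
#' @export
calibration_sweep <- function(alnA, alnB,
                              mask_grid = c(0, 1, 9, 11, 13, 15),
                              insert_grid = c(12, 24, 36, 48),
                              min_cov = 5, min_base_quality = 30,
                              tol = 1e-4) {
  if (!length(mask_grid) || !length(insert_grid)) stop("empty grid")
  cells <- expand.grid(mask = sort(mask_grid),
                       min_insert = sort(insert_grid))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- cells$mask[i]; ins <- cells$min_insert[i]
    pa <- build_pileup(mask_reads(alnA, m), min_base_quality = min_base_quality,
                       min_insert = ins)
    pb <- build_pileup(mask_reads(alnB, m), min_base_quality = min_base_quality,
                       min_insert = ins)
    cmp <- compare_popani(pa, pb, min_cov = min_cov)
    data.frame(mask = m, min_insert = ins, popANI = cmp$popANI,
               conANI = cmp$conANI,
               mean_depth = (mean(pileup_depth(pa)) +
                             mean(pileup_depth(pb))) / 2,
               compared = cmp$compared_positions)
  })
  grid <- do.call(rbind, rows)
  defined <- !is.na(grid$popANI)
  if (!any(defined)) stop("popANI undefined on every grid cell")
  best <- max(grid$popANI[defined])
  cand <- grid[defined & grid$popANI >= best - tol, ]
  sel <- cand[order(cand$mask, cand$min_insert), ][1, ]
  structure(list(grid = grid, selected = sel), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration sweep over", nrow(x$grid), "cells; selected mask",
      x$selected$mask, "insert", x$selected$min_insert, "\n")
  print(x$grid)
  invisible(x)
}
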