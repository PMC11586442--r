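#' Mask read ends against terminal deamination
#'
#' Flags the first and last N aligned bases of every read as
#' non-contributing. Reads are not shortened and coordinates are
#' unchanged; masked bases are simply ignored when pileups are built, so a
#' read whose aligned length is <= 2N contributes nothing. Mask lengths of
#' 1 (UDG-half libraries) and 11 (untreated libraries) are the calibrated
#' protocol values; see \code{\link{calibration_sweep}}.
#'
#' @param aln a \code{calc_alignments} data.frame.
#' @param mask_length single non-negative mask length, or a named vector
#'   keyed by UDG class (\code{none}, \code{half}, \code{non_udg}) applied
#'   via \code{udg_class}.
#' @param udg_class UDG class of this read set (used when
#'   \code{mask_length} is a named map).
#' @return the alignments with the \code{mask} column set.
#' @export
mask_reads <- function(aln, mask_length, udg_class = NULL) {
  if (!is.null(names(mask_length))) {
    if (is.null(udg_class) || !udg_class %in% names(mask_length))
      stop("udg_class must name an entry of mask_length")
    mask_length <- mask_length[[udg_class]]
  }
  mask_length <- as.integer(mask_length)
  if (mask_length < 0) stop("negative mask length")
  aln$mask <- mask_length
  aln
}

#' Build a base-count pileup from alignments
#'
#' Per-position A/C/G/T counts after all read-level filters: pairs whose
#' template length is below \code{min_insert} are excluded entirely, bases
#' under the read-end mask or below the base-quality threshold contribute
#' nothing, and where the two mates of a pair overlap, each position is
#' counted once (the higher-quality base wins; ties keep the first mate),
#' so short-insert pairs do not double-count their fully overlapping
#' bases.
#'
#' @param aln a \code{calc_alignments} data.frame (see
#'   \code{\link{simulate_reads}} / \code{\link{read_sam}}).
#' @param ref_len reference length; defaults to the alignments' attribute.
#' @param min_base_quality minimum phred base quality (default 30).
#' @param min_insert minimum template length in bases (default 12).
#' @return a \code{calc_pileup}: list with \code{ref}, \code{counts}
#'   (ref_len x 4 integer matrix, columns A/C/G/T).
#' @export
build_pileup <- function(aln, ref_len = attr(aln, "ref_len"),
                         min_base_quality = 30, min_insert = 12) {
  if (is.null(ref_len)) stop("ref_len required")
  ref_id <- attr(aln, "ref_id") %||% "chr1"
  counts <- matrix(0L, ref_len, 4, dimnames = list(NULL, BASES))
  keep_read <- abs(aln$tlen) >= min_insert
  a <- aln[keep_read, , drop = FALSE]
  if (nrow(a)) {
    if (any(a$start < 1 | a$start + a$len - 1L > ref_len))
      stop("alignment outside reference bounds")
    ridx <- rep.int(seq_len(nrow(a)), a$len)
    dL <- sequence(a$len) - 1L
    dR <- a$len[ridx] - 1L - dL
    pos <- a$start[ridx] + dL
    base <- unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE)
    qual <- utf8ToInt(paste(a$qual, collapse = "")) - 33L
    msk <- a$mask[ridx]
    ok <- dL >= msk & dR >= msk & qual >= min_base_quality & base %in% BASES
    pos <- pos[ok]; base <- base[ok]; qual <- qual[ok]
    qid <- a$qid[ridx][ok]
    ## one observation per (pair, position): mate-overlap deduplication
    key <- as.numeric(qid) * (ref_len + 1) + pos
    ord <- order(key, -qual)
    dup <- duplicated(key[ord])
    pos <- pos[ord][!dup]; base <- base[ord][!dup]
    for (b in BASES)
      counts[, b] <- tabulate(pos[base == b], nbins = ref_len)
  }
  structure(list(ref = ref_id, counts = counts), class = "calc_pileup")
}

#' @export
print.calc_pileup <- function(x, ...) {
  d <- rowSums(x$counts)
  cat(sprintf("pileup on '%s': %d positions, mean depth %.2f, breadth %.1f%%\n",
              x$ref, nrow(x$counts), mean(d), 100 * mean(d > 0)))
  invisible(x)
}

#' Per-position depth of a pileup
#' @param pileup a \code{calc_pileup}.
#' @return integer vector of depths.
#' @export
pileup_depth <- function(pileup) rowSums(pileup$counts)
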