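#' Cumulative percent decay curve of oral-taxon content
#'
#' For one sample, taxa with nonzero abundance are ranked by decreasing
#' abundance (ties broken lexicographically by taxon id, for determinism)
#' and the curve value at rank k is the percentage of the top-k taxa that
#' belong to the oral reference set:
#' \deqn{curve(k) = 100 \cdot |\{oral\ taxa\ among\ top\ k\}| / k.}
#' Percentages are over taxon counts (presence among the top k), not
#' abundance mass. Well-preserved oral metagenomes keep this curve high;
#' contaminated samples decay towards 0.
#'
#' @param sample_row named numeric vector of taxon abundances for one
#'   sample (names are taxon ids); must contain at least one nonzero
#'   entry and no negative entries.
#' @param oral_reference character vector of oral taxon ids (ids absent
#'   from the sample are permitted and ignored).
#' @return a \code{decay_curve}: list with \code{values} (percentages by
#'   rank), \code{taxa} (taxa in rank order), \code{is_oral}.
#' @examples
#' x <- c(a = 10, b = 8, c = 6, d = 4)
#' decay_curve(x, c("a", "c"))$values  # 100, 50, 66.7, 50
#' @export
decay_curve <- function(sample_row, oral_reference) {
  if (any(sample_row < 0)) stop("negative abundances")
  nz <- sample_row[sample_row > 0]
  if (!length(nz)) stop("all-zero sample row")
  ord <- order(-nz, names(nz), method = "radix")
  taxa <- names(nz)[ord]
  is_oral <- taxa %in% oral_reference
  values <- 100 * cumsum(is_oral) / seq_along(is_oral)
  structure(list(values = values, taxa = taxa, is_oral = is_oral),
            class = "decay_curve")
}

#' Classify sample preservation from a decay curve
#'
#' A sample passes when its decay curve stays at or above the cutoff at
#' every rank from the burn-in rank onward. The \code{"adaptive"} burn-in
#' discards the unstable head of the curve: the burn-in rank is the
#' smallest rank r such that every subsequent rank-to-rank change of the
#' curve is at most \code{burn_in_tol} percentage points. A fixed-rank
#' burn-in may be given instead as an integer. The adaptive rule is this
#' package's deterministic approximation of the cited adaptive-burn-in
#' idea (whose exact criterion is not published); see the methods
#' vignette for the rationale and for how the choice affects
#' classifications.
#'
#' @param curve a \code{\link{decay_curve}}.
#' @param cutoff_percent pass threshold in \[0, 100\] (default 50).
#' @param burn_in \code{"adaptive"} or a fixed integer rank.
#' @param burn_in_tol stability tolerance in percentage points for the
#'   adaptive rule (default 10).
#' @return logical \code{passed}, with attribute \code{burn_in_rank}.
#' @export
classify_preservation <- function(curve, cutoff_percent = 50,
                                  burn_in = "adaptive", burn_in_tol = 10) {
  stopifnot(inherits(curve, "decay_curve"))
  if (cutoff_percent < 0 || cutoff_percent > 100)
    stop("cutoff must be in [0, 100]")
  v <- curve$values
  K <- length(v)
  if (identical(burn_in, "adaptive")) {
    r <- 1L
    if (K > 1) {
      d <- abs(diff(v))
      unstable <- which(d > burn_in_tol)
      r <- if (length(unstable)) min(max(unstable) + 1L, K) else 1L
    }
  } else {
    r <- min(max(as.integer(burn_in), 1L), K)
  }
  passed <- all(v[r:K] >= cutoff_percent)
  structure(passed, burn_in_rank = r)
}

#' Preservation screen over a whole taxon table
#'
#' @param tab a \code{taxon_table} (see \code{\link{make_taxon_table}} /
#'   \code{\link{read_taxon_table}}).
#' @inheritParams classify_preservation
#' @return data.frame: sample, passed, burn_in_rank, n_taxa.
#' @export
preservation_screen <- function(tab, cutoff_percent = 50,
                                burn_in = "adaptive", burn_in_tol = 10) {
  stopifnot(inherits(tab, "taxon_table"))
  res <- lapply(rownames(tab$counts), function(s) {
    cu <- decay_curve(tab$counts[s, ], tab$oral)
    cl <- classify_preservation(cu, cutoff_percent, burn_in, burn_in_tol)
    data.frame(sample = s, passed = as.logical(cl),
               burn_in_rank = attr(cl, "burn_in_rank"),
               n_taxa = length(cu$values))
  })
  do.call(rbind, res)
}
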