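#' FAVA: FST-based assessment of variability across abundance vectors
#'
#' Treating each sample's relative-abundance vector as an allele-frequency
#' vector, FAVA is the FST-style normalized variance
#' \deqn{FAVA = (H_T - \bar H_S) / H_T}
#' where \eqn{H_T = 1 - \sum_j \bar p_j^2} is the Gini-Simpson
#' heterozygosity of the across-sample mean vector \eqn{\bar p} and
#' \eqn{\bar H_S} is the mean within-sample Gini-Simpson heterozygosity
#' \eqn{H_S(i) = 1 - \sum_j p_{ij}^2}. FAVA is 0 when all samples have
#' identical composition and 1 when every sample is concentrated on a
#' single, sample-specific taxon. This is the unweighted form (uniform
#' sample weights, uniform taxon treatment).
#'
#' Rows are closed to relative abundances internally (division by row
#' sums), so raw counts are accepted. The statistic is undefined -- returned
#' with an explicit reason, not an error -- for fewer than two samples
#' (e.g. an island represented by a single specimen) or when \eqn{H_T = 0}.
#'
#' @param abundance_matrix numeric matrix, samples in rows, taxa in
#'   columns; non-negative, rows with positive sums.
#' @param group optional label stored on the result.
#' @return a \code{fava_result}: list with \code{group}, \code{n_samples},
#'   \code{H_T}, \code{H_S_bar}, \code{value} (NA when undefined) and
#'   \code{reason} (\code{"n<2"}, \code{"H_T=0"}, or NA).
#' @examples
#' fava(rbind(c(1, 0), c(0, 1)))$value        # 1
#' fava(rbind(c(1, 0), c(0.5, 0.5)))$value    # 1/3
#' @export
fava <- function(abundance_matrix, group = NA_character_) {
  m <- as.matrix(abundance_matrix)
  if (any(m < 0)) stop("negative abundances")
  n <- nrow(m)
  if (n < 1) stop("empty matrix")
  rs <- rowSums(m)
  if (any(rs == 0)) stop("zero-sum abundance row")
  p <- m / rs
  if (n < 2)
    return(new_fava(group, n, NA_real_, NA_real_, NA_real_, "n<2"))
  pbar <- colMeans(p)
  H_T <- 1 - sum(pbar^2)
  H_S_bar <- mean(1 - rowSums(p^2))
  if (H_T == 0)
    return(new_fava(group, n, H_T, H_S_bar, NA_real_, "H_T=0"))
  new_fava(group, n, H_T, H_S_bar, (H_T - H_S_bar) / H_T, NA_character_)
}

new_fava <- function(group, n, H_T, H_S_bar, value, reason) {
  structure(list(group = group, n_samples = n, H_T = H_T,
                 H_S_bar = H_S_bar, value = value, reason = reason),
            class = "fava_result")
}

#' @export
print.fava_result <- function(x, ...) {
  cat(sprintf("FAVA[%s] n=%d: %s\n", x$group, x$n_samples,
              if (is.na(x$value)) paste0("undefined (", x$reason, ")")
              else format(x$value)))
  invisible(x)
}

#' FAVA per group plus the pooled all-samples value
#'
#' Mirrors the per-island-and-overall usage: one FAVA per group, plus the
#' statistic over all samples together (singleton groups come back
#' undefined with reason \code{"n<2"}, the others are still computed).
#'
#' @param abundance_matrix samples x taxa matrix with rownames.
#' @param grouping factor/character of group labels, one per sample.
#' @return list with \code{groups} (list of \code{fava_result}) and
#'   \code{pooled} (a \code{fava_result} over all samples).
#' @export
fava_by_group <- function(abundance_matrix, grouping) {
  m <- as.matrix(abundance_matrix)
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(m))
    stop("grouping must assign exactly one group per sample")
  if (any(is.na(grouping) | !nzchar(grouping))) stop("empty group label")
  res <- lapply(unique(grouping), function(g)
    fava(m[grouping == g, , drop = FALSE], group = g))
  names(res) <- unique(grouping)
  list(groups = res, pooled = fava(m, group = "all"))
}

#' Tabulate FAVA results
#' @param x output of \code{\link{fava_by_group}}.
#' @return data.frame with group, n, H_T, H_S_bar, value, reason.
#' @export
fava_table <- function(x) {
  rows <- c(x$groups, list(x$pooled))
  do.call(rbind, lapply(rows, function(r)
    data.frame(group = r$group, n = r$n_samples, H_T = r$H_T,
               H_S_bar = r$H_S_bar, value = r$value, reason = r$reason)))
}
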