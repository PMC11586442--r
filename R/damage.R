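#' Terminal deamination damage profile
#'
#' Post-mortem cytosine deamination is read out as C>T substitutions at the
#' 5' ends of sequenced fragments and, for double-stranded libraries, as the
#' mirrored G>A substitutions at 3' ends. The per-position substitution rate
#' is modelled as geometric decay from the read terminus:
#' \deqn{rate(i) = d_0 \cdot decay^i \quad (i < extent), \qquad rate(i) = 0
#' \quad (i \ge extent)}
#' with \code{i} the 0-based distance from the read end. This two-parameter
#' shape captures the high-at-termini, ~10 bp decay pattern that read-end
#' masking is calibrated against; it is a deliberate simplification of
#' empirical per-library damage profiles.
#'
#' Default profiles bracket typical published ancient-DNA damage:
#' \describe{
#'   \item{\code{non_udg}}{d0 = 0.30, decay = 0.70, extent = 15 (untreated
#'     libraries, heavy terminal damage).}
#'   \item{\code{half}}{d0 = 0.05, decay = 0.50, extent = 2 (partial-UDG
#'     libraries, damage confined to the terminal one or two bases).}
#'   \item{\code{none}}{d0 = 0 (modern DNA / fully repaired).}
#' }
#'
#' @param udg_class one of \code{"none"}, \code{"half"}, \code{"non_udg"};
#'   selects the default parameterisation.
#' @param d0 probability of C>T at the 5'-terminal base, in \[0, 1\].
#' @param decay multiplicative per-base decay factor in (0, 1\].
#' @param extent maximum 0-based distance from the read end with a nonzero
#'   rate.
#' @return an object of class \code{damage_profile}.
#' @examples
#' p <- damage_profile("non_udg")
#' damage_rate(p, 0:5)
#' @export
damage_profile <- function(udg_class = c("none", "half", "non_udg"),
                           d0 = NULL, decay = NULL, extent = NULL) {
  udg_class <- match.arg(udg_class)
  defaults <- list(
    none    = list(d0 = 0.00, decay = 0.70, extent = 0L),
    half    = list(d0 = 0.05, decay = 0.50, extent = 2L),
    non_udg = list(d0 = 0.30, decay = 0.70, extent = 15L)
  )[[udg_class]]
  d0 <- d0 %||% defaults$d0
  decay <- decay %||% defaults$decay
  extent <- as.integer(extent %||% defaults$extent)
  if (d0 < 0 || d0 > 1) stop("d0 must be in [0, 1]")
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  if (extent < 0) stop("extent must be >= 0")
  structure(list(d0 = d0, decay = decay, extent = extent,
                 udg_class = udg_class),
            class = "damage_profile")
}

#' Damage rate at given distances from a read end
#'
#' @param profile a \code{\link{damage_profile}}.
#' @param i vector of 0-based distances from the read terminus.
#' @return numeric vector of substitution probabilities.
#' @export
damage_rate <- function(profile, i) {
  stopifnot(inherits(profile, "damage_profile"))
  r <- profile$d0 * profile$decay^i
  r[i >= profile$extent] <- 0
  r
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("damage profile [%s]: d0=%.3g decay=%.3g extent=%d\n",
              x$udg_class, x$d0, x$decay, x$extent))
  invisible(x)
}
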