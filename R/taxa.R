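#' Simulate a sample-by-taxon abundance table with controlled oral content
#'
#' Each sample's counts are drawn by a Dirichlet-multinomial-style scheme:
#' within-group taxon proportions are Dirichlet (via normalized gammas),
#' the oral/contaminant mass split is fixed at the requested expected oral
#' fraction, and a multinomial draw of \code{total_reads} produces counts.
#' This emulates the structure of a species-level abundance table from a
#' burial-environment-exposed oral metagenome: a pool of genuinely oral
#' taxa diluted by contaminant taxa.
#'
#' @param n_samples number of samples (>= 1).
#' @param n_taxa total number of taxa; the first \code{n_oral} form the
#'   oral reference set.
#' @param oral_fraction expected fraction of each sample's reads coming
#'   from oral taxa; scalar or one value per sample, in \[0, 1\].
#' @param seed RNG seed.
#' @param n_oral size of the oral reference set (default: half the taxa).
#' @param total_reads reads per sample.
#' @param concentration Dirichlet concentration per taxon; smaller values
#'   give spikier communities.
#' @return a \code{taxon_table}: list with \code{counts} (samples x taxa
#'   integer matrix), \code{oral} (character vector of oral taxon ids).
#' @export
make_taxon_table <- function(n_samples, n_taxa = 50, oral_fraction = 0.8,
                             seed, n_oral = NULL, total_reads = 100000,
                             concentration = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (any(oral_fraction < 0 | oral_fraction > 1))
    stop("oral_fraction must be in [0, 1]")
  n_oral <- n_oral %||% (n_taxa %/% 2)
  stopifnot(n_oral >= 1, n_oral < n_taxa)
  fr <- rep_len(oral_fraction, n_samples)
  taxa <- c(sprintf("oral_taxon_%03d", seq_len(n_oral)),
            sprintf("env_taxon_%03d", seq_len(n_taxa - n_oral)))
  counts <- with_seed(seed, {
    m <- matrix(0L, n_samples, n_taxa, dimnames = list(
      sprintf("sample_%03d", seq_len(n_samples)), taxa))
    for (i in seq_len(n_samples)) {
      p_oral <- rdirichlet1(n_oral, concentration)
      p_env <- rdirichlet1(n_taxa - n_oral, concentration)
      p <- c(p_oral * fr[i], p_env * (1 - fr[i]))
      m[i, ] <- stats::rmultinom(1, total_reads, p)[, 1]
    }
    m
  })
  structure(list(counts = counts, oral = taxa[seq_len(n_oral)]),
            class = "taxon_table")
}

## One Dirichlet(k, alpha) draw via normalized gammas.
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon table: %d samples x %d taxa (%d oral)\n",
              nrow(x$counts), ncol(x$counts), length(x$oral)))
  invisible(x)
}

#' Write / read a taxon table as TSV (+ one-taxon-per-line oral list)
#' @param tab a \code{taxon_table}.
#' @param path TSV path for the counts (samples in rows).
#' @param oral_path optional path for the oral reference list.
#' @export
write_taxon_table <- function(tab, path, oral_path = NULL) {
  stopifnot(inherits(tab, "taxon_table"))
  df <- data.frame(sample = rownames(tab$counts), tab$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(oral_path)) writeLines(tab$oral, oral_path)
  invisible(path)
}

#' @rdname write_taxon_table
#' @export
read_taxon_table <- function(path, oral_path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  oral <- readLines(oral_path)
  oral <- oral[nzchar(oral)]
  structure(list(counts = m, oral = oral), class = "taxon_table")
}
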