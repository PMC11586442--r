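#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed) || !is.numeric(seed))
    stop("a numeric seed is required", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

## Complement lookup over A/C/G/T (and N -> N).
comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

## md5 of a deparsed R object, for config provenance headers.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Write a TSV with a provenance comment header
#'
#' Prepends a comment line carrying the package version, a hash of the
#' configuration object and the seed, so every output table records how
#' it was produced.
#' @param df data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param config optional configuration object hashed into the header.
#' @export
write_tsv_provenance <- function(df, path, seed = NA, config = NULL) {
  hdr <- sprintf("# calcstrain %s; config_hash=%s; seed=%s",
                 as.character(utils::packageVersion("calcstrain")),
                 if (is.null(config)) "none" else object_hash(config),
                 as.character(seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
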