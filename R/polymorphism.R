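#' Classify coding sites as monomorphic / polymorphic with codon effects
#'
#' polymut-style site classification over protein-coding genes. A site
#' with depth below \code{min_cov} is unevaluated; otherwise the dominant
#' allele is the max-count base and the site is \emph{polymorphic} iff the
#' dominant frequency is below \code{dominant_freq} (default 0.8). For a
#' polymorphic site the effect is determined by substituting the secondary
#' (second-most-frequent) allele into the codon formed from the dominant
#' alleles at the other two codon positions and translating with the
#' standard genetic code. When two sites of one codon are both
#' polymorphic, each is classified holding the other at its dominant
#' allele. Reverse-strand genes are handled by complementing pileup counts
#' into coding orientation. Base quality is expected to have been applied
#' when the pileup was built.
#'
#' @param pileup a \code{calc_pileup} (quality-filtered).
#' @param genes data.frame with \code{gene_id}, \code{start}, \code{end}
#'   (1-based inclusive, length divisible by 3), \code{strand}.
#' @param min_cov minimum depth to evaluate a site (default 5).
#' @param dominant_freq dominant-frequency threshold below which a site is
#'   polymorphic (default 0.8).
#' @return data.frame with one row per coding position: \code{pos},
#'   \code{gene_id}, \code{codon_index}, \code{codon_pos},
#'   \code{dominant}, \code{dom_freq}, \code{secondary}, \code{state}
#'   (monomorphic/polymorphic/unevaluated), \code{effect} (synonymous/
#'   nonsynonymous/not-applicable).
#' @export
classify_sites <- function(pileup, genes, min_cov = 5, dominant_freq = 0.8) {
  stopifnot(inherits(pileup, "calc_pileup"))
  if (!nrow(genes)) stop("no genes supplied")
  glen <- genes$end - genes$start + 1L
  if (any(glen %% 3 != 0)) stop("gene interval not divisible by 3")
  if (any(genes$start < 1 | genes$end > nrow(pileup$counts)))
    stop("gene outside reference bounds")
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    p <- genes$start[i]:genes$end[i]
    off <- if (genes$strand[i] == "-") genes$end[i] - p else p - genes$start[i]
    data.frame(pos = p, gene_id = genes$gene_id[i],
               codon_index = off %/% 3L + 1L, codon_pos = off %% 3L + 1L,
               minus = genes$strand[i] == "-", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per_gene)
  cnt <- pileup$counts[df$pos, , drop = FALSE]
  ## complement counts into coding orientation for minus-strand genes
  if (any(df$minus))
    cnt[df$minus, ] <- cnt[df$minus, c("T", "G", "C", "A"), drop = FALSE]
  depth <- rowSums(cnt)
  dom_i <- max.col(cnt, ties.method = "first")
  dom_cnt <- cnt[cbind(seq_len(nrow(cnt)), dom_i)]
  cnt2 <- cnt
  cnt2[cbind(seq_len(nrow(cnt)), dom_i)] <- -1L
  sec_i <- max.col(cnt2, ties.method = "first")
  sec_cnt <- cnt2[cbind(seq_len(nrow(cnt2)), sec_i)]
  df$dominant <- ifelse(depth > 0, BASES[dom_i], NA_character_)
  df$dom_freq <- ifelse(depth > 0, dom_cnt / depth, NA_real_)
  df$secondary <- ifelse(sec_cnt > 0, BASES[sec_i], NA_character_)
  df$state <- ifelse(depth < min_cov, "unevaluated",
                     ifelse(df$dom_freq < dominant_freq,
                            "polymorphic", "monomorphic"))
  ## codon backgrounds from dominant alleles
  codon_key <- paste(df$gene_id, df$codon_index)
  codon_id <- match(codon_key, unique(codon_key))
  codon_chars <- matrix(NA_character_, 3L, max(codon_id))
  codon_chars[cbind(df$codon_pos, codon_id)] <- df$dominant
  codons <- apply(codon_chars, 2, paste, collapse = "")
  df$effect <- "not-applicable"
  poly <- which(df$state == "polymorphic" & !is.na(df$secondary))
  if (length(poly)) {
    cod <- codons[codon_id[poly]]
    ok <- !grepl("NA", cod, fixed = TRUE)
    idx <- poly[ok]
    cod <- cod[ok]
    alt <- cod
    substr(alt, df$codon_pos[idx], df$codon_pos[idx]) <- df$secondary[idx]
    aa_ref <- translate_codon(cod)
    aa_alt <- translate_codon(alt)
    df$effect[idx] <- ifelse(aa_ref == aa_alt, "synonymous",
                             "nonsynonymous")
  }
  df$minus <- NULL
  df
}

## standard-code translation of codon strings
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Polymorphic-rate dN/dS over protein-coding genes
#'
#' Aggregates \code{\link{classify_sites}}: the ratio of nonsynonymous to
#' synonymous polymorphic coding sites, a count ratio (not normalized by
#' synonymous/nonsynonymous site opportunity), used as an ad-hoc flag for
#' samples containing multiple strains -- mixtures of diverged strains
#' inflate the polymorphic rate, and the N/S spectrum of those
#' polymorphisms resembles between-strain divergence rather than
#' within-strain noise.
#'
#' @inheritParams classify_sites
#' @return a \code{dnds_result}: list with \code{n_nonsynonymous},
#'   \code{n_synonymous}, \code{n_considered} (coding sites at or above
#'   \code{min_cov}), \code{polymorphic_rate}, \code{ratio} (NA with
#'   \code{reason} when no synonymous polymorphic sites exist).
#' @export
dnds <- function(pileup, genes, min_cov = 5, dominant_freq = 0.8) {
  cls <- classify_sites(pileup, genes, min_cov, dominant_freq)
  poly <- cls$state == "polymorphic"
  nn <- sum(poly & cls$effect == "nonsynonymous")
  ns <- sum(poly & cls$effect == "synonymous")
  considered <- sum(cls$state != "unevaluated")
  structure(list(
    n_nonsynonymous = nn, n_synonymous = ns, n_considered = considered,
    polymorphic_rate = if (considered > 0) (nn + ns) / considered else NA_real_,
    ratio = if (ns > 0) nn / ns else NA_real_,
    reason = if (ns > 0) NA_character_ else "no synonymous polymorphic sites"),
    class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN/dS: %d nonsyn, %d syn over %d sites -> %s\n",
              x$n_nonsynonymous, x$n_synonymous, x$n_considered,
              if (is.na(x$ratio)) paste0("NA (", x$reason, ")")
              else format(x$ratio)))
  invisible(x)
}

#' Cross-reference dN/dS experiment on coordinate-compatible genomes
#'
#' Measures the apparent dN/dS obtained when a read set is profiled
#' against its own reference versus a closely related but incorrect
#' reference, across read lengths and deamination levels. For
#' correct-reference cells the pileup is built from reads of the source
#' genome at their true coordinates. For incorrect-reference cells the
#' pileup mixes reads of the source and reference genomes in equal parts
#' at homologous coordinates: this emulates the read stacking that a
#' mismatch-tolerant aligner produces at conserved loci when a diverged
#' relative is mapped to the wrong assembly, and places the allele
#' conflicts exactly at the known substitution positions of the synthetic
#' pair (see the methods vignette for the rationale and limits of this
#' emulation).
#'
#' @param genomes named list of >= 2 annotated \code{calc_genome}s sharing
#'   coordinates and gene sets (e.g. ancestor + \code{\link{mutate_genome}}
#'   derivatives).
#' @param read_lengths read lengths to sweep (default 100/75/50).
#' @param damage_levels named list of \code{\link{damage_profile}}s
#'   (default none / low / high deamination).
#' @param depth per-cell target coverage.
#' @param seed RNG seed; sub-seeds are derived per cell.
#' @param min_cov,dominant_freq forwarded to \code{\link{dnds}}.
#' @return an \code{xref_result}: list with \code{grid} (one row per
#'   source x reference x length x damage cell) and
#'   \code{short_read_cross_mean}, the mean dN/dS over incorrect-reference
#'   cells at the shortest read length, averaged across deamination
#'   levels.
#' @export
cross_reference_experiment <- function(genomes,
                                       read_lengths = c(100, 75, 50),
                                       damage_levels = list(
                                         none = damage_profile("none"),
                                         low = damage_profile("non_udg", d0 = 0.1),
                                         high = damage_profile("non_udg", d0 = 0.3)),
                                       depth = 10, seed,
                                       min_cov = 5, dominant_freq = 0.8) {
  if (length(genomes) < 2) stop("need at least 2 genomes")
  if (is.null(names(genomes))) names(genomes) <- vapply(genomes, `[[`, "", "id")
  rows <- list()
  cell <- 0L
  for (src in names(genomes)) for (ref in names(genomes))
    for (rl in read_lengths) for (dmg in names(damage_levels)) {
      cell <- cell + 1L
      sub_seed <- (as.integer(seed) + 7919L * cell) %% .Machine$integer.max
      gref <- genomes[[ref]]
      if (src == ref) {
        cfg <- sim_config(seed = sub_seed, depth = depth, read_length = rl,
                          damage = damage_levels[[dmg]])
        aln <- simulate_reads(genomes[[src]], cfg)
      } else {
        cfg1 <- sim_config(seed = sub_seed, depth = depth / 2,
                           read_length = rl, damage = damage_levels[[dmg]])
        cfg2 <- sim_config(seed = sub_seed + 1L, depth = depth / 2,
                           read_length = rl, damage = damage_levels[[dmg]])
        a1 <- simulate_reads(genomes[[src]], cfg1)
        a2 <- simulate_reads(gref, cfg2)
        a2$qid <- a2$qid + max(a1$qid)
        aln <- structure(rbind(a1, a2),
                         class = c("calc_alignments", "data.frame"),
                         ref_id = gref$id, ref_len = nchar(gref$sequence))
      }
      pl <- build_pileup(aln, ref_len = nchar(gref$sequence),
                         min_insert = 0)
      d <- dnds(pl, gref$genes, min_cov = min_cov,
                dominant_freq = dominant_freq)
      rows[[cell]] <- data.frame(
        source = src, reference = ref, read_length = rl, damage = dmg,
        n_nonsynonymous = d$n_nonsynonymous, n_synonymous = d$n_synonymous,
        n_considered = d$n_considered,
        polymorphic_rate = d$polymorphic_rate, ratio = d$ratio,
        stringsAsFactors = FALSE)
    }
  grid <- do.call(rbind, rows)
  cross <- grid$source != grid$reference &
    grid$read_length == min(read_lengths)
  structure(list(
    grid = grid,
    short_read_cross_mean = mean(grid$ratio[cross], na.rm = TRUE)),
    class = "xref_result")
}

#' @export
print.xref_result <- function(x, ...) {
  cat(sprintf(
    "cross-reference dN/dS grid (%d cells); short-read incorrect-reference mean %.3f\n",
    nrow(x$grid), x$short_read_cross_mean))
  invisible(x)
}
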