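#' Synthetic bacterial genome
#'
#' A genome is a list with an \code{id}, a \code{sequence} (single character
#' string over A/C/G/T) and a \code{genes} data.frame (columns \code{start},
#' \code{end}, \code{strand}; 1-based inclusive coordinates, interval length
#' divisible by 3). Genomes stand in for reference assemblies so that every
#' downstream stage can be exercised without downloads.
#'
#' @param length genome length in bases (>= 1000 for \code{random_genome}).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed (mandatory; the caller's RNG state is restored).
#' @param id sequence name.
#' @return a \code{calc_genome} object.
#' @export
random_genome <- function(length, gc = 0.5, seed, id = "chr1") {
  if (length < 1000) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  seq <- with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = probs), collapse = "")
  })
  new_genome(id, seq)
}

new_genome <- function(id, sequence, genes = NULL) {
  if (nchar(sequence) == 0) stop("empty genome sequence")
  if (grepl("[^ACGT]", sequence)) stop("genome alphabet must be A/C/G/T")
  genes <- genes %||% data.frame(gene_id = character(), start = integer(),
                                 end = integer(), strand = character())
  structure(list(id = id, sequence = sequence, genes = genes),
            class = "calc_genome")
}

#' @export
print.calc_genome <- function(x, ...) {
  cat(sprintf("genome '%s': %d bp, %d genes\n", x$id, nchar(x$sequence),
              nrow(x$genes)))
  invisible(x)
}

#' Derive a diverged copy of a genome by random substitutions
#'
#' Each site is substituted independently with probability
#' \code{divergence}; substituted sites receive one of the three other bases
#' uniformly. No indels are introduced, so coordinates (and any gene
#' annotation) remain shared between the pair. The list of substituted
#' positions is returned so simulation truth can drive oracle tests.
#'
#' @param genome a \code{calc_genome}.
#' @param divergence expected per-site substitution fraction, in \[0, 1).
#' @param seed RNG seed.
#' @param id id for the derived genome.
#' @return list with \code{genome} (the derived \code{calc_genome}, genes
#'   carried over) and \code{positions} (1-based substituted positions).
#' @export
mutate_genome <- function(genome, divergence, seed, id = NULL) {
  stopifnot(inherits(genome, "calc_genome"))
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  id <- id %||% paste0(genome$id, "_div")
  L <- nchar(genome$sequence)
  out <- with_seed(seed, {
    pos <- which(stats::runif(L) < divergence)
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    if (length(pos)) {
      ## uniform choice among the three non-reference bases
      alt_idx <- sample.int(3L, length(pos), replace = TRUE)
      for (k in seq_along(pos)) {
        others <- setdiff(BASES, chars[pos[k]])
        chars[pos[k]] <- others[alt_idx[k]]
      }
    }
    list(seq = paste(chars, collapse = ""), pos = pos)
  })
  g2 <- new_genome(id, out$seq, genome$genes)
  list(genome = g2, positions = out$pos)
}

#' Generate a genome pair at controlled divergence
#'
#' Convenience wrapper: draws a random genome and a substituted copy at the
#' requested expected divergence, the synthetic analogue of a pair of
#' related assemblies at a known average nucleotide identity
#' (\code{ANI = 1 - divergence}).
#'
#' @inheritParams random_genome
#' @param divergence expected per-site substitution fraction in \[0, 1).
#' @return list with \code{genome1}, \code{genome2} and
#'   \code{positions} (1-based true substitution positions).
#' @examples
#' p <- generate_genome_pair(10000, divergence = 0.01, seed = 1)
#' length(p$positions) / 10000  # ~0.01
#' @export
generate_genome_pair <- function(length, gc = 0.5, divergence, seed) {
  g1 <- random_genome(length, gc, seed = seed, id = "g1")
  m <- mutate_genome(g1, divergence, seed = seed + 1L, id = "g2")
  list(genome1 = g1, genome2 = m$genome, positions = m$positions)
}

#' Annotate a genome with a tiling of synthetic ORFs
#'
#' Lays down non-overlapping forward-strand genes of fixed length separated
#' by fixed spacers, then rewrites the sequence so each gene begins with ATG
#' and contains no internal stop codon (stops are recoded in place). This
#' provides the coding coordinates that the polymorphic-rate dN/dS stage
#' consumes, standing in for downloaded RefSeq annotations.
#'
#' @param genome a \code{calc_genome}.
#' @param gene_length gene length in bases, divisible by 3.
#' @param spacing intergenic spacer length in bases.
#' @return the genome with \code{genes} filled and sequence recoded.
#' @export
annotate_orfs <- function(genome, gene_length = 300, spacing = 100) {
  stopifnot(inherits(genome, "calc_genome"))
  if (gene_length %% 3 != 0) stop("gene_length must be divisible by 3")
  L <- nchar(genome$sequence)
  if (gene_length > L) stop("gene_length exceeds genome length")
  n_genes <- (L + spacing) %/% (gene_length + spacing)
  starts <- (seq_len(n_genes) - 1L) * (gene_length + spacing) + 1L
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  recode <- c(TAA = "TAC", TAG = "TAC", TGA = "TGC")
  for (s in starts) {
    chars[s:(s + 2L)] <- c("A", "T", "G")
    cod_starts <- seq(s + 3L, s + gene_length - 3L, by = 3L)
    for (cs in cod_starts) {
      cod <- paste(chars[cs:(cs + 2L)], collapse = "")
      if (cod %in% stops)
        chars[cs:(cs + 2L)] <- strsplit(recode[[cod]], "", fixed = TRUE)[[1]]
    }
  }
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    start = starts, end = starts + gene_length - 1L,
    strand = rep("+", n_genes), stringsAsFactors = FALSE)
  new_genome(genome$id, paste(chars, collapse = ""), genes)
}

#' Write / read genomes as FASTA
#'
#' Thin wrappers over \pkg{Biostrings}; gene annotations are not carried by
#' FASTA (see \code{\link{write_gff3}}).
#' @param genome a \code{calc_genome} (or list of them).
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  gs <- if (inherits(genome, "calc_genome")) list(genome) else genome
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(vapply(gs, `[[`, "", "sequence"),
                    vapply(gs, `[[`, "", "id")))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i)
    new_genome(sub("\\s.*$", "", names(seqs)[i]), as.character(seqs[[i]])))
}

#' Write / read gene annotations as GFF3
#'
#' Genes are emitted as CDS features with 1-based inclusive coordinates,
#' via \pkg{rtracklayer}.
#' @param genome a \code{calc_genome} with genes.
#' @param path file path.
#' @export
write_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "calc_genome"))
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome$id, nrow(g)),
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand, type = rep("CDS", nrow(g)), ID = g$gene_id,
    phase = rep(0L, nrow(g)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else sprintf("gene_%04d", seq_along(gr))
  data.frame(
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}
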