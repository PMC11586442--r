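#' Call per-position major alleles from a pileup
#'
#' A simple genotyper over a quality-filtered pileup: every position with
#' depth >= \code{min_cov} yields one call carrying the major allele
#' (max count, ties broken A<C<G<T), its frequency and the depth.
#' Heterozygous-style calls are retained (frequency can be well below 1)
#' and are filtered later by \code{\link{filter_homozygous}}.
#'
#' @param pileup a \code{calc_pileup}.
#' @param reference a \code{calc_genome} or reference sequence string.
#' @param min_cov minimum depth to emit a call (default 5).
#' @return data.frame: \code{pos}, \code{ref}, \code{major}, \code{freq},
#'   \code{depth}.
#' @export
call_variants <- function(pileup, reference, min_cov = 5) {
  stopifnot(inherits(pileup, "calc_pileup"))
  refseq <- if (inherits(reference, "calc_genome")) reference$sequence
            else reference
  if (nchar(refseq) != nrow(pileup$counts))
    stop("reference length does not match pileup")
  depth <- rowSums(pileup$counts)
  keep <- which(depth >= min_cov)
  maj_i <- max.col(pileup$counts[keep, , drop = FALSE], ties.method = "first")
  maj_cnt <- pileup$counts[cbind(keep, maj_i)]
  data.frame(pos = keep,
             ref = substring(refseq, keep, keep),
             major = BASES[maj_i],
             freq = maj_cnt / depth[keep],
             depth = depth[keep])
}

#' Fraction of heterozygous calls
#'
#' Share of calls whose major-allele frequency is at or below the
#' homozygosity threshold; a high value flags samples likely to contain
#' multiple strains.
#' @param calls output of \code{\link{call_variants}}.
#' @param threshold homozygosity threshold (default 0.9).
#' @export
het_fraction <- function(calls, threshold = 0.9) {
  if (!nrow(calls)) return(NA_real_)
  mean(calls$freq <= threshold)
}

#' Retain only homozygous calls
#'
#' A call is homozygous when its major-allele frequency is strictly
#' greater than the threshold (default 0.9); a frequency of exactly 0.9 is
#' removed. Idempotent.
#' @inheritParams het_fraction
#' @export
filter_homozygous <- function(calls, threshold = 0.9) {
  calls[calls$freq > threshold, , drop = FALSE]
}

#' Per-sample inclusion QC for phylogenetics
#'
#' Samples enter the tree only with at least \code{min_snps} SNPs and a
#' mean genome-wide coverage of at least \code{min_mean_cov} (both bounds
#' inclusive); the failing criterion is named.
#'
#' @param n_snps integer vector of SNP counts per sample.
#' @param mean_cov numeric vector of mean genome-wide coverage per sample.
#' @param min_snps minimum SNP count (default 1000).
#' @param min_mean_cov minimum mean coverage (e.g. 2 or 5 depending on the
#'   taxon's heterozygosity profile).
#' @param sample optional sample ids.
#' @return data.frame: sample, n_snps, mean_cov, include, reason.
#' @export
sample_qc <- function(n_snps, mean_cov, min_snps = 1000, min_mean_cov = 5,
                      sample = NULL) {
  sample <- sample %||% sprintf("sample_%03d", seq_along(n_snps))
  reason <- rep(NA_character_, length(n_snps))
  few <- n_snps < min_snps
  low <- mean_cov < min_mean_cov
  reason[few & !low] <- sprintf("fewer than %d SNPs", min_snps)
  reason[low & !few] <- sprintf("mean coverage below %gX", min_mean_cov)
  reason[few & low] <- "fewer SNPs and coverage than required"
  data.frame(sample = sample, n_snps = n_snps, mean_cov = mean_cov,
             include = is.na(reason), reason = reason)
}

#' Assemble a multi-sample homozygous-SNP alignment
#'
#' Columns are the union of positions where at least one sample carries a
#' homozygous non-reference allele. Each sample's state at a column is its
#' homozygous allele if it has a (homozygous, covered) call there, the
#' reference allele if its call at that position agrees with the reference
#' (confident reference requires the same coverage and homozygosity
#' thresholds as a SNP, i.e. presence in the filtered calls), and N
#' otherwise -- a conservative fill for insufficient data.
#'
#' @param calls_list named list of homozygous-filtered call data.frames
#'   (one per sample, from \code{\link{filter_homozygous}}), all on the
#'   same reference.
#' @param reference a \code{calc_genome} or sequence string.
#' @return a \code{snp_alignment}: list with \code{samples},
#'   \code{positions} and \code{matrix} (samples x positions characters
#'   over A/C/G/T/N).
#' @export
build_snp_alignment <- function(calls_list, reference) {
  refseq <- if (inherits(reference, "calc_genome")) reference$sequence
            else reference
  if (is.null(names(calls_list)))
    names(calls_list) <- sprintf("sample_%03d", seq_along(calls_list))
  if (any(vapply(calls_list, function(x) any(x$pos > nchar(refseq)), TRUE)))
    stop("calls outside reference; inconsistent reference lengths")
  snp_pos <- sort(unique(unlist(lapply(calls_list, function(x)
    x$pos[x$major != x$ref]))))
  mat <- matrix("N", length(calls_list), length(snp_pos),
                dimnames = list(names(calls_list), NULL))
  for (s in names(calls_list)) {
    x <- calls_list[[s]]
    hit <- match(snp_pos, x$pos)
    has <- !is.na(hit)
    mat[s, has] <- x$major[hit[has]]
  }
  structure(list(samples = names(calls_list), positions = snp_pos,
                 matrix = mat), class = "snp_alignment")
}

#' @export
print.snp_alignment <- function(x, ...) {
  cat(sprintf("SNP alignment: %d samples x %d columns (%.1f%% N)\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * mean(x$matrix == "N")))
  invisible(x)
}

#' Write a SNP alignment as FASTA
#' @param alignment a \code{snp_alignment}.
#' @param path output path.
#' @export
write_snp_alignment <- function(alignment, path) {
  seqs <- apply(alignment$matrix, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Expand a SNP alignment to full reference length
#'
#' Produces the full-length (reference-filled) alignment implied by a SNP
#' alignment: every non-variant position carries the reference base for
#' all samples, and variant columns carry each sample's state (including
#' N). Distance models such as TN93 describe genome-wide divergence;
#' computing them on variant columns alone inflates the difference
#' proportion and can saturate the closed form when lineages at very
#' different depths of divergence are mixed, so the full-length expansion
#' is the appropriate substrate for distance-based trees. It assumes
#' non-variant positions are reference-equal in every sample, which is
#' exact for the synthetic data and an approximation for real samples
#' (see the methods vignette).
#'
#' @param alignment a \code{snp_alignment}.
#' @param reference a \code{calc_genome} or reference sequence string.
#' @return character matrix (samples x reference length).
#' @export
full_snp_alignment <- function(alignment, reference) {
  stopifnot(inherits(alignment, "snp_alignment"))
  refseq <- if (inherits(reference, "calc_genome")) reference$sequence
            else reference
  chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  n <- length(alignment$samples)
  mat <- matrix(rep(chars, each = n), nrow = n,
                dimnames = list(alignment$samples, NULL))
  if (length(alignment$positions))
    mat[, alignment$positions] <- alignment$matrix
  mat
}

as_char_matrix <- function(alignment) {
  if (inherits(alignment, "snp_alignment")) alignment$matrix
  else as.matrix(alignment)
}

#' Tamura-Nei (1993) pairwise distances
#'
#' TN93 distances (distinct purine/pyrimidine transition rates, unequal
#' base frequencies) computed with \code{ape::dist.dna} under pairwise
#' deletion: each pair uses only columns where both states are in
#' A/C/G/T. An optional gamma rate-heterogeneity correction with shape
#' \code{gamma_alpha} is available (the distance-model analogue of a
#' "+G" label); the default is the uncorrected closed form. Pairs with
#' fewer than 2 shared informative columns, or whose closed form
#' saturates (logarithm of a non-positive argument), come back NA; the
#' attribute \code{undefined} lists them with a reason.
#'
#' @param alignment a \code{snp_alignment} or character matrix over
#'   A/C/G/T/N (rows = samples).
#' @param gamma_alpha optional gamma shape; NULL for no correction.
#' @return symmetric numeric matrix of distances (NA where undefined),
#'   with attribute \code{undefined}.
#' @export
tn93_distance <- function(alignment, gamma_alpha = NULL) {
  mat <- as_char_matrix(alignment)
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  if (ncol(mat) == 0) stop("empty alignment")
  bin <- ape::as.DNAbin(tolower(mat))
  d <- ape::dist.dna(bin, model = "TN93",
                     gamma = if (is.null(gamma_alpha)) FALSE else gamma_alpha,
                     pairwise.deletion = TRUE, as.matrix = TRUE)
  valid <- matrix(mat %in% BASES, nrow(mat))
  shared <- valid %*% t(valid)
  undef <- data.frame(i = integer(), j = integer(), reason = character())
  for (i in seq_len(nrow(mat) - 1)) for (j in (i + 1):nrow(mat)) {
    if (shared[i, j] < 2) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- rbind(undef, data.frame(i = i, j = j,
                                       reason = "insufficient shared sites"))
    } else if (!is.finite(d[i, j])) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- rbind(undef, data.frame(i = i, j = j, reason = "saturated"))
    }
  }
  diag(d) <- 0
  attr(d, "undefined") <- undef
  d
}

#' Neighbour-joining tree with non-negative branch lengths
#'
#' Saitou-Nei NJ via \code{ape::nj}. Negative branch lengths (a known NJ
#' artefact on noisy matrices) are clamped to zero with the deficit
#' shifted to the sister branch so tip-to-tip path lengths are preserved
#' as closely as possible; on additive matrices NJ is exact and no
#' clamping occurs.
#'
#' @param distances complete symmetric distance matrix (no NA).
#' @return an unrooted \code{phylo} tree.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (any(!is.finite(d))) stop("undefined distances present")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
      tr$edge.length[sib[1]] <- max(tr$edge.length[sib[1]], 0)
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of its longest tip-to-tip path
#' (\code{phangorn::midpoint}).
#' @param tree a \code{phylo}.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Bootstrap support for the NJ tree of a SNP alignment
#'
#' Resamples alignment columns with replacement, rebuilds the
#' TN93-distance NJ tree per replicate, and reports bipartition support
#' percentages on the full-data tree as node labels. Replicate distance
#' matrices occasionally contain undefined pairs (no shared informative
#' columns after resampling); those entries are imputed with the largest
#' finite distance of the replicate so the replicate still contributes.
#'
#' @param alignment a \code{snp_alignment} or character matrix.
#' @param replicates number of bootstrap replicates (default 200).
#' @param seed RNG seed (mandatory).
#' @param gamma_alpha optional gamma shape for TN93.
#' @return the full-data NJ tree with support percentages in
#'   \code{node.label}.
#' @export
bootstrap_support <- function(alignment, replicates = 200, seed,
                              gamma_alpha = NULL) {
  if (missing(seed)) stop("bootstrap_support requires a seed")
  mat <- as_char_matrix(alignment)
  build <- function(x) {
    d <- suppressWarnings(tn93_distance(x, gamma_alpha))
    if (any(!is.finite(d))) {
      mx <- max(d[is.finite(d)], 0)
      d[!is.finite(d)] <- mx
      diag(d) <- 0
    }
    nj_tree(d)
  }
  full <- build(mat)
  if (nrow(mat) < 4) {
    ## an unrooted tree on <= 3 tips has no internal bipartition to support
    attr(full, "replicates") <- replicates
    return(full)
  }
  counts <- with_seed(seed,
    ape::boot.phylo(full, mat, build, B = replicates, quiet = TRUE,
                    rooted = FALSE))
  full$node.label <- round(100 * counts / replicates, 1)
  attr(full, "replicates") <- replicates
  full
}

#' Concordance among trees / distance matrices (CADM, Kendall's W)
#'
#' Converts trees to cophenetic (tip-to-tip path) distance matrices,
#' stacks them, and runs \code{ape::CADM.global}: Kendall's coefficient of
#' concordance W over the ranked upper-triangle distance vectors with a
#' permutation test (tip labels of all matrices but the first are
#' permuted). W is 1 for identical distance rankings; the smallest
#' attainable p-value with \code{permutations} permutations is
#' \code{1/(permutations + 1)}.
#'
#' @param x list of \code{phylo} trees (same tip set) and/or distance
#'   matrices with identical dimnames.
#' @param permutations number of permutations (default 99).
#' @param seed RNG seed (mandatory).
#' @return a \code{concordance_result}: list with \code{W},
#'   \code{p_value}, \code{n_matrices}, \code{permutations}.
#' @export
concordance <- function(x, permutations = 99, seed) {
  if (missing(seed)) stop("concordance requires a seed")
  if (length(x) < 2) stop("need at least two trees or matrices")
  mats <- lapply(x, function(el) {
    if (inherits(el, "phylo")) stats::cophenetic(el) else as.matrix(el)
  })
  tips <- rownames(mats[[1]])
  if (is.null(tips)) stop("matrices must carry tip names")
  mats <- lapply(mats, function(m) {
    if (!setequal(rownames(m), tips)) stop("mismatched tip sets")
    m[tips, tips]
  })
  D <- do.call(rbind, mats)
  res <- with_seed(seed,
    ape::CADM.global(D, nmat = length(mats), n = length(tips),
                     nperm = permutations, silent = TRUE))
  ca <- res$congruence_analysis
  structure(list(W = unname(ca["W", 1]),
                 p_value = unname(ca["Prob.perm", 1]),
                 n_matrices = length(mats), permutations = permutations),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("CADM concordance over %d matrices: W = %.4f, p = %.4g (%d permutations)\n",
              x$n_matrices, x$W, x$p_value, x$permutations))
  invisible(x)
}
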