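#' Pipeline run configuration
#'
#' Bundles every stage threshold with its protocol default: preservation
#' cutoff 50% (adaptive burn-in), read-end masks of 1 (UDG-half) and 11
#' (non-UDG) bases, minimum insert 12, minimum coverage 5, base quality
#' 30, dominant-frequency threshold 0.8, homozygosity threshold 0.9,
#' >= 1000 SNPs with 5X mean coverage for tree inclusion, 200 bootstrap
#' replicates and 99 concordance permutations. Ranges are validated
#' before any stage runs.
#'
#' @param seed RNG seed (mandatory).
#' @param cutoff_percent,burn_in preservation screen parameters.
#' @param mask_by_udg named masks per UDG class.
#' @param min_insert,min_cov,min_base_quality pileup/comparison filters.
#' @param dominant_freq polymorphic-site threshold.
#' @param homozygous_threshold homozygous-SNP threshold.
#' @param min_snps,min_mean_cov phylogeny sample QC.
#' @param bootstrap_replicates,concordance_permutations tree parameters.
#' @param stages character vector of stages to run, in pipeline order.
#' @return a \code{run_config} list.
#' @export
run_config <- function(seed,
                       cutoff_percent = 50, burn_in = "adaptive",
                       mask_by_udg = c(none = 0, half = 1, non_udg = 11),
                       min_insert = 12, min_cov = 5, min_base_quality = 30,
                       dominant_freq = 0.8, homozygous_threshold = 0.9,
                       min_snps = 1000, min_mean_cov = 5,
                       bootstrap_replicates = 200,
                       concordance_permutations = 99,
                       stages = c("preservation", "fava", "strain",
                                  "polymorphism", "phylogeny")) {
  if (missing(seed)) stop("run_config requires a seed")
  stopifnot(cutoff_percent >= 0, cutoff_percent <= 100,
            all(mask_by_udg >= 0), min_insert >= 0, min_cov >= 1,
            min_base_quality >= 0, dominant_freq > 0, dominant_freq <= 1,
            homozygous_threshold >= 0, homozygous_threshold < 1,
            min_snps >= 0, min_mean_cov >= 0, bootstrap_replicates >= 1,
            concordance_permutations >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a sample manifest
#'
#' TSV with columns \code{sample}, \code{udg_class} (none/half/non_udg),
#' \code{group}, and optionally \code{sam} (per-sample alignment path).
#' Sample ids must be unique.
#' @param path manifest TSV.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample", "udg_class", "group")
  if (!all(req %in% names(m)))
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(m$sample)) stop("duplicate sample ids in manifest")
  bad <- setdiff(unique(m$udg_class), c("none", "half", "non_udg"))
  if (length(bad)) stop("unknown udg_class: ", paste(bad, collapse = ", "))
  m
}

#' Run the analysis pipeline end to end
#'
#' Stages run in order: preservation screen -> FAVA by group -> strain
#' comparison (masking, pileups, pairwise popANI) -> polymorphic-rate
#' dN/dS -> homozygous-SNP phylogeny. Samples failing the preservation
#' screen are excluded from all downstream stages, with the exclusion and
#' its reason recorded rather than silently dropped. Every output table
#' carries a provenance header (package version, config hash, seed);
#' reruns with the same inputs and seed are byte-identical.
#'
#' @param config a \code{\link{run_config}}.
#' @param manifest data.frame from \code{\link{read_manifest}}.
#' @param taxon_table a \code{taxon_table} covering the manifest samples.
#' @param reference a \code{calc_genome} (with genes, for the dN/dS
#'   stage) or NULL to skip alignment-based stages.
#' @param alignments named list of \code{calc_alignments} per sample
#'   (overrides \code{manifest$sam} paths).
#' @param out_dir output directory (created).
#' @return invisibly, a list of stage results; files under \code{out_dir}.
#' @export
run_pipeline <- function(config, manifest, taxon_table, reference = NULL,
                         alignments = NULL, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  missing_samples <- setdiff(manifest$sample, rownames(taxon_table$counts))
  if (length(missing_samples))
    stop("preservation stage aborted: samples absent from taxon table: ",
         paste(missing_samples, collapse = ", "))

  ## -- preservation -------------------------------------------------------
  pres <- preservation_screen(taxon_table, config$cutoff_percent,
                              config$burn_in)
  pres <- pres[match(manifest$sample, pres$sample), ]
  pres$reason <- ifelse(pres$passed, NA_character_,
                        "decay curve below cutoff after burn-in")
  results$preservation <- pres
  if ("preservation" %in% config$stages)
    write_tsv_provenance(pres, file.path(out_dir, "preservation.tsv"),
                         seed, config)
  passing <- pres$sample[pres$passed]

  ## -- FAVA ---------------------------------------------------------------
  if ("fava" %in% config$stages && length(passing) >= 1) {
    keep <- manifest$sample %in% passing
    fv <- fava_by_group(taxon_table$counts[manifest$sample[keep], ,
                                           drop = FALSE],
                        manifest$group[keep])
    results$fava <- fava_table(fv)
    write_tsv_provenance(results$fava, file.path(out_dir, "fava.tsv"),
                         seed, config)
  }

  ## -- alignment-based stages --------------------------------------------
  if (!is.null(reference)) {
    aln_of <- function(s) {
      a <- if (!is.null(alignments)) alignments[[s]]
           else if ("sam" %in% names(manifest)) {
             p <- manifest$sam[manifest$sample == s]
             if (!file.exists(p))
               stop("strain stage aborted: missing input file ", p)
             read_sam(p)
           }
      if (is.null(a)) stop("no alignments for sample ", s)
      mask_reads(a, config$mask_by_udg,
                 manifest$udg_class[manifest$sample == s])
    }
    strain_samples <- intersect(passing, manifest$sample)
    pileups <- lapply(stats::setNames(strain_samples, strain_samples),
                      function(s)
      build_pileup(aln_of(s), ref_len = nchar(reference$sequence),
                   min_base_quality = config$min_base_quality,
                   min_insert = config$min_insert))

    if ("strain" %in% config$stages && length(pileups) >= 2) {
      pairs <- utils::combn(strain_samples, 2)
      cmp <- lapply(seq_len(ncol(pairs)), function(k) {
        r <- compare_popani(pileups[[pairs[1, k]]], pileups[[pairs[2, k]]],
                            min_cov = config$min_cov)
        data.frame(sample1 = pairs[1, k], sample2 = pairs[2, k],
                   compared = r$compared_positions, popANI = r$popANI,
                   conANI = r$conANI, coverage_overlap = r$coverage_overlap)
      })
      results$strain <- do.call(rbind, cmp)
      write_tsv_provenance(results$strain,
                           file.path(out_dir, "popani_pairs.tsv"),
                           seed, config)
    }

    if ("polymorphism" %in% config$stages && nrow(reference$genes)) {
      pm <- lapply(strain_samples, function(s) {
        d <- dnds(pileups[[s]], reference$genes, min_cov = config$min_cov,
                  dominant_freq = config$dominant_freq)
        data.frame(sample = s, n_nonsynonymous = d$n_nonsynonymous,
                   n_synonymous = d$n_synonymous,
                   n_considered = d$n_considered,
                   polymorphic_rate = d$polymorphic_rate, ratio = d$ratio)
      })
      results$polymorphism <- do.call(rbind, pm)
      write_tsv_provenance(results$polymorphism,
                           file.path(out_dir, "dnds.tsv"), seed, config)
    }

    if ("phylogeny" %in% config$stages) {
      calls <- lapply(pileups, function(p)
        filter_homozygous(call_variants(p, reference,
                                        min_cov = config$min_cov),
                          config$homozygous_threshold))
      qc <- sample_qc(vapply(calls, function(x)
                        sum(x$major != x$ref), 0L),
                      vapply(pileups, function(p)
                        mean(pileup_depth(p)), 0),
                      config$min_snps, config$min_mean_cov,
                      sample = strain_samples)
      results$phylo_qc <- qc
      write_tsv_provenance(qc, file.path(out_dir, "phylo_qc.tsv"),
                           seed, config)
      inc <- qc$sample[qc$include]
      if (length(inc) >= 3) {
        alig <- build_snp_alignment(calls[inc], reference)
        if (ncol(alig$matrix) >= 1) {
          write_snp_alignment(alig, file.path(out_dir, "snp_alignment.fasta"))
          tree <- bootstrap_support(alig, config$bootstrap_replicates,
                                    seed = seed)
          tree <- midpoint_root(tree)
          ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
          results$tree <- tree
        }
      }
    }
  }
  invisible(results)
}

#' Validate input file formats
#'
#' Sanity checks that report rather than throw: SAM header and coordinate
#' bounds, FASTA alphabet, GFF3 frame divisibility, TSV numeric
#' rectangularity. Returns a machine-readable error table (zero rows when
#' everything is valid).
#'
#' @param paths named character vector; names give the declared format of
#'   each file (\code{sam}, \code{fasta}, \code{gff3}, \code{tsv}); unnamed
#'   entries are guessed from the extension.
#' @return data.frame with columns file, check, message.
#' @export
validate_formats <- function(paths) {
  errs <- list()
  add <- function(file, check, message)
    errs[[length(errs) + 1]] <<- data.frame(file = file, check = check,
                                            message = message)
  fmts <- names(paths) %||% rep("", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    fmt <- if (nzchar(fmts[i])) fmts[i] else
      switch(tolower(tools::file_ext(p)), sam = "sam",
             fa = "fasta", fasta = "fasta", gff = "gff3", gff3 = "gff3",
             tsv = "tsv", "unknown")
    if (!file.exists(p)) { add(p, "exists", "file not found"); next }
    res <- try(switch(fmt,
      sam = {
        lines <- readLines(p)
        sq <- lines[startsWith(lines, "@SQ")]
        if (!length(sq)) add(p, "sam_header", "missing @SQ line")
        else {
          ln <- as.integer(sub("^.*LN:([0-9]+).*$", "\\1", sq[1]))
          body <- lines[!startsWith(lines, "@")]
          pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 4))
          seqs <- vapply(strsplit(body, "\t"), `[`, "", 10)
          if (any(pos < 1 | pos + nchar(seqs) - 1 > ln, na.rm = TRUE))
            add(p, "sam_coords", "alignment outside reference length")
        }
      },
      fasta = {
        g <- try(read_fasta(p), silent = TRUE)
        if (inherits(g, "try-error"))
          add(p, "fasta_parse", "unreadable FASTA")
        else if (any(grepl("[^ACGTN]", vapply(g, `[[`, "", "sequence"))))
          add(p, "fasta_alphabet", "non-ACGTN characters")
      },
      gff3 = {
        g <- try(read_gff3(p), silent = TRUE)
        if (inherits(g, "try-error")) add(p, "gff3_parse", "unreadable GFF3")
        else {
          bad <- (g$end - g$start + 1) %% 3 != 0
          if (any(bad))
            add(p, "gff3_frame",
                paste("gene length not divisible by 3:",
                      paste(g$gene_id[bad], collapse = ",")))
        }
      },
      tsv = {
        t <- try(utils::read.table(p, header = TRUE, sep = "\t",
                                   comment.char = "#"), silent = TRUE)
        if (inherits(t, "try-error"))
          add(p, "tsv_parse", "unreadable TSV")
        else {
          num <- vapply(t[-1], is.numeric, TRUE)
          if (length(num) && !all(num))
            add(p, "tsv_numeric", "non-numeric abundance columns")
          else if (length(num) && any(as.matrix(t[-1]) < 0))
            add(p, "tsv_negative", "negative entries")
        }
      },
      add(p, "format", "unknown format")), silent = TRUE)
    if (inherits(res, "try-error"))
      add(p, "io", "unreadable file")
  }
  if (!length(errs))
    return(data.frame(file = character(), check = character(),
                      message = character()))
  do.call(rbind, errs)
}
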