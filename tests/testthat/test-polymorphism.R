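# polymut-style site classification and polymorphic-rate dN/dS.

# one forward gene covering positions 1..n over the given codon string
gene_df <- function(codons, strand = "+") {
  data.frame(gene_id = "g1", start = 1L,
             end = nchar(codons), strand = strand)
}

# pileup whose dominant bases spell `seq_chars`, with overrides
# counts_at[[pos]] = named count vector
spelled_pileup <- function(seq_chars, depth = 10L, counts_at = list()) {
  p <- uniform_pileup(seq_chars, depth)
  for (pos in names(counts_at)) {
    i <- as.integer(pos)
    p$counts[i, ] <- 0L
    p$counts[i, names(counts_at[[pos]])] <- as.integer(counts_at[[pos]])
  }
  p
}

test_that("coverage and dominant-frequency thresholds gate classification", {
  chars <- strsplit("ATGGCT", "")[[1]]
  # depth 4 < 5: unevaluated
  p <- spelled_pileup(chars, counts_at = list("6" = c(C = 3, T = 1)))
  cls <- classify_sites(p, gene_df("ATGGCT"))
  expect_identical(cls$state[6], "unevaluated")
  # dominant frequency 0.9 >= 0.8: monomorphic
  p <- spelled_pileup(chars, counts_at = list("6" = c(C = 9, T = 1)))
  cls <- classify_sites(p, gene_df("ATGGCT"))
  expect_identical(cls$state[6], "monomorphic")
  expect_identical(cls$effect[6], "not-applicable")
  # dominant frequency 0.7 < 0.8: polymorphic; GCC vs GCT both Ala
  p <- spelled_pileup(chars, counts_at = list("6" = c(C = 7, T = 3)))
  cls <- classify_sites(p, gene_df("ATGGCT"))
  expect_identical(cls$state[6], "polymorphic")
  expect_identical(cls$effect[6], "synonymous")
  expect_equal(cls$dom_freq[6], 0.7)
  expect_identical(cls$secondary[6], "T")

  expect_error(classify_sites(p, data.frame(gene_id = "g", start = 1,
                                            end = 5, strand = "+")),
               "divisible by 3")
})

test_that("reverse-strand genes are classified in coding orientation", {
  # reference AGC; minus-strand gene reads revcomp = GCT (Ala)
  chars <- strsplit("AGC", "")[[1]]
  p <- spelled_pileup(chars, counts_at = list("1" = c(A = 7, G = 3)))
  cls <- classify_sites(p, gene_df("AGC", strand = "-"))
  # reference position 1 is codon position 3 on the minus strand
  row <- cls[cls$pos == 1, ]
  expect_equal(row$codon_pos, 3)
  expect_identical(row$dominant, "T")  # complement of A
  expect_identical(row$state, "polymorphic")
  expect_identical(row$effect, "synonymous")  # GCT -> GCC, both Ala
})

test_that("dN/dS aggregates site classes; hand case gives ratio 1", {
  # ATG GCT AAA: make GCT pos 3 synonymous-polymorphic and
  # AAA pos 1 nonsynonymous-polymorphic (AAA Lys -> CAA Gln)
  chars <- strsplit("ATGGCTAAA", "")[[1]]
  p <- spelled_pileup(chars, counts_at = list(
    "6" = c(C = 7, T = 3), "7" = c(A = 7, C = 3)))
  d <- dnds(p, gene_df("ATGGCTAAA"))
  expect_equal(d$n_synonymous, 1L)
  expect_equal(d$n_nonsynonymous, 1L)
  expect_equal(d$ratio, 1)
  expect_equal(d$n_considered, 9L)

  # single-strain perfect reads: no polymorphism, ratio NA with reason
  clean <- dnds(uniform_pileup(chars), gene_df("ATGGCTAAA"))
  expect_equal(clean$n_nonsynonymous + clean$n_synonymous, 0L)
  expect_true(is.na(clean$ratio))
  expect_match(clean$reason, "no synonymous")
})

test_that("classification is invariant to depth scaling", {
  g <- annotate_orfs(random_genome(3000, 0.5, seed = 12), 300, 100)
  chars <- strsplit(g$sequence, "")[[1]]
  p1 <- uniform_pileup(chars, 8L)
  set.seed(4)
  poly <- sample(3000, 30)
  for (i in poly) {
    alt <- setdiff(BASES4, chars[i])[1]
    p1$counts[i, alt] <- 5L  # dominant freq 8/13 < 0.8
  }
  p3 <- make_pileup(p1$counts * 3L)
  c1 <- classify_sites(p1, g$genes)
  c3 <- classify_sites(p3, g$genes)
  expect_identical(c1$state, c3$state)
  expect_identical(c1$effect, c3$effect)
  expect_equal(dnds(p1, g$genes)$ratio, dnds(p3, g$genes)$ratio)
})

test_that("a 50:50 strain mixture recovers the coding truth sites", {
  anc <- annotate_orfs(random_genome(30000, 0.5, seed = 21), 300, 50)
  der <- mutate_genome(anc, 0.02, seed = 22)
  cfg1 <- sim_config(seed = 23, depth = 12, read_length = 75)
  cfg2 <- sim_config(seed = 24, depth = 12, read_length = 75)
  a1 <- simulate_reads(anc, cfg1)
  a2 <- simulate_reads(der$genome, cfg2)
  a2$qid <- a2$qid + max(a1$qid)
  both <- rbind(a1, a2)
  attr(both, "ref_len") <- 30000L
  class(both) <- c("calc_alignments", "data.frame")
  p <- build_pileup(both, ref_len = 30000, min_insert = 0)
  cls <- classify_sites(p, anc$genes)
  poly_pos <- cls$pos[cls$state == "polymorphic"]
  in_genes <- unlist(Map(seq, anc$genes$start, anc$genes$end))
  truth <- intersect(der$positions, in_genes)
  # recovered polymorphic sites are essentially the coding truth sites
  expect_gt(length(intersect(poly_pos, truth)) / length(truth), 0.85)
  # and vastly outnumber the single-strain case
  single <- classify_sites(build_pileup(a1, ref_len = 30000,
                                        min_insert = 0), anc$genes)
  expect_gt(length(poly_pos), 20 * sum(single$state == "polymorphic"))
})

test_that("masking removes the damage-induced polymorphism floor", {
  g <- annotate_orfs(random_genome(20000, 0.5, seed = 31), 300, 50)
  cfg <- sim_config(seed = 32, depth = 25, read_length = 75,
                    damage = damage_profile("non_udg"))
  aln <- simulate_reads(g, cfg)
  raw <- dnds(build_pileup(aln, min_insert = 0), g$genes)
  masked <- dnds(build_pileup(mask_reads(aln, 11), min_insert = 0), g$genes)
  expect_lte(masked$n_nonsynonymous + masked$n_synonymous,
             raw$n_nonsynonymous + raw$n_synonymous)
  expect_equal(masked$polymorphic_rate, 0)
})
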