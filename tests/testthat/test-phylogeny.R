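# Variant calling, homozygous-SNP alignments, TN93/NJ trees, concordance.

test_that("variant calls respect the coverage floor and report frequencies", {
  cnt <- matrix(0L, 4, 4, dimnames = list(NULL, BASES4))
  cnt[1, "A"] <- 4L                      # depth 4: no call
  cnt[2, "A"] <- 19L; cnt[2, "G"] <- 1L  # freq 0.95
  cnt[3, "A"] <- 9L; cnt[3, "G"] <- 1L   # freq exactly 0.9
  cnt[4, "C"] <- 12L
  calls <- call_variants(make_pileup(cnt), "TTTT", min_cov = 5)
  expect_identical(calls$pos, c(2L, 3L, 4L))
  expect_equal(calls$freq, c(0.95, 0.9, 1))
  expect_identical(calls$major, c("A", "A", "C"))
  expect_equal(het_fraction(calls), 1 / 3)
})

test_that("homozygous filtering is strict at 0.9 and idempotent", {
  calls <- data.frame(pos = 1:3, ref = "A", major = "G",
                      freq = c(0.95, 0.9, 1), depth = 20)
  kept <- filter_homozygous(calls)
  expect_identical(kept$pos, c(1L, 3L))
  expect_identical(filter_homozygous(kept), kept)
})

test_that("sample QC applies inclusive bounds and names the failure", {
  qc <- sample_qc(n_snps = c(999, 1000, 1000, 500),
                  mean_cov = c(5, 1.9, 5.0, 1.0),
                  min_snps = 1000, min_mean_cov = 2)
  expect_identical(qc$include, c(FALSE, FALSE, TRUE, FALSE))
  expect_match(qc$reason[1], "fewer than 1000 SNPs")
  expect_match(qc$reason[2], "coverage below 2X")
  expect_match(qc$reason[4], "fewer SNPs and coverage")
})

test_that("SNP alignment assembles columns with reference fill and N", {
  ref <- "AAAAAA"
  s1 <- data.frame(pos = c(2L, 5L), ref = c("A", "A"),
                   major = c("G", "A"), freq = 1, depth = 10)
  s2 <- data.frame(pos = 5L, ref = "A", major = "T", freq = 1, depth = 10)
  alig <- build_snp_alignment(list(s1 = s1, s2 = s2), ref)
  expect_equal(alig$positions, c(2L, 5L))
  # s1 has a SNP at 2 and confirms reference at 5; s2 is uncovered at 2
  expect_identical(alig$matrix["s1", ], c("G", "A"))
  expect_identical(alig$matrix["s2", ], c("N", "T"))
  # no SNPs anywhere: empty alignment, tree building refused downstream
  none <- build_snp_alignment(
    list(a = s1[2, ], b = s1[2, ]), ref)
  expect_equal(ncol(none$matrix), 0)
  expect_error(tn93_distance(none), "empty")
})

# independent closed-form TN93 oracle (hand-coded, separate from ape)
tn93_oracle <- function(x, y) {
  keep <- x %in% BASES4 & y %in% BASES4
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  pr <- table(factor(c(x, y), levels = BASES4)) / (2 * n)
  pA <- pr[["A"]]; pC <- pr[["C"]]; pG <- pr[["G"]]; pT <- pr[["T"]]
  pR <- pA + pG; pY <- pC + pT
  P1 <- mean((x == "A" & y == "G") | (x == "G" & y == "A"))
  P2 <- mean((x == "C" & y == "T") | (x == "T" & y == "C"))
  Q <- mean(x != y) - P1 - P2
  e1 <- 1 - pR * P1 / (2 * pA * pG) - Q / (2 * pR)
  e2 <- 1 - pY * P2 / (2 * pC * pT) - Q / (2 * pY)
  e3 <- 1 - Q / (2 * pR * pY)
  -2 * pA * pG / pR * log(e1) - 2 * pC * pT / pY * log(e2) -
    2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY) * log(e3)
}

test_that("TN93 distances match an independent closed-form evaluation", {
  # identical sequences: zero
  m <- rbind(a = rep(BASES4, 10), b = rep(BASES4, 10))
  expect_equal(unname(tn93_distance(m)[1, 2]), 0)

  # 100 columns, 10 A<->G transitions: closed form from counted proportions
  x <- rep(BASES4, 25)
  y <- x
  y[which(x == "A")[1:10]] <- "G"
  d <- tn93_distance(rbind(a = x, b = y))
  expect_equal(unname(d[1, 2]), tn93_oracle(x, y), tolerance = 1e-12)

  # random sequence pairs agree with the oracle too
  set.seed(11)
  for (i in 1:5) {
    x <- sample(BASES4, 400, replace = TRUE)
    y <- x
    flip <- sample(400, 30)
    y[flip] <- vapply(y[flip], function(b) sample(setdiff(BASES4, b), 1), "")
    expect_equal(unname(tn93_distance(rbind(a = x, b = y))[1, 2]),
                 tn93_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("TN93 reduces to Jukes-Cantor in the symmetric limit", {
  # balanced base frequencies; substitutions spread uniformly over all 12
  # ordered types (P1 = P2 = Q/4)
  s1 <- c(rep("A", 12), rep("C", 12), rep("G", 12), rep("T", 12))
  s2 <- s1
  s2[1] <- "G"; s2[25] <- "A"        # A<->G
  s2[13] <- "T"; s2[37] <- "C"       # C<->T
  s2[2:3] <- "C"; s2[14:15] <- "A"   # transversions
  s2[26:27] <- "T"; s2[38:39] <- "G"
  jc <- -3 / 4 * log(1 - 4 / 3 * (12 / 48))
  expect_equal(unname(tn93_distance(rbind(a = s1, b = s2))[1, 2]), jc,
               tolerance = 1e-10)
})

test_that("pairs without shared informative sites are undefined", {
  m <- rbind(a = c("A", "C", "N", "N"), b = c("N", "N", "G", "T"),
             c = c("A", "C", "G", "T"))
  d <- tn93_distance(m)
  expect_true(is.na(d["a", "b"]))
  und <- attr(d, "undefined")
  expect_match(und$reason[1], "insufficient shared sites")
  expect_false(is.na(d["a", "c"]))
  expect_error(nj_tree(d), "undefined distances")
})

test_that("NJ satisfies the three-point formulas and recovers additive trees", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d3)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    d <- stats::cophenetic(true)
    rec <- nj_tree(d)
    # exact topology and branch lengths on additive input
    expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(stats::cophenetic(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    expect_true(all(rec$edge.length >= 0))
  }
})

test_that("midpoint rooting is equidistant on two-tip trees", {
  tr <- ape::read.tree(text = "(a:1,b:3);")
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)
  expect_equal(depths[1], depths[2], tolerance = 1e-12)
  expect_equal(depths[1], 2)
})

test_that("bootstrap support is 100 for congruent columns, seeded", {
  # 5 taxa: invariant background plus perfectly congruent ladder columns
  col_block <- function(split, n) {
    v <- rep("A", 5); v[split] <- "G"; matrix(rep(v, n), 5)
  }
  set.seed(8)
  bg <- matrix(rep(sample(BASES4, 200, replace = TRUE), each = 5), 5)
  m <- cbind(bg, col_block(4:5, 25), col_block(3:5, 25), col_block(5, 20))
  rownames(m) <- paste0("t", 1:5)
  tr1 <- bootstrap_support(m, replicates = 50, seed = 5)
  expect_true(all(stats::na.omit(tr1$node.label) == 100))
  tr2 <- bootstrap_support(m, replicates = 50, seed = 5)
  expect_identical(tr1$node.label, tr2$node.label)
  expect_error(bootstrap_support(m, replicates = 10), "seed")
})

test_that("conflicting column classes split bootstrap support", {
  # 4 taxa, 50/50 columns supporting t1t2|t3t4 vs t1t3|t2t4 over an
  # invariant background
  cA <- c("G", "G", "A", "A"); cB <- c("G", "A", "G", "A")
  set.seed(12)
  bg <- matrix(rep(sample(BASES4, 120, replace = TRUE), each = 4), 4)
  m <- cbind(bg, matrix(rep(cA, 30), 4), matrix(rep(cB, 30), 4))
  rownames(m) <- paste0("t", 1:4)
  tr <- bootstrap_support(m, replicates = 200, seed = 9)
  sup <- stats::na.omit(tr$node.label)
  sup <- sup[sup > 0]
  # the single internal bipartition wins about half the replicates
  expect_true(all(sup >= 25 & sup <= 75))
})

test_that("concordance is 1 for identical trees with the minimal p-value", {
  set.seed(3)
  tr <- ape::rtree(6)
  res <- concordance(list(tr, tr), permutations = 99, seed = 17)
  expect_equal(res$W, 1)
  expect_equal(res$p_value, 0.01)  # 1/(99+1)
})

test_that("reversed distance rankings drive Kendall's W to zero", {
  n <- 5
  d1 <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d1[upper.tri(d1)] <- 1:10
  d1 <- d1 + t(d1)
  d2 <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d2[upper.tri(d2)] <- 11 - (1:10)
  d2 <- d2 + t(d2)
  res <- concordance(list(d1, d2), permutations = 99, seed = 23)
  expect_lt(res$W, 1e-10)
})

test_that("mismatched tip sets are rejected", {
  set.seed(2)
  t1 <- ape::rtree(5); t2 <- ape::rtree(5)
  t2$tip.label <- paste0("x", 1:5)
  expect_error(concordance(list(t1, t2), seed = 1), "mismatched tip sets")
})
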