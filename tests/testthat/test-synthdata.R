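# Synthetic genomes, damaged reads, taxon tables.

test_that("genome pairs honour the requested divergence", {
  # zero divergence: identical copies
  p0 <- generate_genome_pair(10000, divergence = 0, seed = 1)
  expect_identical(p0$genome1$sequence, p0$genome2$sequence)
  expect_length(p0$positions, 0)

  # binomial check against the returned truth list at divergence 0.001
  p1 <- generate_genome_pair(100000, divergence = 0.001, seed = 7)
  expect_lt(abs(length(p1$positions) - 100), 3 * sqrt(100 * 0.999))
  # every listed position truly differs; all others agree
  c1 <- strsplit(p1$genome1$sequence, "")[[1]]
  c2 <- strsplit(p1$genome2$sequence, "")[[1]]
  diffs <- which(c1 != c2)
  expect_identical(diffs, as.integer(p1$positions))

  # 5% divergence sits at the ~95% identity species cutoff
  p5 <- generate_genome_pair(100000, divergence = 0.05, seed = 7)
  identity <- 100 * (1 - length(p5$positions) / 100000)
  expect_lt(abs(identity - 95), 0.3)

  expect_error(generate_genome_pair(10000, divergence = 1, seed = 1),
               "divergence")
})

test_that("genome generation is seed-deterministic and alphabet-checked", {
  g1 <- random_genome(2000, 0.6, seed = 3)
  g2 <- random_genome(2000, 0.6, seed = 3)
  expect_identical(g1$sequence, g2$sequence)
  gc <- mean(strsplit(g1$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.6), 0.05)
  expect_error(calcstrain:::new_genome("x", "ACGTN"), "alphabet")
})

test_that("ORF annotation tiles genes with intact frames and no stops", {
  g <- annotate_orfs(random_genome(3000, 0.5, seed = 2), 300, 100)
  expect_equal(nrow(g$genes), 7)  # floor((3000+100)/(300+100))
  expect_true(all((g$genes$end - g$genes$start + 1) %% 3 == 0))
  for (i in seq_len(nrow(g$genes))) {
    cds <- substring(g$sequence, g$genes$start[i], g$genes$end[i])
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- seqinr::translate(strsplit(cds, "")[[1]])
    expect_false(any(aa[-length(aa)] == "*"))
  }
  expect_error(annotate_orfs(random_genome(3000, 0.5, seed = 2), 301),
               "divisible by 3")
})

test_that("undamaged reads are exact genome substrings at their coordinates", {
  g <- random_genome(20000, 0.5, seed = 4)
  aln <- simulate_reads(g, sim_config(seed = 5, n_pairs = 300,
                                      read_length = 50))
  expect_true(all(aln$len == 50))  # fixed read length: point mass
  got <- substring(g$sequence, aln$start, aln$start + aln$len - 1)
  expect_identical(aln$seq, got)
  expect_true(all(abs(aln$tlen) >= aln$len))
})

test_that("deamination follows the geometric terminal profile", {
  g <- random_genome(50000, 0.5, seed = 6)
  prof <- damage_profile("non_udg")  # d0 = 0.30, decay = 0.70
  aln <- simulate_reads(g, sim_config(seed = 9, n_pairs = 8000,
                                      read_length = 60, damage = prof))
  ref <- substring(g$sequence, aln$start, aln$start + aln$len - 1)
  refc <- do.call(rbind, strsplit(ref, ""))
  obsc <- do.call(rbind, strsplit(aln$seq, ""))
  # empirical C>T rate at the left terminus and by position
  rates <- vapply(1:10, function(j) {
    isC <- refc[, j] == "C"
    mean(obsc[isC, j] == "T")
  }, 0)
  nC <- vapply(1:10, function(j) sum(refc[, j] == "C"), 0)
  expect_lt(abs(rates[1] - 0.30), 3 * sqrt(0.3 * 0.7 / nC[1]))
  # matches d0 * decay^i within binomial error, hence non-increasing
  for (j in 1:10) {
    want <- 0.30 * 0.70^(j - 1)
    expect_lt(abs(rates[j] - want),
              4 * sqrt(want * (1 - want) / nC[j]) + 1e-9)
  }
  # no damage beyond the modelled extent
  isC <- refc[, 20] == "C"
  expect_equal(mean(obsc[isC, 20] == "T"), 0)
  # G>A mirrored at the right end
  isG <- refc[, 60] == "G"
  expect_gt(mean(obsc[isG, 60] == "A"), 0.25)
})

test_that("UDG-half damage is confined to the terminal two bases", {
  prof <- damage_profile("half")
  expect_lte(prof$extent, 2)
  expect_equal(damage_rate(prof, 0:4), c(0.05, 0.025, 0, 0, 0))
})

test_that("simulation is byte-identical under a fixed seed (SAM output)", {
  g <- random_genome(5000, 0.5, seed = 8)
  cfg <- sim_config(seed = 21, n_pairs = 200, read_length = 75,
                    damage = damage_profile("non_udg"))
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(simulate_reads(g, cfg), f1, udg_class = "non_udg")
  write_sam(simulate_reads(g, cfg), f2, udg_class = "non_udg")
  expect_identical(readLines(f1), readLines(f2))
  # round trip preserves the alignment table
  aln <- simulate_reads(g, cfg)
  back <- read_sam(f1)
  expect_equal(back$start, aln$start)
  expect_equal(back$seq, aln$seq)
  expect_equal(back$tlen, aln$tlen)
  expect_equal(attr(back, "ref_len"), 5000L)
})

test_that("empirical read-length lists are honoured", {
  g <- random_genome(20000, 0.5, seed = 4)
  for (rl in c(50, 75, 100)) {
    a <- simulate_reads(g, sim_config(seed = 3, n_pairs = 100,
                                      read_length = rl))
    expect_true(all(a$len == rl))
  }
  a <- simulate_reads(g, sim_config(seed = 3, n_pairs = 400,
                                    read_length = c(50, 75, 100)))
  expect_true(all(a$len %in% c(50, 75, 100)))
  expect_gt(length(unique(a$len)), 1)
})

test_that("taxon tables realize the requested oral mass", {
  # pure oral / pure environmental endpoints
  t1 <- make_taxon_table(3, 20, oral_fraction = 1, seed = 2)
  nz <- colnames(t1$counts)[colSums(t1$counts) > 0]
  expect_true(all(nz %in% t1$oral))
  t0 <- make_taxon_table(3, 20, oral_fraction = 0, seed = 2)
  expect_true(all(colSums(t0$counts[, t0$oral]) == 0))

  tt <- make_taxon_table(20, 50, oral_fraction = 0.8, seed = 3)
  mass <- rowSums(tt$counts[, tt$oral]) / rowSums(tt$counts)
  expect_lt(abs(mean(mass) - 0.8), 0.05)
  expect_error(make_taxon_table(0, 10, 0.5, seed = 1), "n_samples")

  # TSV round trip
  f <- tempfile(fileext = ".tsv"); fo <- tempfile(fileext = ".txt")
  write_taxon_table(tt, f, fo)
  back <- read_taxon_table(f, fo)
  expect_equal(unname(back$counts), unname(tt$counts))
  expect_identical(back$oral, tt$oral)
})
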