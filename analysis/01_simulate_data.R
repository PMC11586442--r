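#!/usr/bin/env Rscript

# Build the synthetic study inputs every later step consumes: an
# annotated reference genome, a two-island panel of strain genomes,
# per-sample damaged read sets (SAM), a sample-by-taxon abundance table
# with its oral reference list, and a sample manifest.

suppressPackageStartupMessages(library(calcstrain))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Reference genome: 100 kb, GC 0.5, ORFs of 300 bp every 400 bp")
ref <- annotate_orfs(random_genome(100000, gc = 0.5, seed = seed), 300, 100)
write_fasta(ref, file.path(out, "reference.fasta"))
write_gff3(ref, file.path(out, "reference.gff3"))

message("Two islands of strains: founders at 0.2% divergence, ",
        "4 samples each at 0.02% within-island pair divergence")
fA <- mutate_genome(ref, 0.001, seed = seed + 1L, id = "founderA")$genome
fB <- mutate_genome(ref, 0.001, seed = seed + 2L, id = "founderB")$genome
panel <- c(
  lapply(1:4, function(i) mutate_genome(fA, 1e-4, seed = 100 + i,
                                        id = paste0("A", i))$genome),
  lapply(1:4, function(i) mutate_genome(fB, 1e-4, seed = 200 + i,
                                        id = paste0("B", i))$genome))
names(panel) <- vapply(panel, `[[`, "", "id")

udg <- rep(c("half", "non_udg"), 4)
for (i in seq_along(panel)) {
  cfg <- sim_config(seed = 300 + i, depth = 12, read_length = 75,
                    damage = damage_profile(udg[i]))
  aln <- simulate_reads(panel[[i]], cfg)
  write_sam(aln, file.path(out, paste0(names(panel)[i], ".sam")),
            udg_class = udg[i])
  message(sprintf("  %s: %d reads (%s library)", names(panel)[i],
                  nrow(aln), udg[i]))
}

message("Taxon table: 8 calculus-like samples (high oral mass) plus 2 ",
        "contaminated burials (low oral mass)")
tt <- make_taxon_table(10, n_taxa = 60, n_oral = 40,
                       oral_fraction = c(rep(0.9, 8), 0.1, 0.15),
                       seed = seed + 3L)
rownames(tt$counts) <- c(names(panel), "C1", "C2")
write_taxon_table(tt, file.path(out, "taxa.tsv"),
                  file.path(out, "oral_taxa.txt"))

manifest <- data.frame(
  sample = rownames(tt$counts),
  udg_class = c(udg, "none", "none"),
  group = c(rep(c("island_A", "island_B"), each = 4), "burial", "burial"),
  sam = c(file.path(out, paste0(names(panel), ".sam")), NA, NA))
utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Inputs written under ", out)
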