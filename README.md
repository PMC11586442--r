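# calcstrain

Strain-level and community analyses for ancient dental calculus
metagenomes.

Archaeological dental calculus preserves oral bacterial DNA for
millennia, but the reads are short, carry terminal deamination damage
(C→T at 5′ ends, G→A at 3′ ends), and sit in a matrix of
burial-environment contamination. `calcstrain` implements the
computational core needed to work at strain resolution under those
conditions, for researchers analysing ancient oral metagenomes or
benchmarking strain methods against ancient-DNA damage:

- **Preservation screening** — cumulative percent decay curves:
  `curve(k) = 100 · |{oral taxa among the top k by abundance}| / k`,
  classified against a cutoff (default 50%) with an adaptive burn-in.
- **Community variability** — FAVA, the FST-based statistic
  `(H_T − H̄_S) / H_T` over relative-abundance vectors, 0 for identical
  samples, 1 for maximally distinct single-species samples, undefined
  (with reason) for singleton groups.
- **Strain identity** — popANI/conANI from masked base-count pileups:
  a popANI substitution is a jointly covered position where two samples
  share *no* detected allele, making the statistic robust to residual
  damage; popANI > 99.999 ⇒ identical strains, ≤ 99.99 ⇒ shared but
  distinct. Includes the mask-length × insert-size calibration sweep
  ("maximum popANI with minimal loss of coverage").
- **Multi-strain detection** — polymorphic-rate dN/dS over coding genes
  (site polymorphic iff dominant allele frequency < 0.8; effect from
  substituting the secondary allele into the dominant-allele codon),
  plus the wrong-reference control experiment.
- **Phylogenetics** — homozygous-SNP alignments (major frequency > 0.9,
  coverage ≥ 5), TN93 distances, neighbour-joining trees with 200
  bootstrap replicates and midpoint rooting, CADM/Kendall's W tree
  concordance.
- **Synthetic data** — seeded generators for genomes at controlled
  divergence, ORF annotations, damaged paired-end read alignments (SAM),
  strain mixtures and abundance tables, so the whole pipeline is
  testable without downloading a single sequence.

## Worked example

Two read sets simulated from the *same* 100 kb genome with heavy
non-UDG damage, compared under the calibrated protocol (mask 11 bases
per read end, minimum insert 12, base quality ≥ 30, coverage ≥ 5):

```r
library(calcstrain)

g <- random_genome(100000, gc = 0.5, seed = 1)
prof <- damage_profile("non_udg")           # C>T 0.30 decaying by 0.70
a1 <- simulate_reads(g, sim_config(seed = 11, depth = 30,
                                   read_length = 75, damage = prof))
a2 <- simulate_reads(g, sim_config(seed = 12, depth = 30,
                                   read_length = 75, damage = prof))
compare_popani(
  build_pileup(mask_reads(a1, 11), min_base_quality = 30, min_insert = 12),
  build_pileup(mask_reads(a2, 11), min_base_quality = 30, min_insert = 12),
  min_cov = 5)
#> compared 99911 positions: popANI 100.00000% (0 subs), conANI 100.00000% (0 subs), overlap 1.000
```

Despite ~30% terminal damage, masking leaves zero popANI substitutions
across ~10^5 compared positions — an "identical strains" call. Repeating
with a genome pair at 0.1% divergence
(`generate_genome_pair(100000, divergence = 0.001, seed = 1)`) gives

```
#> compared 99904 positions: popANI 99.91092% (89 subs), ...
```

which matches the truth list exactly (89 substitutions were introduced)
and lands below the 99.99 "shared, not identical" bound.

FAVA reads the same way at the community level:

```r
fava(rbind(c(1, 0), c(0.5, 0.5)))$value   # 1/3
fava(diag(3))$value                       # 1 (each sample its own taxon)
fava(matrix(0.25, 2, 4))$value            # 0 (identical samples)
```

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R     # genomes, reads (SAM), taxa, manifest
Rscript analysis/02_preservation_fava.R # decay screen + FAVA by island
Rscript analysis/03_strain_identity.R   # calibration sweep + pairwise popANI
Rscript analysis/04_polymorphism.R      # dN/dS: single strains, mixture, wrong reference
Rscript analysis/05_phylogeny.R         # SNP alignment, NJ tree, concordance
```

Each script states what it found; all randomness is seeded, and reruns
are byte-identical. `run_pipeline()` performs the same orchestration as
a single call with one `run_config()` of thresholds.

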