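---
title: "Methods: strain-level analysis of ancient dental calculus metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level analysis of ancient dental calculus metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcstrain)
```

# Scope

`calcstrain` implements the computational spine of strain-level and
community analyses for ancient oral metagenomes, where post-mortem DNA
damage, short fragments and burial-environment contamination complicate
every step. The package covers six stages, each usable on its own:

1. **Synthetic data** — seeded genomes, annotations, damaged paired-end
   read alignments and abundance tables, so every downstream stage can be
   exercised and tested without any sequence download.
2. **Preservation screening** — cumulative percent decay curves of
   oral-taxon content.
3. **Community variability** — the FST-based FAVA statistic.
4. **Strain identity** — masked pileups and popANI/conANI comparisons,
   with the mask-length/insert-size calibration sweep.
5. **Multi-strain detection** — polymorphic-rate dN/dS over coding genes.
6. **Phylogenetics** — homozygous-SNP alignments, TN93 distances,
   neighbour-joining trees with bootstrap and midpoint rooting, and CADM
   concordance.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where the
methods literature leaves the details open. Nothing here states an
empirical result that the test suite or the analysis scripts do not
themselves compute.

# The damage model

Post-mortem cytosine deamination appears in sequencing data as C→T
substitutions concentrated at the 5′ ends of reads and, in
double-stranded libraries, mirrored G→A substitutions at 3′ ends. We
model the per-position substitution probability as geometric decay from
the read terminus,

$$\mathrm{rate}(i) = d_0\,\lambda^i \;(i < e), \qquad \mathrm{rate}(i) = 0
\;(i \ge e),$$

with $i$ the 0-based distance from the read end, amplitude $d_0$, decay
$\lambda \in (0,1]$ and extent $e$. Three default profiles bracket
typical published ancient-DNA damage:

| profile   | $d_0$ | $\lambda$ | $e$ | emulates                          |
|-----------|------:|----------:|----:|-----------------------------------|
| `non_udg` | 0.30  | 0.70      | 15  | untreated libraries               |
| `half`    | 0.05  | 0.50      |  2  | partial-UDG treatment             |
| `none`    | 0     | —         |  0  | modern / fully repaired DNA       |

Two parameters reproduce the qualitative "high at the termini, decaying
over ~10 bp" shape that read-end masking exploits; the model deliberately
omits what masking does not interact with: there are **no indels and no
sequencing error other than deamination**, base qualities are constant
(Q37) unless a fixture says otherwise, and damage is drawn independently
on the two mates of a pair (real deamination lives on the fragment, so
overlapping mates can disagree here — which is precisely what the
mate-overlap deduplication rule must tolerate). Empirical profile fitting
from real alignments is out of scope; the defaults are stand-ins chosen
once, not fits.

Applying damage in read orientation (C→T from the read 5′ end, G→A from
the 3′ end) and storing sequences in reference orientation is equivalent,
for either strand, to C→T at the alignment's left end and G→A at its
right end with the same positional rates; the empirical-rate tests
exploit this identity.

# Read simulation

Fragments are placed uniformly on the genome; fragment (= insert =
template) lengths follow a log-normal (default meanlog $\log 120$, sdlog
0.35) truncated to `[insert_min, insert_max]`. Read length is
`min(read_length, fragment)`: short ancient fragments yield fully
overlapping mate pairs, which is what makes the minimum-insert filter and
overlap deduplication meaningful. With the default
`insert_min = read_length` all reads are exactly `read_length` bases — a
point-mass read-length distribution, matching the short/medium/long (50,
75, 100 bp) design used in the damage experiments. True alignment
coordinates are recorded, so no aligner is involved anywhere in the
package; SAM output carries a correct header, 1-based positions,
proper-pair flags and signed template lengths, and reruns with the same
seed are byte-identical.

Coordinates are 1-based inclusive throughout the R API (the R idiom);
SAM and GFF3 are written in their native 1-based conventions.

# Masked pileups

`mask_reads()` flags the first and last $N$ aligned bases of each read as
non-contributing without shortening reads or moving coordinates; a read
of aligned length $\le 2N$ contributes nothing. `build_pileup()` then
counts A/C/G/T per position after three further filters, in this order:

* pairs with template length `< min_insert` (default 12) are excluded
  entirely;
* bases with quality below `min_base_quality` (default 30) are dropped;
* where the two mates of a pair overlap, each position is counted
  **once** — the higher-quality base wins, ties keep the first mate.
  Double-counting overlapping mates would inflate depth exactly at the
  short inserts that the insert filter is calibrated around.

# popANI / conANI strain comparisons

Positions covered at `min_cov` (default 5) or more in both samples are
compared. A sample's detected allele set at a position contains the bases
with count ≥ 2 and frequency ≥ 0.05 (these two thresholds are not fixed
by the methods literature we follow; they mirror the referenced strain
tool's defaults and are exposed as parameters). Then

* a **popANI substitution** is a compared position where the allele sets
  are disjoint (no shared allele);
* a **conANI substitution** is a compared position where the consensus
  bases differ (consensus = max count, ties broken A<C<G<T for
  determinism);
* `popANI = 100 (1 − substitutions / compared)`, likewise conANI.

Sharing a minor allele rescues a position from being a popANI
substitution, which is why popANI ≥ conANI always, and why popANI is the
statistic robust to residual damage: a damaged minority of reads cannot
create a disjoint allele pair as long as the true allele remains
detected. The working thresholds are popANI > 99.999 for "identical
strains" and ≤ 99.99 for "shared but distinct strains".
`coverage_overlap` is reported as compared positions over positions
reaching `min_cov` in either sample.

## Calibration sweep

`calibration_sweep()` re-runs masking, pileup and comparison over a grid
of mask lengths (default {0, 1, 9, 11, 13, 15}) × minimum inserts
(default {12, 24, 36, 48}) and codifies "maximum popANI with minimal loss
of coverage" as an explicit rule: among cells whose popANI is within a
tolerance (default $10^{-4}$ percentage points) of the grid maximum,
select the smallest mask, then the smallest insert. On damage-free input
every cell sits at 100 and mask 0 is selected; on damaged input the rule
reproduces the protocol choice of masking 11 bases at a minimum insert of
12 whenever smaller masks lose popANI. Mean depth decreases strictly with
mask length, which the sweep reports alongside popANI so the coverage
cost is visible.

# Polymorphic-rate dN/dS

`classify_sites()` evaluates every coding position of a quality-filtered
pileup: depth < `min_cov` (default 5) is *unevaluated*; otherwise the
site is *polymorphic* iff the dominant allele's frequency is below
`dominant_freq` (default 0.8). For a polymorphic site the effect is
determined by substituting the secondary allele into the codon formed
from the **dominant** alleles at the other two codon positions and
translating under the standard genetic code; when two sites of one codon
are polymorphic, each is classified holding the other at its dominant
allele — per-site semantics matching the referenced ad-hoc script.
Reverse-strand genes are complemented into coding orientation before
codon assembly. `dnds()` reports the **count ratio** of nonsynonymous to
synonymous polymorphic sites — deliberately *not* normalized by
synonymous/nonsynonymous site opportunity, again matching the method it
reimplements — with an explicit NA reason when no synonymous polymorphic
site exists. An exhaustive 64-codon × 3-position × 3-alternative
enumeration against an independent translation oracle backs the effect
classification.

A single strain profiled against its own reference has essentially no
polymorphic sites; unmasked heavy damage leaves a small polymorphic
floor, and protocol masking removes it (both shown in the test suite).
Strain mixtures inflate the polymorphic rate at exactly the
between-strain substitution sites, which is the multi-strain flag.

## The cross-reference experiment and its emulation

When reads are mapped with a mismatch-tolerant aligner against a
closely related but *incorrect* reference, conserved loci recruit reads
from homologous-but-not-orthologous regions of the source genome, and
the stacked alleles masquerade as polymorphism with an elevated,
deamination-independent dN/dS. This package contains no aligner, and its
synthetic genome pairs are collinear with substitutions only, so
single-source reads placed at their true coordinates can never produce a
polymorphic pileup. `cross_reference_experiment()` therefore emulates
the recruitment artifact explicitly: incorrect-reference cells build the
pileup from an equal mixture of source-genome and reference-genome reads
at homologous coordinates, placing the allele conflicts exactly at the
known substitution positions of the pair. What the emulation preserves:
the N/S spectrum of apparent polymorphisms at diverged sites, its
elevation above the correct-reference floor, and its independence from
deamination level. What it does not reproduce: the magnitude printed for
any particular trio of real genomes, which depends on real gene content,
real paralogy and real aligner behaviour — reproducing such a value
requires user-supplied assemblies, annotations and alignments, which the
dN/dS functions accept.

# Preservation decay curves

For one sample, taxa with nonzero abundance are ranked by decreasing
abundance (ties broken lexicographically by taxon id) and

$$\mathrm{curve}(k) = 100 \cdot \frac{|\{\text{oral taxa among the top }
k\}|}{k},$$

a percentage over taxon *counts*, not abundance mass. A sample passes
when the curve stays at or above the cutoff (default 50%) from the
burn-in rank onward.

The adaptive burn-in needs care. The cited idea — discard the unstable
head of the curve — does not come with a published criterion, and one
natural formalisation ("changes bounded by a multiple of the single-taxon
increment") turns out to be vacuous: the largest possible rank-to-rank
change of this curve is exactly $100/(k+1)$, attained when the taxon
entering at rank $k+1$ flips the count, so *every* curve satisfies any
bound of at least one single-taxon increment at every rank. We therefore
use a fixed stability tolerance: the burn-in rank is the smallest $r$
such that every subsequent rank-to-rank change is at most
`burn_in_tol` percentage points (default 10). This is deterministic,
testable, and excludes exactly the early ranks where single taxa still
swing the percentage wildly; a fixed-rank burn-in is available as the
alternative (`burn_in = <integer>`). The default tolerance was chosen
once from the curve's arithmetic — at rank 10 the largest possible step
is ~9 points, so instability beyond rank ~10 cannot be produced by a
single taxon — and is not tuned to any dataset.

# FAVA

Treating each sample's relative-abundance vector as an allele-frequency
vector, FAVA is the FST-style normalized variance

$$\mathrm{FAVA} = \frac{H_T - \bar H_S}{H_T}, \qquad
H_T = 1 - \sum_j \bar p_j^2, \qquad
H_S(i) = 1 - \sum_j p_{ij}^2,$$

with $\bar p$ the across-sample mean vector. It is 0 iff all samples have
identical composition (given $H_T > 0$) and 1 when every sample is
concentrated on its own taxon. We implement the **unweighted** form
(uniform sample weights, uniform taxon treatment); weighted variants
exist in the method's literature and are out of scope. Rows are closed to
relative abundances internally, so raw counts are accepted; zero-sum rows
are rejected. Two degenerate cases return an explicit reason instead of a
number: fewer than two samples (`"n<2"` — a singleton island cannot have
a variability) and $H_T = 0$ (all mass on one shared taxon, where the
ratio is 0/0). `fava_by_group()` adds the pooled all-samples value, the
baseline against which per-group values are read.

# Phylogenetics

**Calling.** `call_variants()` emits one call per position with depth ≥ 5
(major allele = max count, ties A<C<G<T); `filter_homozygous()` retains
calls with major frequency **strictly greater than** 0.9 (a frequency of
exactly 0.9 is removed), and is idempotent. `sample_qc()` applies the
inclusion rule — at least 1000 SNPs and mean genome-wide coverage at
least 2× or 5× depending on the taxon's heterozygosity profile, both
bounds inclusive — and names the failing criterion.

**Alignment.** `build_snp_alignment()` columns are the union of positions
where at least one sample carries a homozygous non-reference allele. A
sample's state is its homozygous allele where called, the reference base
where its call passes the same coverage and homozygosity thresholds and
agrees with the reference, and N otherwise. Requiring full call support
for the reference fill is the conservative reading of an
under-documented step; it converts low-coverage regions into N rather
than silently asserting identity with the reference.

**Distances.** TN93 (distinct purine/pyrimidine transition rates,
unequal base frequencies) is computed with `ape::dist.dna` under pairwise
deletion. The "+G4" label of the original model selection is
under-determined in a distance context, so the default is the
uncorrected closed form with an optional gamma shape (`gamma_alpha`).
Pairs with fewer than two shared informative columns, or whose closed
form saturates, return NA with a reason rather than a number.

On *SNP-only* columns the pairwise difference proportion is not the
genome divergence: it is inflated by a factor of roughly (alignment
columns)/(genome length), and when lineages at very different divergence
depths are mixed — e.g. two island clades split 10× deeper than the
within-island diversity — cross-clade pairs can differ at the majority of
columns and drive the TN93 logarithms past their singularities. For
distance-based trees the package therefore provides
`full_snp_alignment()`, which expands the SNP alignment to reference
length (reference base at every non-variant column). On synthetic data
the expansion is exact; on real data it asserts reference-identity at
non-variant positions, which is an approximation whose cost is shared
equally by all samples and leaves relative distances intact.

**Trees.** NJ via `ape::nj`; negative branch lengths — an NJ artefact on
noisy matrices — are clamped to zero with the deficit shifted to the
sister branch, preserving path lengths as closely as possible (this
matters because midpoint placement depends on path lengths). Midpoint
rooting via `phangorn::midpoint`. Bootstrap resamples alignment
**columns only** (no site-pattern weighting), rebuilds the NJ tree per
replicate, and reports bipartition support percentages on the full-data
tree; replicate distance matrices with undefined pairs are imputed at
the replicate's largest finite distance so the replicate still counts.
Trees with three or fewer tips have no internal bipartition and are
returned without support values.

**Concordance.** `concordance()` converts trees to cophenetic distances
and runs `ape::CADM.global` — Kendall's W over ranked upper-triangle
distance vectors with a permutation test (99 permutations by default, so
the smallest attainable p is 0.01).

# Determinism and problem sizes

Every randomized function takes a mandatory seed and restores the
caller's RNG state; pipelines rerun byte-identically under the same seed
and inputs. The test suite and acceptance script run entirely on
synthetic data at desk scale, chosen once as realistic for the questions
being asked: 100 kb genomes at ~30× for strain-identity comparisons
(where the popANI denominator needs ~10^5 compared positions for a
99.999% threshold to be meaningful), ~6× for the calibration sweep's
low-coverage regime, 20–30 kb annotated genomes for the dN/dS
experiments, and a two-island panel (founders at 0.2% divergence, four
samples per island at 0.02% within-island pair divergence, ~10×) for
end-to-end tree recovery.

# What the synthetic data does and does not show

The generator emulates: controlled genome divergence (substitutions
only), terminal deamination at UDG-class-dependent intensities, short
paired fragments with overlapping mates, strain mixtures, and abundance
tables with a controlled oral/contaminant split (Dirichlet-multinomial
within each compartment). It does **not** emulate: indels or
rearrangements, gene content differences and paralogy, sequencing error,
empirical damage-profile shapes, aligner behaviour (mapping bias,
multi-mapping, clipping), reference database incompleteness, or the
taxonomic-profiler noise upstream of real abundance tables. Passing
tests therefore demonstrate that the statistics and their thresholds
behave as designed under their own model assumptions — e.g. that popANI
at 30× with protocol masking cleanly separates identical strains from
0.1%-diverged ones — not that any particular real dataset will be free
of the artifacts listed above. The analyses that depend on those real
artifacts (notably the absolute dN/dS value of a specific
wrong-reference trio) are supported through user-supplied FASTA/GFF3/SAM
inputs instead of being simulated.
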