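---
title: "Methods: quantifying trade-offs between codon translation times and mRNA secondary structure"
author: "codontrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-structure trade-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codontrade)
```

## The question and the model

During elongation, a ribosome is slowed both by codons whose cognate
aminoacyl-tRNAs are scarce and by stable mRNA secondary structure that
must be unwound ahead of it.  If selection favours a smooth local
translation speed, the two brakes should not co-occur: stretches of
mRNA with strong secondary structure should be enriched in codons read
by abundant tRNAs (short translation times), and unstructured
stretches should tolerate slower codons.  `codontrade` quantifies this
trade-off genome-wide.

The model of elongation speed is deliberately minimal: the
instantaneous time spent on a codon is taken as proportional to the
inverse concentration of its cognate aa-tRNA pool, so each of the 61
sense codons carries a fixed translation time in arbitrary units
(a.u.), supplied as a `time_table`.  No queueing, wobble-modification
or initiation effects are modelled.

The pipeline is:

1. **Sequences** (`read_cds`, `trim_cds`): protein-coding sequences
   from FASTA or GenBank CDS features; records violating the reading
   frame or containing ambiguity codes are excluded (codon-time lookup
   and folding are undefined on ambiguous bases, and no masking rule
   is defensible).  The first and last 51 nt (17 codons) of every CDS
   are removed before analysis so that initiation- and
   termination-coupled codon bias cannot contaminate the signal.
2. **Structure** (`read_pars_scores`, `sliding_window_mfe`,
   `extract_regions`): a per-nucleotide structure track, either
   experimental PARS-style scores (high structure: score > 0; low:
   score <= 0) or the predicted minimum free energy (MFE) of a 101-nt
   centered sliding window (high: MFE < -35 kcal/mol; low: MFE > -20
   kcal/mol; the band in between is unclassified).  Maximal runs of
   uniformly classified nucleotides of at least `min_len_nt` (default
   20 nt, varied 10/20/30 in reports) become regions: isolated
   structured nucleotides cannot slow a ribosome, so a minimum extent
   is required.
3. **Speed** (`speed_profiles`, `smooth_profile`): per-codon
   translation times, optionally smoothed over a 27-nt (9-codon)
   centered window matching the ribosome footprint.  Smoothing serves
   trace inspection; region statistics use instantaneous times by
   default, since medians over whole regions already aggregate
   locally.
4. **Trade-off statistic** (`genome_tradeoff`): codons fully contained
   in a region are pooled by class across the genome;
   `delta_t = median(low pool) - median(high pool)` is positive when
   high-structure regions use faster codons.  Because the two sign
   conventions are easy to confuse, the complementary
   `tradeoff_score = -delta_t` (more negative = stronger trade-off) is
   carried alongside.  Distributions of codon times are far from
   Gaussian, so medians with interquartile ranges summarize them and a
   two-sided Mann-Whitney test compares the pools.
5. **Null models** (`null_distribution`): randomized genomes that keep
   each gene's codon multiset but destroy positional coupling, either
   preserving the protein (synonymous codon shuffling) or not
   (whole-codon shuffling).  Structure is re-predicted for every
   randomized genome with the same folding engine and thresholds, and
   the observed trade-off is compared against 100 replicate scores
   with a one-sample Wilcoxon signed-rank test.
6. **Expression** (`score_variant_library`): for a library of
   synonymous variants of one gene, the per-gene trade-off score is
   correlated (Pearson, with an ordinary least-squares slope) against
   measured absolute expression, with the codon adaptation index (CAI)
   computed as the classic geometric mean of relative adaptiveness
   weights for context.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| trim | 51 nt | terminal exclusion per CDS end (17 codons) |
| window_nt | 101 nt | MFE sliding window, value assigned to the center |
| high_cut / low_cut (MFE) | -35 / -20 kcal/mol | classification cut-offs |
| high_cut / low_cut (PARS) | 0 / 0 | score > 0 high, score <= 0 low |
| min_len_nt | 20 nt | minimum region length (reports sweep 10/20/30) |
| smoothing window | 27 nt | 9 codons, ribosome footprint |
| n_genomes | 100 | null-model replicates |

Window MFE is assigned to the center nucleotide and half-window ends
stay undefined: truncated windows would bias MFE towards zero and
manufacture "low structure" at gene ends.  A PARS score of exactly 0
classifies as low.  Quartiles use linear interpolation (R type 7);
IQR comparisons are qualitative, so the quartile convention is not
critical.

## Folding engines

Window MFE needs a folding engine.  `mfe_engine("vienna")` calls the
RNAfold program for thermodynamically realistic energies and is the
right choice for real genomes.  The default `mfe_engine("fallback")`
is a deterministic base-pair-maximization dynamic program (A-U, G-C,
G-U pairs, minimum hairpin loop 3 nt, implemented in C++) scoring
-1 kcal/mol per pair.  The scale was fixed from the pairing behaviour
of the algorithm itself: uniform-random 101-nt windows reach 32-40
pairs, so typical windows span the -35/-20 classification range,
pairing-poor (purine-only) windows score 0 and a designed 48-bp stem
scores exactly -48.  The fallback engine keeps simulations and the
test suite fast, deterministic and dependency-free; its absolute
energies are not thermodynamic and should not be interpreted as such.

## Rank tests

Region pools are routinely tied (61 distinct codon times), and
standard implementations fall back to approximations under ties.  The
package therefore implements both tests directly: for small samples
(`min(n, m) <= 8` and at most 2e5 assignments for Mann-Whitney, up to
12 non-zero differences for the signed-rank test) the null
distribution of the statistic is enumerated exactly with average-rank
tie handling, and the two-sided p-value is
`min(1, 2 * min(P(lower), P(upper)))`; larger samples use the normal
approximation with tie correction and continuity correction, which
matches `wilcox.test`'s approximation on tie-free data (cross-checked
in the tests).  Exact enumeration under ties is validated against
brute-force oracles in the test suite.

## The synthetic-genome generator

Real genome-scale inputs (complete genomes, experimental structure
maps, organism-specific codon-time tables) are large external data
sets, so validation rests on synthetic genomes with *planted* and
therefore exactly known structure-codon coupling
(`synthetic_spec`/`generate_genome`).  Genes alternate high/low
structural blocks (default 60 nt); amino acids are drawn uniformly;
within a high block each amino acid's codon is drawn with probability
`(1 - beta)/k` plus `beta` on the fastest synonymous codon, and low
blocks mirror towards the slowest.  `beta = 0` decouples codon choice
from structure, `beta = 1` makes it deterministic.  The packaged
codon-time table (`synthetic_time_table()`) is itself synthetic:
within each amino acid, synonymous codons span 25-125 a.u., while
"structure-extreme" codons (letters only G/C or only A/G) sit in a
60-100 a.u. mid-band so that planted structure and planted speed can
be varied independently.  The fast/slow ranking used by the generator
always comes from the active time table, so ground truth and analysis
share one source.

Two structure channels exist.  The default PARS channel emits noisy
per-nucleotide scores (block mean +1 or -1, Gaussian noise, default
sd 0.3) decoupled from sequence content, so the planted effect is
analytically computable: `expected_delta_t()` evaluates the population
medians of the high- and low-class codon-time mixtures exactly from
their finite support.  The recovery properties checked in the
acceptance suite (200 genes of 300 codons per beta point) compare the
genome-wide estimate with this analytic value within three bootstrap
standard errors.

The MFE channel writes structure into the sequence so the folding
pipeline itself can be exercised end to end: 75% of codons are
"skeleton" positions (high blocks: GCC/GCG/CCC/CCG/GGC/GGG, which
pair strongly; low blocks: AAA/AAG/GAA/GAG/AGA/AGG, which contain no
pyrimidines and barely pair), and the remaining 25% are shared amino
acids carrying the beta coupling.  Blocks are 150 nt so that 101-nt
windows fit inside them.  For this composition the pooled-codon
median is pinned to the few discrete skeleton time values and cannot
respond smoothly to the planted coupling, so the null-model contrast
uses `pool = "region"`: the medians of per-region mean times, the
same summary used when comparing region-level distributions.  Region
means respond continuously to codon-level changes, and synonymous
shuffling (which preserves the amino-acid skeleton and hence the
structure blocks, while scattering fast/slow synonymous choices
across blocks) collapses the observed score towards zero.  Whole-codon
shuffling instead destroys the amino-acid blocks themselves; the
resulting uniform-composition windows fall into the unclassified
-35..-20 band and such replicates typically have *no* classifiable
regions at all - their scores are recorded as `NA` and reported as
such, which is itself the strongest possible statement that amino-acid
placement carries the structure signal in this design.

What the generator does *not* emulate: real codon-usage bias, GC
landscapes, gene-length distributions, thermodynamic folding
energies, or tRNA modification effects.  Passing the synthetic suite
demonstrates that the statistical machinery recovers known coupling
through the full pipeline; it does not certify organism-specific
conclusions, which additionally depend on the quality of the
codon-time table and structure data supplied by the user.

## Study sizes and numerical choices

Simulation sizes are chosen so the full validation runs on a laptop
in about a minute: 200 genes x 300 codons for recovery of the planted
delta_t (about 60,000 pooled codons, at which point the sample median
sits on the population median's support point); 10 genes x 150 codons
x 100 replicate genomes for the null model (about 3,500 folded
windows per genome); 30 variants of a 300-codon protein for the
expression analysis.  Degenerate inputs are handled explicitly:
empty region classes yield `NA` results carrying their counts rather
than errors; an all-tied signed-rank test signals a condition of class
`degenerate_test`; zero variance in an expression correlate is an
error rather than a silent `NA`.  Genes are always processed in
sorted-id order from a single seeded RNG, so every randomized analysis
is reproducible and independent of input order.

## Known limitations

* The fallback engine maximizes pair counts; it ranks structure
  plausibly but its energies are not thermodynamic.  Use the RNAfold
  backend for real analyses.
* Codon-region assignment requires full containment of all three
  nucleotides (a `majority` mode is available); boundary codons are
  deliberately left unassigned.
* No multiple-testing correction is applied across region-length
  cut-offs, and no GO/functional enrichment is included.
* Initiation-rate prediction and ribosome-profiling comparisons are
  out of scope.
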