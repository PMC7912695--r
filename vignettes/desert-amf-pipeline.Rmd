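---
title: "Profiling desert AM fungal communities: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling desert AM fungal communities: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`desertam` implements a closed-reference amplicon pipeline for arbuscular
mycorrhizal (AM) fungal communities — from raw paired SSU rRNA reads to
per-site diversity, phylogenetic community structure, and randomization
tests of desert-habitat affiliation — together with a seeded synthetic-data
generator that stands in for raw sequencing data and for a
MaarjAM-style reference catalogue of virtual taxa (VT). This vignette
documents the statistical model behind each stage, the tunable parameters
and why their defaults are what they are, and the design decisions taken
where more than one defensible choice existed.

## 1. Read processing

Raw paired reads pass three gates, in a fixed order so that every read pair
is counted in exactly one failure category and per-site counts always sum
to the input count:

1. **Primer matching.** Primers are anchored at the 5′ terminus of each
   mate (amplicon primers are terminal by construction; no internal search
   is attempted). IUPAC degeneracy codes in the primer match any of their
   expansions; an `N` in the *read* matches nothing. A pair is rejected if
   either mate exceeds `max_mismatch` (default 1) mismatches in the
   primer-length window. The per-position mask test is exactly equivalent
   to minimising Hamming distance over all concrete primer expansions,
   which the test suite verifies by brute-force enumeration.
2. **Quality filtering.** A pair is kept iff the *arithmetic mean* Phred
   score of both mates is ≥ `min_mean_q` (default 30, inclusive). The mean
   is taken over raw Phred integers, not error probabilities: "average
   quality score" is interpreted literally.
3. **Merging.** The reverse mate is reverse-complemented and candidate
   overlap lengths in `[min_overlap, max_overlap]` (default 10–300 bp) are
   scanned exhaustively. Overlap identity is matching bases over overlap
   length, with `N` matching nothing. The highest-identity overlap with
   identity ≥ `min_identity` (default 0.75) wins; among equal-identity
   candidates the **longest** overlap is preferred (a deliberate tie rule:
   a short spurious perfect overlap should not beat the true overlap
   carrying one sequencing error — and for error-free data the true
   overlap always has identity 1 and maximal length). Consensus bases in
   the overlap take the mate with the higher Phred score, ties going to
   the forward mate.

Chimera screening is out of scope (it is delegated to external tools in
practice); `drop_chimeras()` removes reads listed in an externally
produced id file.

## 2. Virtual-taxon assignment

Merged reads are assigned to VT by best hit against the catalogue's type
sequences, at ≥ 97% identity and ≥ 95% coverage. Design choices a BLAST
user would otherwise make implicitly:

* **Aligner.** A native Smith–Waterman local aligner (in C++), not an
  external BLAST binary: reference sets at this scale (tens to hundreds of
  VT) need no heuristic seeding and an external dependency would hurt
  reproducibility. Scoring is match +1, mismatch −1, and an affine gap of
  length *L* costs *L*+1. The test suite cross-checks optimal scores
  against `Biostrings::pairwiseAlignment` under the same scheme.
* **Identity** is matching bases / alignment columns, gap columns included
  in the denominator. **Coverage** is aligned read positions / read
  length: the 95% length threshold is taken relative to the *read* (query),
  the more conservative reading for partial reads.
* **Strand.** Both the read and its reverse complement are considered,
  since merged-read orientation depends on library layout.
* **Prescreen.** By default each read is aligned only against the
  `prescreen_top = 2` references sharing the most 6-mers with it (the
  prescreen also picks the strand; exact ties align both strands).
  Closed-reference assigners (BLAST, vsearch) all seed heuristically; with
  references ≥ 6% divergent and a 97% identity threshold the true best hit
  shares overwhelmingly more 6-mers than any other reference, so the
  prescreen returns the same best passing hit as the exhaustive scan —
  which remains available (`prescreen_top = Inf`) and is what the contract
  tests exercise. Best-hit ties break by higher coverage, then
  lexicographically smallest VT id, making assignment independent of
  reference order.

Dataset-level singletons (VT with exactly one read in the whole dataset)
are removed before any downstream analysis, mirroring standard practice
for rare-artifact suppression. `cultured_fraction()` reports the share of
retained VT flagged as cultured (containing sequences of known
morphospecies identity).

## 3. Diversity

Within-site diversity uses Hill numbers (effective numbers of species) of
order *q* = 0, 1, 2. Sampling-depth differences between sites are handled
two ways:

* **Rarefaction** uses the exact hypergeometric expectation
  $E[S_m] = \sum_i 1 - \binom{n - n_i}{m} / \binom{n}{m}$ (via
  `vegan::rarefy`), verified against a 100,000-draw resampling oracle.
* **Asymptotic extrapolation**: Chao1 for richness
  ($S_{obs} + f_1^2 / 2 f_2$, bias-corrected
  $S_{obs} + f_1 (f_1 - 1) / (2 (f_2 + 1))$ when $f_2 = 0$), and the
  Chao–Jost asymptotic estimators of Shannon and Simpson effective numbers
  (the entropy estimator with the `(1-A)` rare-species correction for
  q = 1; the minimum-variance unbiased estimator of $\sum p_i^2$ for
  q = 2). The classic Chao1 form is used, without the $(n-1)/n$
  small-sample factor. Uncertainty is a multinomial bootstrap
  (default `B = 200` resamples) with normal-approximation 95% limits; for
  q = 0 the lower limit is floored at the observed richness.

The Shannon and Simpson table entries are effective numbers (Hill-number
convention), i.e. the exponential of Shannon entropy and the inverse
Simpson concentration, so all three orders share a common unit and are
monotone non-increasing in *q*.

## 4. Phylogenetic community structure

Type sequences arrive **pre-aligned** (multiple sequence alignment is out
of scope; the generator emits substitution-only evolution, so synthetic
sequences are aligned by construction). Distances are Jukes–Cantor
($-\tfrac34 \log(1 - \tfrac43 p)$ over ungapped column pairs; saturated
pairs with $p \ge 0.75$ are capped at a finite value, default 5
substitutions/site, rather than returned infinite). The tree is
Saitou–Nei neighbor joining (`ape::nj`); negative branch lengths — which
NJ can produce on non-additive inputs — are clamped to zero with the
deficit transferred to the sister edge. On additive matrices the
patristic distances reproduce the input exactly (tested on random 4–12
taxon trees to 1e-9).

Community structure statistics are presence–absence weighted: `mpd_obs()`
(mean patristic distance over within-sample pairs; fewer than two taxa
yields `NA`, not zero), `comdist_pair()` (mean over cross-sample pairs),
and `ses_mpd()`, whose null draws are uniform random subsets of a
configurable taxon pool, of the observed sample's size, without
replacement. $Z = (\text{obs} - \bar{x}_{null}) / s_{null}$ with the
sample SD over the `n_reps = 999` null values (denominator
`n_reps − 1`; the observed value is *not* appended as a 1000th null
value). A null SD of zero (e.g. sample = pool) flags the result
degenerate instead of producing an infinite Z.

## 5. Ordination

Jaccard dissimilarity on presence–absence feeds principal coordinates
analysis (Gower double-centring; negative eigenvalues are reported, not
corrected), and the between-sample phylogenetic distance matrix
(`comdist_matrix()`) feeds non-metric multidimensional scaling
(`vegan::metaMDS`/`monoMDS`: Kruskal stress-1 with monotone regression,
best of `n_starts` random starts plus a metric start). Both ordinations
accept either matrix. Environmental vectors are fitted by least squares
(`vegan::envfit`) with permutation p-values under the add-one convention
$(1 + \#\{r^2_{perm} \ge r^2_{obs}\}) / (n_{perm} + 1)$; constant
variables get $r^2 = 0$, $p = 1$ rather than an error.

## 6. Habitat affiliation

The per-VT **aridity index** is the fraction of its database records
labelled "deserts and xeric shrublands" (a VT with zero records has an
undefined index and is excluded from community means). The
**community aridity** of a sample is the unweighted mean over member VT
with defined indices. The randomization test draws `n_reps = 999` uniform
subsets (without replacement, unweighted by record counts — the plain
reading of "randomly selecting n VT") of the scale-specific pool, each of
the observed sample's size, and compares by the same Z rule as above,
two-sided at |Z| > 1.96. Three design points deserve emphasis:

* Member VT absent from a sub-global pool still contribute to the
  *observed* mean; the pool only shapes the *null*. A community can thus
  legitimately be compared against a narrower pool than it was drawn from.
* Over-representation counts (`count_significant()`) use the one-sided
  rule Z > z_crit, strict at the boundary, while the stored `significant`
  flag stays two-sided.
* Multi-scale runs produce one result per site × scale
  (global / continent / realm), and `z_table()` lays them out as the
  familiar scales × sites Z matrix.

## 7. The synthetic-data generator

`simulation_config()` fixes the study conditions the pipeline is exercised
under; the defaults are deliberate and are not adjusted per test:

| parameter | default | rationale |
|---|---|---|
| `n_vt` | 50 | catalogue size of the order observed in desert surveys |
| `site_names` / `site_richness` | ARG, AUS, ISR, KAZ, SAU, USA with 13, 17, 36, 13, 3, 4 VT | the six desert sites and their observed richness values |
| `reads_per_site` | 5,000 | desk-scale sequencing depth |
| `seq_length` / `read_length` | 250 / 170 bp | keeps a realistic paired-read geometry (48 bp overlap after primer trimming) at desk scale |
| `read_error_rate` | 0.01/bp | ~3 errors per merged read: inside the 97% identity budget but enough to exercise every filter |
| `quality_mean`, `quality_sd` | 35, 3 | typical good-run Phred profile |
| `affiliation_beta` | 8 | see power note below |
| `desert_fraction_range` | [0, 0.6] | spreads per-VT aridity indices widely |
| `cultured_prob` | 0.42 | the survey's observed cultured share |
| `min_pendant` | 0.03 subs/site | floors pairwise reference divergence near 6%, the identifiability regime for 97%-identity closed-reference assignment |

The reference phylogeny is a Yule tree (`ape::rphylo`, death rate 0)
rescaled to root-to-tip height `mutation_scale` (0.15 substitutions/site)
with `min_pendant` added to every terminal branch; sequences evolve along
it under JC69 (`phangorn::simSeq`) with **no indels**, so type sequences
stay aligned and multiple sequence alignment stays out of scope.
Communities draw their members without replacement with weight
$\exp(\beta \cdot \text{aridity})$; in `clade` mode each site's candidate
pool is restricted to the *smallest* clade of the reference tree that can
host it (the tightest monophyletic restriction, so clustering is planted
at every site regardless of richness). Member read counts are log-normal,
scaled to `reads_per_site` and floored at 2 reads so every planted member
is observable after singleton filtering. Reads are windows of
`primer + type sequence + revcomp(primer)` with per-base substitution
errors and, optionally, planted defect fractions (corrupted primer,
low-quality mate, unmergeable mate) recorded in the ground truth.

**Power note.** `affiliation_beta = 8` comes from a design-time
calculation, not from tuning against test outcomes: with ~50 pool VT and
aridity indices spread over [0, 0.6] (SD ≈ 0.17), a sample of n ≈ 13 has
null SE ≈ 0.17/√13 · √((50−13)/49) ≈ 0.04, while β = 8 shifts the
selected-member mean by ≈ 0.15–0.2, i.e. an expected Z of 3.5–5 — enough
for > 90% power at the 1.96 threshold at the study's mid-range richness.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: quality-dependent Illumina miscall spectra
(errors are uniform substitutions, qualities independent of errors),
indels, chimeras, PCR abundance bias, intragenomic rRNA variation, and a
reference catalogue with the real MaarjAM's uneven record counts and
phylogenetic depth. Recovery rates on synthetic data are therefore an
upper bound on real-data behaviour.

## 8. Numerical and reproducibility choices

* Every stochastic routine takes a `seed`; `run_pipeline()` derives
  per-stage seeds from one global seed by hashing the stage name
  (`derive_seed()`), so a stage rerun standalone reproduces its in-pipeline
  results, and two full runs under one seed produce byte-identical
  manifests (md5-checksummed TSV/FASTA/Newick artifacts).
* NMDS convergence: relative stress change < 1e-6 within monoMDS's
  iteration cap; non-convergence returns the best configuration with a
  warning flag. A two-sample ordination is handled analytically
  (stress 0).
* Degenerate inputs return flagged results, not errors, wherever a
  downstream consumer can meaningfully continue (degenerate nulls,
  undefined aridity indices, `NA` mpd for singleton samples); hard errors
  are reserved for contract violations (unknown taxa, empty pools,
  mismatched FASTQ mates — reported with both file names).
* Problem sizes in the shipped tests: unit tests run on 12–40 VT,
  two-site configurations with 100–150 reads/site; the end-to-end,
  calibration (1,000 replicates), and power (200 replicates) checks run at
  the full default conditions above. These sizes are the package's own
  statistical design: large enough for the stated error rates, small
  enough to iterate on.

## 9. Known limitations

* Closed-reference only: reads from taxa absent from the catalogue are
  reported unassigned, never clustered de novo.
* The aridity index inherits the reference catalogue's record biases;
  record-weighted null draws were considered and rejected as unsupported
  by the method's plain description.
* Neighbor joining is distance-based; likelihood or Bayesian trees are out
  of scope, as are abundance-weighted mpd variants and MNTD.
* The merging consensus ignores quality recalibration; merged reads carry
  no quality strings downstream (assignment does not use them).
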