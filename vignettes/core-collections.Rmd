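---
title: "Building core collections from SSR and metabolite data with corekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building core collections from SSR and metabolite data with corekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corekit)
```

## The problem

A germplasm collection of a medicinal plant is expensive to maintain and to
phenotype. A *core collection* is a small subset of accessions chosen so
that the genetic diversity of the whole panel — and, for a medicinal crop,
its content of active compounds — is preserved as far as possible.
`corekit` implements this workflow for panels typed at codominant
microsatellite (SSR) loci and assayed for metabolite concentrations (here:
six coumarins of dried *Angelica* roots, in mg/g):

1. per-locus genetic diversity statistics,
2. genetic structure (UPGMA clustering, PCoA, AMOVA with Phi-statistics),
3. nested candidate cores by least-distance stepwise sampling (LDSS) with
   a metabolite-content deletion rule, and
4. quality evaluation of a candidate core against the full panel.

A Balding–Nichols simulator generates panels with the same statistical
shape as a real survey, so the whole pipeline runs and is testable without
any external data. A MISA-style SSR miner for transcript sequences is
included for the marker-development side of such projects.

## Data model

`genotype_matrix()` stores, per accession and locus, an unordered pair of
allele labels (amplified fragment sizes in bp, positive integers). A call
is either fully observed or fully missing; half-missing calls are rejected
because they leave allele dosage undefined. Allele labels are compared as
integers exactly as given — no binning or size correction is applied, that
is the job of the upstream fragment-analysis software. Missing data on
disk follow the GenAlEx convention (`0`).

`metabolite_table()` holds non-negative concentrations with no missing
values: every accession entering the LDSS rule needs a defined total
score, and imputing concentrations would silently bias the deletion order.

## Diversity statistics

For a locus with allele frequencies $p_i$ estimated by gene counting over
the $N$ accessions typed at that locus (missing calls are dropped locus by
locus — pairwise deletion, the POPGENE convention, since nothing in the
data supports imputation):

* $N_a$ — observed allele count; $N_e = 1/\sum p_i^2$ — effective allele
  number;
* $H_o$ — observed heterozygote fraction;
* $H = 1 - \sum p_i^2$ — Nei's gene diversity (plug-in);
* $H_e = \frac{2N}{2N-1} H$ — unbiased expected heterozygosity (Levene);
* $I = -\sum p_i \ln p_i$ — Shannon's information index;
* $PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ — Botstein's
  polymorphism information content.

Reporting both $H$ and $H_e$ is deliberate: legacy population-genetics
software prints both, and on a large panel they differ only in the second
decimal, which is exactly the behaviour users of those tools expect.
Means across loci are unweighted — a locus with fewer typed accessions
counts the same as a fully typed one.

The allele retention rate of a subset is
$R_a = 100 \cdot \bar{N_a}(\text{subset}) / \bar{N_a}(\text{full})$,
computed on unrounded means and printed to two decimals. $R_a$ is the
primary criterion for accepting a candidate core.

```{r}
g <- generate_panel(paper_like_config(seed = 1))$genotypes
diversity_summary(g)
```

## Distances, clustering, ordination

Codominant calls are first collapsed to a binary band matrix (one column
per distinct allele per locus; dosage is not distinguished). Two distances
are offered:

* **simple matching** — mismatching columns over mutually known columns,
  counting shared absences as matches; the classical NTSYS input for
  UPGMA on marker bands;
* **band squared-Euclidean** (default) — the squared Euclidean distance
  between band vectors, rescaled by total/known columns under missingness.
  This is the GenAlEx-style individual distance for codominant data
  exported as bands, and it is the default input for PCoA, AMOVA and LDSS.

At the level of individuals, "Nei's genetic distance" is not uniquely
defined, so the package does not pretend to compute it; the band
squared-Euclidean distance is the documented stand-in, with simple
matching selectable everywhere. On complete data the two are proportional,
so UPGMA topologies and Phi-statistics agree between them.

`upgma()` merges the minimum-distance pair at height $d/2$ with
size-weighted average linkage. Ties are resolved toward the lowest (row,
column) index pair, which makes every result — including the Newick
export — deterministic. The Newick branch lengths are height differences,
so trees are exactly ultrametric.

`pcoa()` double-centres $-\tfrac12 d^2$ (Gower), reports all eigenvalues,
and computes percent variance over the positive eigenvalues only; negative
eigenvalues (non-Euclidean inputs) are reported, not hidden. For distances
stored already squared (the band distance) the matrix itself is centred,
not its square.

`amova()` is the one-level Excoffier partition of squared distances with
the standard unequal-size coefficient $n_0$; negative variance-component
estimates are clamped to zero with a warning, and
$\Phi_{PT} = \sigma^2_{among}/(\sigma^2_{among}+\sigma^2_{within})$.
The permutation p-value shuffles population labels under a fixed seed and
uses the $(1 + \#\{ \Phi^* \ge \Phi \})/(1+B)$ estimator. Within-individual
components ($\Phi_{IS}$) are out of scope: the analyses this package
supports report only among/within population structure.

## LDSS core construction

The sampler repeats two moves until the smallest target size is reached:

1. find the globally closest pair among retained accessions — this is
   precisely the first merge a fresh UPGMA run would make, so "repeated
   clustering" reduces to masking the distance matrix, with no
   recomputation;
2. delete the member of that pair with the lower total metabolite score
   (unweighted sum over compounds by default; weights are configurable).

Removing an accession never changes the distances among the survivors, so
checkpoints taken at a ladder of target sizes are nested by construction.
Tie rules are explicit — lowest (row, column) pair for equal distances,
remove the lexicographically larger id for equal scores — so the removal
log is reproducible to the byte.

Target sizes default to half-up rounding of $n \times$ ratio
(`target_size(208, 0.20)` is 42). Published ladders do not always follow a
single rounding rule (a 30% rung of 63 out of 208 is consistent with
ceiling but not with half-up, while 83 at 40% is the opposite), so
`ldss_sample(sizes = )` accepts explicit sizes to reproduce any ladder
verbatim.

`select_core()` codifies the published trade-off "mainly genetic
diversity, supplemented by metabolite content": among rungs with
$R_a \ge 90\%$, take the smallest; break ties by the higher
total-metabolite mean. The threshold is a parameter, not a constant.

## Evaluation

`evaluate_core()` compares original, core and removed sets on all seven
statistics, computes retention percentages, and tests $N_e$, $H$ and $I$
with a *paired* t-test across loci. Pairing is a deliberate choice: core
and original share the same loci, and per-locus diversity varies far more
between loci than between nested accession sets, so an unpaired test would
be badly miscalibrated. No multiple-testing correction is applied across
the three parameters, matching the practice this workflow mirrors. The
PCoA overlay projects the full panel once and flags core members; the core
is never re-ordinated alone, because the question is how the core sits
inside the original cloud.

`random_baseline()` gives the null reference: the distribution of $R_a$
over uniformly random subsets of the same size. A useful directed sampler
must beat its mean.

## The synthetic generator

`paper_like_config()` encodes the study conditions the package is tested
under: three populations of 70/69/69 accessions, 17 SSR loci with 4–15
alleles drawn per locus, weak differentiation, a 1% missing-call rate, and
six log-normal coumarins whose means differ by population (the first two
populations are columbianadin-rich, the third osthole-rich; concentrations
are truncated at 20 mg/g, a simple and documented bias that avoids
re-drawing extremes).

Differentiation uses the Balding–Nichols model: population frequencies
are Dirichlet$\big(p \cdot (1-F)/F\big)$ around ancestral frequencies
$p \sim$ Dirichlet(1). $F$ is the single interpretable knob. On band
distances the realised among-population variance fraction reads higher
than the nominal $F$ (collapsing dosage to presence/absence discards
within-individual variation), so the default $F = 0.035$ was calibrated
once by replicate simulation to put the realised AMOVA among-population
component at about 6% — the weak-structure regime of interest — where it
stays within roughly 2–12% across seeds. Genotypes are drawn in
Hardy–Weinberg proportions within populations; all randomness flows
through one seed, so a config reproduces its panel bit for bit.

What the generator does **not** emulate: SSR mutation processes (no
stepwise mutation model — allele labels are arbitrary sizes), linkage
between loci, genotyping artefacts (stutter, null alleles, allelic
dropout), and spatial/migration structure beyond the island-style drift
model. Passing tests on synthetic panels therefore demonstrate the
correctness and behaviour of the algorithms under the stated statistical
shape, not robustness to laboratory error.

## Numerical and testing choices

* Frequencies sum to 1 within 1e−12 by construction; oracle tests compare
  statistics against brute-force enumeration at 1e−12.
* UPGMA is checked against a naive recomputation oracle (and `hclust`)
  on random matrices up to n = 12, including tie cases.
* PCoA round-trips Euclidean configurations to 1e−9 and agrees with
  `cmdscale`.
* AMOVA sums of squares are checked against direct double summation.
* Full-pipeline tests run on a 208-accession panel (the study scale);
  property suites use 10–60 accessions and 200 random-baseline
  replicates, sizes chosen to exercise every code path while keeping the
  default test run fast.

## Limitations

* The pairwise-deletion policy and the Levene correction are conventions;
  other software may print slightly different $H_e$ on missing-data-heavy
  panels.
* $\Phi_{PT}$ on band data is not the Weir–Cockerham $F_{st}$; the two
  differ systematically, which is why the simulator's $F$ is calibrated
  rather than passed through.
* LDSS is greedy: it makes no claim of optimality against
  maximisation-style core samplers, which are out of scope here.
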