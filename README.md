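# corekit

Construction and evaluation of germplasm **core collections** from
codominant microsatellite (SSR) genotypes and per-accession metabolite
profiles.

Medicinal-plant collections — the motivating case is wild *Angelica*
germplasm assayed for six root coumarins — are conserved and bred from a
small representative subset of accessions. `corekit` implements the full
workflow for choosing that subset:

* **Diversity statistics** per locus and averaged: allele count *Na*,
  effective allele number *Ne* = 1/Σp², observed heterozygosity *Ho*,
  Nei's gene diversity *H* = 1 − Σp², unbiased expected heterozygosity
  *He* = 2N/(2N−1)·*H*, Shannon's index *I* = −Σp·ln p, and Botstein's
  *PIC* = 1 − Σp² − Σᵢ<ⱼ2pᵢ²pⱼ²; plus the allele retention rate
  *Ra* = 100·meanNa(subset)/meanNa(full) of any candidate subset.
* **Genetic structure**: simple-matching and band squared-Euclidean
  distances from allele incidence ("band") vectors, deterministic UPGMA
  with Newick export, principal coordinates analysis, one-level AMOVA
  with Φ\_PT and permutation tests, and pairwise population Φ\_PT.
* **LDSS core sampling** (least-distance stepwise sampling): repeatedly
  find the closest pair of retained accessions and delete the member with
  the lower total metabolite content, checkpointing nested cores at a
  ladder of sampling ratios; `select_core()` picks the smallest rung
  retaining ≥ 90% of the alleles, ties broken by metabolite content.
* **Evaluation**: retention percentages, paired t-tests across loci for
  *Ne*, *H*, *I*, metabolite means per set, PCoA overlay of the core on
  the full panel, and a random-subset baseline.
* **SSR mining**: MISA-style detection of perfect and compound
  microsatellites in transcript FASTA (minimum repeats 10/6/5/5/5/5 for
  mono- through hexanucleotide motifs), with strand/phase canonical motif
  classes and summary statistics.
* **Synthetic germplasm**: a Balding–Nichols simulator producing
  multi-population SSR panels with calibrated weak differentiation and
  population-structured log-normal coumarin profiles, so the entire
  pipeline is testable without external data.

## Worked example

Simulate a study-shaped panel (3 populations of 70/69/69 accessions, 17
SSR loci), summarise its diversity, test its structure, build the LDSS
ladder and evaluate the selected core:

```r
library(corekit)
panel <- generate_panel(paper_like_config(seed = 1))
diversity_summary(panel$genotypes)
#> diversity_summary: 17 loci, 208 accessions, 161 alleles
#>    Na    Ne    Ho    He     I     H   PIC
#> 9.471 5.390 0.760 0.769 1.784 0.767 0.742

d <- genetic_distance(panel$genotypes)
amova(d, panel$populations, n_permutations = 199, seed = 2)
#>              source  df        SS       MS
#>   Among populations   2  187.9953 93.99765
#>  Within populations 205 3864.8710 18.85303
#>               Total 207 4052.8663       NA
#> PhiPT = 0.0544 (among 5.4%, within 94.6%); P = 0.005 (199 permutations)
```

Only ~5% of the molecular variance lies among populations — the
weak-differentiation regime in which a single core can represent all
sampling sites. The LDSS ladder then trades panel size against allele
retention *Ra* and coumarin content:

```r
lad <- ldss_ladder(panel$genotypes, panel$metabolites, d = d)
lad$table[, c("name", "size", "Na", "He", "PIC", "Ra", "total_coumarin")]
#>       name size   Na    He   PIC    Ra total_coumarin
#> 1 original  208 9.47 0.769 0.742 100.0           5.32
#> 2     40CC   83 9.24 0.795 0.767  97.5           6.47
#> 3     35CC   73 9.24 0.798 0.769  97.5           6.46
#> 4     30CC   62 9.18 0.801 0.771  96.9           6.65
#> 5     25CC   52 9.18 0.804 0.772  96.9           6.84
#> 6     20CC   42 9.00 0.807 0.772  95.0           7.06
#> 7     15CC   31 8.88 0.804 0.767  93.8           7.79
#> 8     10CC   21 8.12 0.810 0.764  85.7           7.80

select_core(lad)   # smallest rung with Ra >= 90, ties by coumarin mean
#> [1] "15CC"

evaluate_core(lad$core$checkpoints[["15CC"]], panel$genotypes,
              panel$metabolites, panel$populations, d = d)
#> evaluation_report: core 31 vs original 208 accessions
#>  parameter original  core removed retention_percent
#>         Na    9.471 8.882   9.353            93.789
#>         Ne    5.390 5.968   5.208           110.716
#>         Ho    0.760 0.804   0.752           105.791
#>         He    0.769 0.804   0.761           104.626
#>          I    1.784 1.846   1.759           103.452
#>          H    0.767 0.791   0.759           103.161
#>        PIC    0.742 0.767   0.734           103.380
#> paired t-tests (core vs original):
#>  parameter     t      p
#>         Ne 3.862 0.0014
#>          H 3.138 0.0063
#>          I 3.312 0.0044
```

Every statistic except *Na* is *higher* in the core than in the original
panel (retention > 100%): deleting near-duplicates concentrates
diversity, while the mean total coumarin content rises from 5.32 to
7.79 mg/g because the deletion rule always discards the lower-scoring
member of the closest pair. `run_pipeline(out_dir, seed = 1)` chains all
of the above and writes every stage output plus a manifest of md5 digests
for reproducibility; `read_genotypes()` / `read_metabolites()` ingest
GenAlEx-style CSV, simple TSV and metabolite CSV for real panels.

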