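# epiensemble

Comparative analysis of a chromatin-modifier ("epigenetic") gene ensemble
across related genomes, packaged as a tested R pipeline.

## The problem

Chromatin-modifier genes — acetyltransferases and deacetylases, histone
methylases and demethylases, remodeling-complex components, heterochromatin
proteins — form a compact gene ensemble whose evolution can be tracked
across species. For a reference ensemble defined in one well-annotated
genome (a *Drosophila*-like reference of 215 genes in the bundled
fixtures), the questions this package answers are:

* Which ensemble genes have orthologs in a second species, and how
  confident are the calls? Orthology is called by **modified reciprocal
  best hit (MRBB)** search plus two external ortholog-database call
  tables, combined under a **2-of-3 consensus rule**: a call stands only
  when at least two of the three methods name the *same* target gene.
* Which gene families have **expanded or contracted** across a panel of
  related genomes, relative to the reference species? Apparent expansions
  whose extra copies map to unplaced assembly contigs (the `UNKN`
  "chromosome") are filtered as potential assembly artifacts, and
  intronless duplicates of multi-exon genes are flagged as **retrocopies**
  (retrotransposed duplicates).
* How fast is the ensemble evolving? Pairwise **dN/dS (ω)** is estimated
  with the Nei–Gojobori (NG86) counting method — synonymous and
  nonsynonymous sites counted per codon, differences averaged over
  stop-avoiding mutational paths, Jukes–Cantor corrected — with the
  standard exclusion filters (dS > 1 saturated, dS = 0 uninformative).
  Group rates are compared with a Welch t-test.
* Are **expression programs** conserved? Gene-by-stage matrices are
  clustered into high/low expression classes (1 − Pearson r distance,
  complete linkage, two-cluster cut) and class membership is compared
  across species over the ortholog map; tissue profiles are compared by
  reference-gene-normalized PCA and per-tissue fold-change ANOVA.

Because the original genome-scale inputs are not redistributable, the
package ships a **synthetic-data generator** (`simulate_families()`,
`simulate_expression()`) that simulates multi-species gene families with
planted duplication/loss/retrotransposition events, codon sequences
evolved at a chosen ω, and two-class expression profiles — with full
ground truth, so every stage is tested by parameter recovery. The printed
summary tables of the source study are transcribed as fixtures
(`make_table_fixtures()`).

## Worked example

Consensus calling and family dynamics on the bundled fixtures:

```r
library(epiensemble)

fx <- make_table_fixtures()
catalog <- call_consensus(fx$evidence, min_support = 2)
support_distribution(catalog)
#>   3   2   1   0
#> 146  23  10  36
conservation_rate(catalog)$percent_rounded
#> [1] 79

ev <- detect_events(fx$copy_table)
c(ev$n_event_families, ev$n_expansion_families, ev$n_contraction_families)
#> [1] 7 4 3

conservation_stats(fx$copy_table, 169)
#> 1:1 copy-number conservation over 169 families
#>      A. epiroticus       A. stephensi        A. funestus      A. arabiensis
#>               99.4               99.4               98.8              100.0
#>       A. albimanus           A. dirus         A. minimus A. quadriannulatus
#>               98.2               98.2               98.8              100.0
#>      A. atroparvus           A. merus         A. farauti
#>               97.6               99.4               98.8
#> min 97.6%, mean 99.0%
```

Reading the output: of the 215 reference-ensemble genes, 146 get the same
ortholog from all three methods, 23 from exactly two, 10 from one (no
consensus), and 36 from none — 169 consensus orthologs, a 79%
conservation rate. Across the 12-species panel, seven families show
copy-number events (4 expansions, 3 contractions); per-species 1:1
conservation over the 169 ensemble families ranges from 97.6% to 100%.

An end-to-end run on synthetic genomes (search → MRBB → family dynamics →
rates → expression) with a machine-readable report:

```r
report <- run_pipeline(list(
  mode = "simulation",
  simulation = list(n_families = 20, dup_rate = 0.5, retro_rate = 0.5),
  seed = 7))
report$families$n_event_families
report$rates$comparison$p_value
```

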