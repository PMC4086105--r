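# evocor

Functional-linkage prediction from phylogenetic profiles refined by
co-expression.

## The problem

Most genes are studied one at a time, but cellular processes are run by
groups of genes.  Two genome-scale signals betray such groups without any
prior functional knowledge:

* **co-evolution** — genes working in the same process are kept or lost
  together across species, so their *phyletic profiles* (binary
  presence/absence vectors over a fixed panel of genomes) are similar;
* **co-expression** — genes working in the same process are transcribed in
  the same tissues, so their expression vectors across a tissue atlas are
  correlated.

`evocor` implements the combined method: build a presence/absence vector
per gene over an ordered species universe (presence in species *s* iff a
profile-HMM search finds a sequence with at least one domain at E-value
strictly below 1e-7), score co-evolution between genes *q* and *c* as the
Hamming distance

d(q, c) = Σ_s | x_qs − x_cs |,

then rank candidates for a query by *d* ascending, breaking equal-distance
ties by Pearson expression correlation *r* descending (gene identifier as
the final tie-break), after discarding every candidate with *r* < 0.2.
The top 125 candidates form the result list.  The package also implements
the method's validation machinery — split-half annotation-term overlap
against randomized controls (two-sided Kolmogorov–Smirnov test) and an
evolution-only vs combined comparison (one-sided Wilcoxon rank-sum test) —
plus a synthetic-data generator with planted co-evolving, co-expressed
modules so the whole pipeline is testable offline.

It is aimed at computational biologists who want a local, scriptable,
reproducible version of this class of candidate-gene screens, with every
stage exposed as an R function.

## Worked example

```r
library(evocor)

cfg   <- simulation_config(seed = 1)   # 500 genes, 182 species, 20 planted modules
bench <- simulate_benchmark(cfg)

query <- bench$membership$modules$m01[1]
evocor_rank(query, bench$profiles, bench$expression)
#> ranked candidates for query 'g001' (evolution + expression): 22 gene(s)
#>  gene hamming         r rank
#>  g010       7 0.7330600    1
#>  g007       7 0.7287453    2
#>  g004       7 0.6953816    3
#>  g005       7 0.6836986    4
#>  g006       7 0.6519879    5
#>  g003       9 0.7187815    6
#>  g008       9 0.6558973    7
#>  g009      10 0.7865528    8
#>  g002      10 0.6804268    9
#>  g402      83 0.2188447   10
#> ... and 12 more
```

The nine top-ranked genes are exactly the query's true module partners:
within-module bit-flip noise of 2% puts them at Hamming distance ≈ 7 of
182 with correlation ≈ 0.7, while unrelated genes sit near distance 91 and
pass the 0.2 correlation filter only by chance (the list tail).  The
validation protocol over all 200 module queries:

```r
queries <- unlist(bench$membership$modules, use.names = FALSE)
sets <- lapply(queries, function(q)
  evocor_rank(q, bench$profiles, bench$expression)$gene)
names(sets) <- queries

evaluate_method(sets[lengths(sets) > 0], bench$annotations, seed = 11)
#> split-half term-overlap evaluation (jaccard statistic, 200 queries)
#>   mean overlap: method 0.6012, randomized control 0.1634
#>   two-sided KS: D = 0.8200, p = 7.891e-59

compare_evo_vs_combined(queries, bench$profiles, bench$expression,
                        bench$annotations, seed = 12)
#> evolution-only vs combined ranking (200 queries, over_smaller overlap)
#>   mean overlap: evolution-only 0.8936, combined 0.8753
#>   Wilcoxon rank-sum (combined first, greater): W = 45470, p = 9.157e-07
```

Method lists overlap far more across their halves than shuffled controls
(D = 0.82), and adding expression to the evolutionary ranking shifts the
per-query overlap distribution upward (combined lists usually achieve
perfect containment of the smaller half's terms; the improvement is
distributional, which is why it is read from the rank-sum test rather than
the means — see the methods vignette).

## Command line

```sh
Rscript inst/cli/evocor.R simulate --config sim.yaml --out-dir data/
Rscript inst/cli/evocor.R build-profiles --hits data/hits.domtblout \
        --universe data/universe.txt -o data/profiles.tsv
Rscript inst/cli/evocor.R rank --query g001 --profiles data/profiles.tsv \
        --expression data/expression.tsv -o results/g001.tsv
Rscript inst/cli/evocor.R evaluate --results-dir results/ \
        --gmt data/annotations.gmt --seed 1 -o report.tsv
```

Flags override a YAML config file, which overrides the published defaults
(E < 1e-7, r ≥ 0.2, top 125); every run logs its resolved configuration.

## Package tour

| file | contents |
|---|---|
| `R/formats-io.R` | HMMER3 domtblout, species universe, TSV matrix, GMT and ranked-list readers/writers |
| `R/profiles.R` | presence rule, profile matrices, Hamming distances |
| `R/expression.R` | log2 + quantile normalization, Pearson correlations |
| `R/ranking.R` | the two-key filter-and-rank scheme |
| `R/evaluation.R` | split-half overlap, randomized controls, KS and Wilcoxon statistics |
| `R/simulate.R` | planted-module generator (profiles, expression, hits, annotations) |
| `R/cli.R` | `build-profiles` / `rank` / `evaluate` / `simulate` subcommands |
| `vignettes/methods.Rmd` | model, assumptions, parameters, design notes, limitations |
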