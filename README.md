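# MIFilter

Contaminant filtering for microbiome count tables via mutual-information
network analysis.

16S amplicon studies routinely produce ASV/OTU tables polluted by
reagent contamination, cross-talk and sequencing error. Ad hoc abundance
or prevalence cutoffs remove such taxa only at the price of an arbitrary
threshold, and they discard genuinely rare community members. MIFilter
instead exploits the fact that members of a real community co-vary:
it scores every taxon by how much information it shares with the rest of
the table and removes the taxa that share none.

## Method

For a count table *X* (*n* samples × *m* taxa), each taxon profile is
discretized (equal-width histogram bins, Sturges' rule by default) and
every pair *j*, *j′* receives the **adjusted mutual information**

  Ĩ<sub>jj′</sub> = I(X<sub>j</sub>; X<sub>j′</sub>) / H(X<sub>j</sub>, X<sub>j′</sub>),

mutual information normalized by joint entropy, giving a symmetric
adjacency matrix with entries in [0, 1] and unit diagonal (and no
dependence on the logarithm base). The weighted network is hard-thresholded
at the cutoff τ that maximizes the fit of the degree distribution to a
power law P(k) ∝ k<sup>−γ</sup> (R² of the log–log regression; ties broken
by higher mean connectivity). **Isolated nodes** — taxa with no edge at the
selected τ — are flagged as putative contaminants and removed.

How much of the table can be discarded is quantified by the Frobenius
information loss Λ = 1 − ‖Ĩ′‖²<sub>F</sub>/‖Ĩ‖²<sub>F</sub> of the
submatrix Ĩ′ retained after removing all taxa whose weighted degree
d<sub>j</sub> = Σ<sub>j′≠j</sub> Ĩ<sub>jj′</sub> falls below successive
quantiles. A permutation test (taxon profiles independently permuted
across samples, the entire network recomputed) and a studentized bootstrap
decide at which quantile step the extra loss stops being explainable by
chance; the largest level reached before the first significant step is the
recommended removal level.

The package also implements four traditional filters (relative abundance,
minimum reads/samples, prevalence, and depth-plus-totals) and ROC/AUC
evaluation against ground-truth labels, plus a seeded mock-community
simulator for testing everything without external data.

## Worked example

```r
library(MIFilter)

tab <- simulateCommunity(communitySpec(seed = 42))
tab
#> MICountTable: 240 samples x 46 taxa
#>   total reads: 2,400,000

res <- miFilter(tab)
res
#> MIFilterResult: tau = 0.1; kept 7 / 46 taxa (84.8% filtered)
res$kept
#> [1] "TRUE_01" "TRUE_02" "TRUE_03" "TRUE_04" "TRUE_05" "TRUE_06" "TRUE_07"

rocAnalysis(res$adjustedMI, attr(tab, "labels"))$auc
#> [1] 1

ss <- scanSteps(tab, tests = "permutation", M = 500, seed = 1)
tail(ss$results[, c("step_lo", "step_hi", "r_lo", "r_hi", "p_perm")], 4)
#>    step_lo step_hi r_lo r_hi      p_perm
#> 16    0.76    0.81   35   37 1.000000000
#> 17    0.81    0.86   37   39 1.000000000
#> 18    0.86    0.91   39   41 0.001996008
#> 19    0.91    0.96   41   44 0.001996008
ss$recommended
#> [1] 0.86
```

The simulated mock community holds 7 interdependent true taxa carrying
~99.8% of the reads and 39 sparse independent contaminants. The pipeline
selects τ = 0.10, keeps exactly the 7 true taxa (84.8% of taxa filtered,
none of the kept taxa are contaminants, AUC = 1), and the step tests say
that up to 86% of taxa — everything below the first step that cuts into
the true community — can be removed without significant information loss
(p-values hit the 1/(M+1) floor beyond that point).

A command-line front end with `simulate`, `network`, `select-threshold`,
`loss`, `test`, `filter`, `baselines`, `roc` and `report` subcommands is
installed at `inst/scripts/mifilter.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","mifilter.R",package="MIFilter"))')" \
    filter --input counts.tsv --out run1
```

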