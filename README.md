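# netmark

Gene-subnetwork biomarker identification from case/control or multiclass
expression data, integrating curated gene sets (pathways) and a gene–gene
or protein–protein interaction network.

Single differentially expressed genes transfer poorly between cohorts, and
flat gene sets cannot say which interacting genes carry a disease signal.
netmark searches, within each pathway, for a small connected subnetwork of
genes whose joint expression separates the sample classes better than any
single member. A subnetwork with members $g_1,\dots,g_n$ and orientations
$s_g \in \{+1,-1\}$ summarizes sample $j$ by the activity

$$a_j = \frac{1}{\sqrt{n}}\sum_g s_g\, z_{gj},$$

where $z$ is the row-standardized expression and $s_g$ is the sign of the
Pearson correlation between the gene and the growing subnetwork's
activity. The search objective is the one-way ANOVA F statistic of the
activity against the class labels (equal to the squared pooled t for two
classes). Subnetworks grow from high-degree significant seed genes by one
of three strategies:

* **greedy** — expand only from the last-added member (path-shaped
  subnetworks; the baseline);
* **gs** — gene-set-based: all neighbours of every current member are
  candidates, scored by the full-subnetwork F;
* **pn** — parent-node-based: candidates ranked by a two-gene
  parent/candidate F, accepted on full-subnetwork improvement.

Expansion stops when no candidates remain or the best candidate no longer
strictly improves F; the max-F subnetwork per gene set is its
representative, and representatives with fewer than three members are
discarded. The package also ships the surrounding harness: format readers
(expression TSV + labels, GMT gene sets, edge-list/SIF/BioGRID networks),
a normalized cluster-purity homogeneity measure for judging whether two
cohorts are comparable, gene/gene-set agreement between runs, cross-cohort
SVM classification of activity features reported as ROC AUC, and a
synthetic benchmark generator with planted modules on scale-free networks
so every claim is testable offline.

## Worked example

```r
library(netmark)

net <- generateNetwork(200, attachment = 2, rngSeed = 7)
gsc <- generateGeneSets(net, nSets = 5, setSizeRange = c(20, 40),
                        overlapFraction = 0, rngSeed = 7)
sim <- generateExpression(net, gsc, effectSize = 2, nPerClass = 50,
                          rngSeed = 7)
ds  <- zTransform(sim$dataset)

run <- filterMinSize(identifySubnetworks(ds, gsc, net, searchConfig("gs")), 3)
run$representatives[[1]]
#> Subnetwork [gs] in set set01: 5 members, F = 401.7
#>    +g0003 -g0097 +g0013 -g0081 -g0029

recoveryMetrics(run, sim$truth)$aggregate
#> $meanPrecision
#> [1] 1
#> $meanRecall
#> [1] 1
#> ...
```

The representative of `set01` is a five-gene tree whose activity yields
F = 401.7 against the two classes; the `-` signs mark members that enter
the activity anti-correlated (the generator plants such members
deliberately). Here the search recovered exactly the planted five-gene
module in every gene set (precision and recall 1).

A command-line front end over the same functions is installed at
`inst/scripts/netmark-tool.R`
(`simulate`, `identify`, `purity`, `agreement`, `classify`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","netmark-tool.R",package="netmark"))')" \
    identify --expression expr.tsv --labels labels.tsv \
    --gene-sets sets.gmt --network net.tsv --strategy gs --out run1
```

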