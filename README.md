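# nestscore

Network neighbor scoring for gene essentiality prioritization.

## What problem this solves

Genome-scale CRISPR/shRNA screens, expression compendia, and ChIP-seq
experiments each produce one noisy number per gene; deciding which genes
are *essential* in a condition from that number alone is hard. A robust
empirical signal helps: essential genes tend to be members of **active
protein complexes** — their interaction partners are highly expressed, or
selected in the same direction by the screen. `nestscore` implements the
NEST (Network Essentiality Scoring Tool) statistic built on that signal,
for computational biologists who want to prioritize screen hits, rank
putative TF targets, or test network association of any per-gene value.

For a gene $g$ with network neighbors $N(g)$ and interaction confidences
$w_{gn} \in (0,1]$, the neighbor score of a value vector $v$ is

$$ s_g = \sum_{n \in N(g)} w_{gn}\, v_n = (A v)_g, $$

the connectivity matrix $A$ (zero diagonal) applied to $v$. The value
vector can be across-sample-centered expression, screen fold change, or a
ChIP-seq regulatory potential; a gene's own value never contributes to its
own score.

Significance is assessed against a degree-preserving null: the unweighted
network is randomized by **stub rewiring** (restarting until ≥ 98 % of
edges reconnect), scores are recomputed on each of `n_random` rewired
networks, and each gene gets a permutation Z
(real minus null mean, over the null spread) and a sign-conditional
empirical p-value, never smaller than `1/n_random`.

The package also ships the full evaluation harness (ROC/AUC via the
tie-aware Mann–Whitney statistic, Wilcoxon rank-sum specificity Z,
multivariate logistic confounder analysis with Logit Z = coef/stderr,
Gaussian-noise degradation experiments), a distance-weighted
regulatory-potential calculator for BED peak files, and a planted-module
synthetic data generator so everything is testable offline.

## Worked example

The three-gene network A–B (0.5), A–C (1.0), B–C (0.2) with values
A = 1, B = 2, C = −1:

```r
library(nestscore)
net <- gene_network(data.frame(from = c("A", "A", "B"),
                               to   = c("B", "C", "C"),
                               weight = c(0.5, 1, 0.2)))
rank_percentile(nest_scores(net, c(A = 1, B = 2, C = -1)))
#>   gene score rank_percentile
#> 1    A   0.0       0.3333333
#> 2    B   0.3       0.6666667
#> 3    C   1.4       1.0000000
```

A's score is 0.5·2 + 1.0·(−1) = 0; C collects 1.0·1 + 0.2·2 = 1.4 and
ranks highest.

On the synthetic benchmark (500 genes, 10 planted complexes of 10 genes,
3 of them active), neighbor scores recover the active-complex members far
better than the raw values themselves:

```r
ds <- generate_dataset(synthetic_spec())
ds
#> synthetic_dataset: 500 genes, 1495 edges, 3/10 modules active, 30 truth positives

vals <- setNames(ds$values[, 1], rownames(ds$values))
gold <- gold_standard(ds$truth_positives,
                      setdiff(ds$network$nodes, ds$truth_positives))
roc_auc(nest_scores(ds$network, vals), gold)
#> ROC: AUC = 0.9932 (30 positives, 470 negatives)
roc_auc(vals, gold)
#> ROC: AUC = 0.7331 (30 positives, 470 negatives)
```

The permutation test ranks genes by how far their real score exceeds the
degree-preserving random expectation; at 100 randomizations the smallest
reportable p is 0.01:

```r
perm <- permutation_test(ds$network, vals,
                         randomization_config(n_random = 100, seed = 1))
head(perm[order(perm$p, -abs(perm$z)), ], 5)
#>     gene score null_mean null_sd     z    p p_upper_bound
#> 89 g0089  7.95      1.39    2.69  2.44 0.01         FALSE
#> 86 g0086  8.56      1.85    2.97  2.26 0.01         FALSE
#> 82 g0082  8.84      1.85    3.55  1.97 0.01         FALSE
#> 85 g0085  7.70      1.91    3.16  1.83 0.02         FALSE
#> 15 g0015 -4.32      1.67    3.34 -1.79 0.03         FALSE
```

The same pipeline is scriptable from a shell via the installed `exec/nest`
entry point: `nest simulate`, `nest score`, `nest permtest`,
`nest rewire`, `nest evaluate`, and `nest rp`, all file-to-file with a
YAML echo of the resolved configuration.

See `vignettes/network-essentiality-scoring.Rmd` for the model,
null-model, and benchmark details.

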