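# crvnet

Differential protein association networks as a network-based biomarker.

## The problem

Single-gene expression signatures for classifying disease samples are
notoriously unstable: gene lists from similar cohorts barely overlap, and a
flat list says nothing about how its members relate. `crvnet` implements a
systems alternative for two-phenotype studies (the motivating application is
diagnosing lung cancer in smokers from airway epithelium microarrays): the
biomarker is not a gene list but a *pair of networks* — one protein
association network fitted to the disease cohort, one to the control cohort
— built by integrating expression profiles with protein–protein interaction
(PPI) data. Comparing the two networks highlights proteins whose
*associations* rewire in disease, even when their own expression barely
changes, and the pair of networks doubles as a classifier for new samples.

It is aimed at computational biologists with a labeled expression matrix
(rows = genes/proteins, columns = samples), a PPI table (BioGRID TAB2, HPRD
flat file, or any two-column edge list), and a two-group phenotype.

## The model

Expression rows are z-transformed per protein. Differentially expressed
proteins (one-way ANOVA, Bonferroni p < 0.05, at least one PPI record) plus
proteins interacting with ≥ 3 of them form the protein pool; linking pool
proteins that share an interaction gives the *rough PPI network*, with every
degree capped below the smaller group's sample size to keep the regressions
determined. For each target protein *i* and each phenotype, the linear
association model

    y_i[n] = Σ_k α_ik · y_ik[n] + ε_i[n]

is fitted over that phenotype's samples (Gaussian ML = least squares without
intercept on z-scores), then refined by AIC-gated backward elimination and a
coefficient t-test screen. The retained association abilities α_ik, after
symmetrizing each pair by the larger |α|, form the cancer and non-cancer
protein association networks **C** and **N** (CPAN/NPAN).

Scoring: with **D** = **C** − **N**, each protein's *carcinogenesis
relevance value* is CRV_i = Σ_j |d_ij|. Significance comes from a
permutation null that scatters the observed edge-difference magnitudes onto
random protein pairs (edge count preserved, 100 000 replicates by default);
proteins with empirical p ≤ 0.05 are called significant.

Diagnosis: a new z-scored sample **Z** gets mapping errors
ME_C = ‖**Z** − **C Z**‖₂ and ME_N = ‖**Z** − **N Z**‖₂; ME_C < ME_N
classifies it as cancer (ties go to non-cancer).

## Worked example

Everything below is synthetic and self-contained (no downloads):

```r
library(crvnet)

truth <- generate_network_pair(K = 30, n_edges = 60, shared_fraction = 0.7, seed = 42)
x  <- simulate_study(truth, n_cancer = 100, n_noncancer = 100, seed = 43)
xz <- znormalize(x)

net  <- truth$rough_true
cpan <- build_association_network(net, xz, "cancer")
npan <- build_association_network(net, xz, "noncancer")
cpan
#> AssociationNetwork (cancer): 30 proteins, 56 associations

d   <- difference_matrix(cpan, npan)
crv <- permutation_null(net, d, n_permutations = 1000, seed = 44)
head(crv, 5)
#>   protein   crv p_value p_display significant
#> 1    P002 1.927 0.03227 0.0322667        TRUE
#> 2    P004 1.826 0.04470    0.0447        TRUE
#> 3    P028 1.630 0.08203 0.0820333       FALSE
#> 4    P019 1.628 0.08250    0.0825       FALSE
#> 5    P018 1.556 0.10167  0.101667       FALSE

test <- znormalize(simulate_study(truth, 20, 20, seed = 45))
evaluate_diagnoses(classify_samples(test, cpan, npan))
#> PerformanceSummary: n=40 (tp=15 tn=15 fp=5 fn=5)
#>   accuracy 75.00%  sensitivity 75.00%  specificity 75.00%
```

With 30 % of the generating edges differing between phenotypes, the two
top-CRV proteins are flagged significant against the permutation null, and
held-out samples classify well above the 50 % chance level (identical
generating networks give ~50 %; see the acceptance tests).

For real data, start instead from files:

```r
x   <- read_expression("expression.tsv", "labels.tsv")   # raw values
ppi <- read_interactions(c("biogrid.tab2.txt", "hprd.txt"),
                         c("biogrid_tab2", "hprd"))
xz  <- znormalize(overlay_genes_on_proteins(x))
dt  <- differential_test(xz)
pool <- select_pool(dt, ppi)                 # DE ∪ highly connected
net  <- build_rough_network(pool, ppi, xz)   # degree-capped
```

or drive the whole thing from the shell:

```sh
Rscript inst/cli/crvnet.R run-all \
  --expression expression.tsv --labels labels.tsv --ppi ppi_edges.tsv \
  --query-expression prospective.tsv --query-labels prospective_labels.tsv \
  --out run1 --permutations 100000 --seed 1
```

which writes the differential table, rough-network edges, CPAN/NPAN edge
lists (+ SIF for Cytoscape), the CRV table, and per-sample diagnoses under
`run1/`.

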