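# ncatrim

Deconvolution of transcription-factor activities from gene expression
data by Network Component Analysis (NCA), extended with iterative
trimming of false TF–gene edges, in-silico data augmentation for
under-determined designs, and a genome-scramble permutation test for
significantly perturbed transcription factors.

## The problem

Transcription-factor (TF) activity is regulated largely
post-transcriptionally, so it cannot be read off the TF's own mRNA.
NCA recovers it from the targets instead: given a log-ratio expression
matrix *E* (*N* genes × *M* experiments) and a TF–gene connectivity
pattern *Z* (*N* × *L*), it solves the constrained bilinear
decomposition

```
E = A P + Γ,      A[i, j] = 0 wherever Z[i, j] = 0
```

where *A* holds control strengths (CS), *P* holds the latent TF
activity profiles (TFA), and the zero-pattern constraint makes the
factorisation essentially unique when the network satisfies three
structural criteria.

Connectivity priors curated from databases contain edges that are
false, or inactive in the condition of interest, and these distort the
estimated control strengths. The package's core algorithm trims them:
TFAs estimated from the current network feed a per-gene **forward
stepwise regression** scored by the small-sample corrected Akaike
criterion,

```
AICc_k = M log(2π RSS / M) + M (M + k) / (M − k − 2),
```

which needs no user threshold; edges not in a gene's selected model are
deleted and the loop repeats until an iteration retains more than 99%
of its edges. Designs with too few experiments (genes with more
regulators than data points) are first expanded with seeded in-silico
replicates drawn per-cell from *N*(E\_ij, E\_ij² σ²). Finally, TFs that
respond to the condition are identified by robust z-scores of the real
TFAs against null distributions built from genome-scrambled data
(median/MAD with the 1.4826 normal-consistency factor, two-tailed
p-values, Benjamini–Hochberg adjustment across TFs).

A synthetic benchmark generator (power-law in-degree topology,
planted control strengths, false-edge injection at a prescribed false
connection rate, relative Gaussian noise) plus ROC and SNR scoring
close the loop for validation.

## Worked example

The paper-scale benchmark: a 348-gene × 20-TF network corrupted with
20% false edges, three noisy experiments (the hardest realistic
design), augmented and trimmed.

```r
library(ncatrim)

net  <- generate_network(seed = 1)                      # ground truth
net  <- corrupt_pattern(net, fcr = 0.20, seed = 2)      # + false edges
sim  <- simulate_expression(net, r = 3, noise_level = 0.5, seed = 3)
pat0 <- connectivity_pattern(net$Z0)

check_compliance(pat0, ncol(sim$E))
#> Compliance of the connectivity pattern:
#>   (i)   regulon sizes <= N - L + 1 : ok
#>   (ii)  no regulon nested in another: ok
#>   (iii) max regulators per gene (7) <= M (3): VIOLATED
#>   offending genes: 41 (e.g. gene7, gene13, gene18, gene21, gene29)

plan <- augmentation_plan(sim$E, pat0)                  # -> 3 replicate blocks
E    <- augment_expression(sim$E, plan$n_replicates, seed = 4)

trace <- trim_network(E, pat0, seed = 5)
trace
#> Network trimming: 4 iteration(s), 673 -> 450 edges (converged)
#>   iteration 1: 475 edges retained (70.58%)
#>   iteration 2: 458 edges retained (96.42%)
#>   iteration 3: 452 edges retained (98.69%)
#>   iteration 4: 450 edges retained (99.56%)

edge_recovery_roc(trace$final_decomposition, trace$final_pattern,
                  net, mode = "important")
#> Edge-recovery ROC (important edges): AUC 0.706; trimmed operating point
#> TPR 0.787 / FPR 0.626 (178 pos, 495 neg)
```

The first pass removes most of the injected false edges (673 → 475);
later passes stabilise the pattern. At the trimmed operating point,
79% of the *important* true edges — those whose |CS| ranks in the top
30% of their TF's regulon — survive, despite only three informative
experiments at 50% relative noise. With real data the same pipeline is
driven from files:

```r
res <- run_pipeline(run_config("expression.tsv", "edges.tsv",
                               pool = "genome.tsv", out_dir = "out/",
                               seed = 1))
res$calls        # significantly perturbed TFs (z, p, BH-adjusted p)
```

or from a shell via `exec/ncatrim` (`simulate`, `augment`, `trim`,
`nulltest`, `evaluate`, `run` subcommands).

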