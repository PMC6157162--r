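# mircascade

Nonparametric Bayesian clustering of miRNA–mRNA binding sites for
microRNA target prediction.

microRNAs silence their mRNA targets by base-pairing, primarily through
the seed region (bases 2–8 from the miRNA 5′ end), but large-scale
crosslink-and-sequencing assays (CLASH, CLIP variants) show that real
interactions follow many distinct binding patterns — non-seed pairing,
coding-region sites, cooperative and competitive binding. `mircascade`
treats target prediction as a clustering problem over those patterns
rather than a single seed-match rule: experimentally observed binding
sites are described by an `m`-dimensional feature vector and grouped
with a Dirichlet-process Gaussian mixture model (DPGMM), whose number of
components is learned from the data.

The model, in the field's standard notation:

- the mixture likelihood is `p(x) = Σ_j π_j N(x; μ_j, Σ)` with fixed
  isotropic covariance `Σ = σ²I` and a conjugate `N(0, 1)` prior on the
  component means (features are standardized);
- the Chinese-restaurant-process prior on cluster assignments is
  `p(z_i = j) = n_j / (α + n − 1)` for an existing cluster with `n_j`
  members and `α / (α + n − 1)` for a new cluster;
- assignment uses normalized log posteriors,
  `log n_j + log N(x; μ_j, σ²I)` for existing clusters and
  `log α + log N(x; 0, (σ²+1)I)` for a new one, with points placed at the
  argmax and exact ties broken at random;
- `(α, sweeps)` are selected by BIC over a grid, and mixed clusters with
  more than 30 members are recursively re-clustered into a **cascade
  tree** until leaves are homogeneous in the participating miRNA or
  transcript, too small (excluded if still label-mixed), or at maximum
  depth;
- a new interaction is routed to a leaf and ranked by the interaction
  confidence `IC = z · c_k`, the product of its normalized leaf
  posterior `z` and the leaf's dominant-miRNA proportion `c_k`.

Around the core model the package provides feature generation (k-mer
composition, seed/duplex pairing counts, a Smith–Waterman
complementarity alignment score, flank AU content, site position, and
secondary-structure accessibility via a built-in Nussinov engine or an
external thermodynamic folder such as `RNAfold`), four-tier negative-set
synthesis from sliding transcript windows, t-test/AUC/recursive feature
elimination, and transcriptome screening by iterated local alignment.
A synthetic-world generator plants seed-complementary sites with known
coordinates, so the whole pipeline is testable without external data.

## Worked example

```r
library(mircascade)

world <- make_world(n_mirnas = 3, n_transcripts = 8, sites_per_pair = 2, seed = 42,
                    n_decoy_mirnas = 2, n_decoy_transcripts = 3)
negs  <- generate_negative_set(world$interactions, world$mirnas, world$transcripts,
                               n_per_tier = 20, seed = 42)
interactions <- dplyr::bind_rows(world$interactions, negs)
split <- split_interactions(interactions, test_fraction = 0.25, seed = 42)

fit <- train_pipeline(split$train, world$mirnas, world$transcripts,
                      cascade = cascade_config(size_threshold = 12, grid = "all",
                                               alphas = c(1, 10, 30, 60, 100),
                                               iteration_counts = 30, seed = 42),
                      seed = 42)
fit
#> mircascade pipeline: 693 -> 10 features after selection
#> Cascade DPGMM tree: 4 nodes, depth 1
#>   1 internal, 3 leaves (0 excluded)

evaluate_pipeline(fit, split$test, world$mirnas, world$transcripts, level = "leaf")
#> # A tibble: 1 × 8
#>      tp    fp    tn    fn sensitivity specificity accuracy   mcc
#>   <int> <int> <int> <int>       <dbl>       <dbl>    <dbl> <dbl>
#> 1    12     0    20     0           1           1        1     1

preds <- screen_transcriptome(fit$tree, world$mirnas[1:3, ], world$transcripts[1:8, ])
head(preds, 3)
#> # A tibble: 3 × 10
#>   mirna_id transcript_id site_start site_end alignment_score leaf_node     z ...
#> 1 mir-002  tx-002               342      364              42 node2     1.000
#> 2 mir-002  tx-008               328      350              41 node2     1.000
#> 3 mir-003  tx-001               322      344              40 node2     1.000
```

The training pipeline generated 693 features per interaction, removed
non-discriminative ones with a per-feature Welch t-test, ranked the rest
by univariate AUC, pruned them by recursive elimination with 5-fold
cross-validated DPGMM accuracy (10 features survive on this small
world), and built the cascade tree on the standardized selection.  Held
out 25% of the data, every test interaction is classified correctly at
leaf level.  Screening aligns each miRNA against each transcript,
featurizes the candidate sites exactly as at training time, and ranks
positive calls by `IC`; the top rows are planted sites recovered at
their true coordinates.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; models serialize to versioned JSON with
`save_model()`/`load_model()`.  A command-line wrapper over the same
functions is installed at `inst/cli/mircascade.R` (subcommands
`simulate`, `negatives`, `train`, `screen`, `eval`).

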