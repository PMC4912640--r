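# spongenet

Analysis toolkit for large replicated host–microbiome surveys, built
for the kind of data a global sponge-microbiome study produces:
hundreds of specimens across dozens of host species, with OTU count
tables (mothur `.shared` or plain TSV), sample metadata, taxonomy, host
trees and similarity hit tables.

The package answers three connected questions:

1. **How are symbionts distributed across hosts?** The host–OTU
   association structure is a bipartite network. Its OTU-side
   complementary cumulative degree distribution is fitted with a
   truncated power law, Pc(k) = k^−a · e^(−k/b), and the host side
   with an exponential Pc(k) = e^(−k/λ). Degree thresholds split OTUs
   into specialists (< 5 host species), generalists (> 50) and, via
   replicate prevalence, opportunists.
2. **Do core symbionts interact?** For each well-replicated host, the
   core microbiome (OTUs in ≥ 85% of 47 replicates, above a 1%
   abundance floor) is modelled with sparse Lotka–Volterra dynamics on
   log abundance,
   `n[i,m] = n[i,m-1] + r_i (1 − (N_i − Σ γ_ij α_ij N_j)/k_i) + ε`,
   with a Poisson observation layer and Gibbs variable selection
   (γ_ij ~ Bernoulli(0.1)) over the interaction coefficients, sampled
   by a purpose-built Metropolis-within-Gibbs MCMC. The stationary
   variance is decomposed into density dependence, interactions and
   stochasticity, and a representative signed network is extracted and
   typed (amensal, commensal, mutualist, …).
3. **Does host phylogeny matter?** Blomberg's K with a permutation
   test, and Mantel / partial Mantel tests linking host phylogeny,
   host identity and community dissimilarity.

A first-class synthetic-data module generates every input the pipeline
consumes — communities with prescribed degree laws and prevalence
classes, replicate series from known interaction matrices, hit tables,
trees with Brownian or signal-free traits — so the whole pipeline is
testable without downloads.

## Worked example

```r
library(spongenet)

spec <- community_spec(n_hosts = 40, n_otus = 1200, replicates_per_host = 6,
                       depth = 8000, seed = 42)
com <- gen_bipartite_community(spec)
net <- build_network(com$counts, com$meta, min_samples = 5)
print(net)
#> bipartite_network: 40 hosts, 1116 OTUs, 4464 links (mean OTU degree 4.00)
fit_truncated_power_law(ccdf(net$otu_degree))
#> degree_fit [otu]: Pc(k) = k^-0.2686 * exp(-k/6.526), RSS 0.0447
```

The generator drew OTU degrees from Pc(k) = k^−0.32 · e^(−k/7.44); the
refit recovers the exponent and cutoff up to the truncation imposed by
the 5-sample occupancy filter and finite sampling. Classification and
its threshold diagnostics:

```r
cls <- classify_otus(net, com$counts, com$meta, spec_max = 5, gen_min = 25)
table(cls$classification$class)
#> generalist intermediate   specialist
#>          2          309          805
#> mean degree overall 4.00 | specialists 2.12 | generalists 28.50
```

Interaction inference on a synthetic core with known sparse truth
(8 OTUs, 200 replicates, ~10% true links):

```r
truth <- random_lv_truth(S = 8, p_link = 0.1, seed = 7)
sim <- gen_lv_series(truth, n_replicates = 200, depth_mean = 2e4, seed = 8)
post <- sample_posterior(t(sim$counts$counts),
                         lv_config("test", chains = 2, iterations = 6000,
                                   burn_in = 3000, thin = 4,
                                   pilot_iterations = 1200, seed = 9))
colMeans(variance_decomposition(post)$shares[, 3:5])
#>       interactions density_dependence      stochasticity
#>              0.016              0.147              0.838
rn <- representative_network(post)
print(rn)
#> representative_network: 8 OTUs, 7 links, connectance 0.125 (posterior mean 0.124)
classify_interactions(rn)$tally
#>    mutualism  competition exploitation commensalism   amensalism         none
#>            0            0            0            6            1           21
```

Inclusion probabilities rank the true links almost perfectly here
(AUROC 0.991 against the generating γ). Variance is dominated by
stochasticity and density dependence, with interactions contributing a
small share — the expected regime for sparse, weak interaction
networks. For real analyses use `lv_config("desk")` (or `"paper"` for
the full-length protocol) rather than the quick `"test"` preset; the
R-hat warning printed by short runs means exactly what it says.

The end-to-end pipeline (filters → metrics → network → classification
→ cores → interaction inference → manifest) runs from one call:

```r
cfg <- run_config(shared = "study.shared", meta = "metadata.tsv",
                  taxonomy = "taxonomy.tsv", out_dir = "out",
                  lv = lv_config("desk"), seed = 1)
run_pipeline(cfg)
```

or from the thin CLI wrapper `inst/scripts/spongenet`.

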