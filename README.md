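# clockrank

Prioritization of circadian-clock-associated proteins from the topology of a
protein-interaction network (PIN).

Plant circadian clocks are driven by a small core oscillator (CCA1/LHY, the
PRR family, TOC1, the evening complex, GI, …), but most of the physiology
they control runs through a wider set of clock-*associated* proteins. In
species with an interactome but thin functional annotation, the network
wiring around the known core-clock proteins is the main usable signal.
clockrank turns that signal into a ranked, statistically filtered candidate
list using two complementary branches over an undirected PIN and a seed list
of core-clock proteins:

* **RWR branch** — random walk with restart from the seeds,
  `P_{i+1} = (1 − r)·W·P_i + r·P_0` with column-stochastic `W`
  (`W[i,j] = 1/deg(j)`), restart `r = 0.8`, stopping when
  `‖P_{i+1} − P_i‖₁ < 1e−6`. Nodes with stationary probability `> 1e−5`
  are raw candidates.
* **GDV branch** — graphlet degree vectors over the 15 automorphism orbits
  of the 2–4-node graphlets (11 non-redundant orbits by default), pairwise
  similarity `S_GDV(u, v) = 1 − Σ|uᵢ − vᵢ| / Σ(uᵢ + vᵢ)` to every seed, with
  an adaptive threshold walked down from 0.96 in steps of 0.01 until every
  seed has a match. Nodes of degree < 3 are removed first.

Each branch is filtered by an empirical permutation FDR
`p(g) = θ/n` (random seed sets for RWR; degree-preserving double-edge-swap
null networks for GDV; strict exceedance; `p < 0.05`), then by maximum
annotation similarity: the cosine `Γ` between hypergeometric
neighborhood-enrichment profiles must reach 0.75 against some seed in
**both** a GO and a pathway namespace. The final candidate set is the union
of the two branches.

A synthetic benchmark generator (scale-free backbone, planted densely wired
seed module, enriched module annotations) makes the whole pipeline testable
without external data.

## Worked example

```r
library(clockrank)

inst <- generate_benchmark(generator_config(
  n_nodes = 400, module_size = 20, n_seeds = 6, rng_seed = 42))
inst
#> <benchmark_instance> 400 nodes, 1251 edges; module 20 (6 seeds + 14 planted)

res <- run_pipeline(inst$network, inst$seeds,
                    inst$annotations_go, inst$annotations_pathway,
                    pipeline_config(n_permutations = 200, rng_seed = 42))
res
#> <clockrank_result>
#>   network: 400 nodes, 1251 edges; seeds mapped: 6
#>   RWR: 278 raw -> 17 significant -> 6 final
#>   GDV (threshold 0.91): 47 raw -> 26 significant -> 0 final
#>   union: 6 candidates (0 in both branches)

head(tidy(res), 3)
#> # A tibble: 3 × 10
#>   node     in_rwr in_gdv rwr_probability rwr_p s_gdv gdv_p mas_go mas_pathway
#>   <chr>    <lgl>  <lgl>            <dbl> <dbl> <dbl> <dbl>  <dbl>       <dbl>
#> 1 prot0099 TRUE   FALSE          0.0112  0.015    NA    NA  0.937       0.976
#> 2 prot0078 TRUE   FALSE          0.0107  0.02     NA    NA  0.900       0.935
#> 3 prot0225 TRUE   FALSE          0.00725 0.04     NA    NA  0.950       0.981

evaluate_recovery(inst, tidy(res)$node)
#> # A tibble: 1 × 5
#>   n_final n_planted n_hit precision recall
#>     <int>     <int> <int>     <dbl>  <dbl>
#> 1       6        14     6         1  0.429
```

Reading the run: 278 nodes hold more than `1e−5` of the walk's stationary
mass, 17 of them survive the 200-set random-seed permutation test at
`p < 0.05`, and 6 of those also share enriched GO *and* pathway profiles
with a seed (`MAS ≥ 0.75`). On this instance the wiring branch finds
significant lookalikes but none passes the dual-namespace annotation filter,
so the union is the 6 RWR survivors — all of which are planted module
members (precision 1, recall 0.43 of the 14 planted proteins).

`glance(res)` returns the same stage counts as a one-row tibble,
`autoplot(res)` draws the per-branch funnel, and
`write_pipeline_outputs(res, dir)` writes per-stage TSVs plus a
`manifest.json` with every count, threshold, and the RNG seed.

For shell use, `exec/clockrank` wraps the same functions
(`clockrank simulate | rwr | gdv | run`), e.g.
`clockrank run --network net.tsv --seeds seeds.txt --go go.gmt
--pathway pathway.gmt --out-dir results/`.

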