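# percnet

Percolation centrality and targeted immunization analysis on networks,
for epidemiologists, network scientists, and anyone allocating scarce
intervention resources during a spreading process.

## The problem and the measure

Betweenness centrality ranks nodes by the fraction of shortest paths
through them, but it is static: it cannot see that a contagion is
currently burning in one corner of the network.  Percolation centrality
(PC) weights those same geodesics by the percolation state
`x_s ∈ [0, 1]` of their source node (0 = susceptible, 1 = fully
percolated/infected, intermediate = partial), so nodes on the paths
*out of* the percolated region score highly while the spread is still
containable:

    PC(v) = 1/(N-2) * Σ_{s≠v≠r} [σ_sr(v)/σ_sr] * x_s/(S - x_v),   S = Σ_i x_i

with `σ_sr` the geodesic count, `σ_sr(v)` those through `v`, ordered
pairs, endpoints excluded.  The weights make PC collapse exactly to
normalized betweenness `BC(v) = Σ σ_sr(v)/σ_sr / [(N-1)(N-2)]` when all
states are equal, and averaging over all single-source scenarios
recovers BC too.  The package also provides:

- a source–target variant `PC_st` that weights each pair by the ramp
  `R(x_s - x_r)` (paths toward less-percolated targets), normalized over
  pairs;
- current-flow (random-walk) analogues of BC, PC, and PC_st, where the
  geodesic fraction is replaced by electrical throughput on a
  unit-resistance circuit;
- hop distance to the percolated set (the ring-vaccination ranking);
- a discrete-time SI spread simulator and the PC/BC ratio diagnostic;
- an immunization experiment harness comparing pc/bc/hop strategies over
  (ρ % percolated, i % immunized) grids, with censoring at 30
  post-intervention steps;
- scale-free (truncated power-law configuration model) and Erdős–Rényi
  generators, canonical fixtures, and brute-force oracle
  implementations used by the test suite.

Graphs are plain **igraph** objects; states are named vectors built with
`percolation_states()`.

## Worked example

```r
library(percnet)

fx <- canonical_fixture("two-hub-8")   # two bridge hubs h1-h2, left/right triples
betweenness_centrality(fx$graph)[c("h1", "h2")]
#>        h1        h2
#> 0.7142857 0.7142857
percolation_centrality(fx$graph, fx$states$right_heavy)[c("h1", "h2")]
#>   h1   h2
#> 0.55 0.90
percolation_centrality(fx$graph, fx$states$left_heavy)[c("h1", "h2")]
#>   h1   h2
#> 0.90 0.55
```

Topologically the two hubs are identical (equal BC), but when the right
group is heavily percolated the right hub `h2` carries most of the
potential spread and outranks its neighbour; mirroring the states
mirrors the ranking.  A spread-plus-intervention experiment:

```r
g <- giant_component(generate_scale_free(500, gamma = 2.5, seed = 2025))
tab <- experiment_grid(g, rho = c(2, 25), i_percent = c(1, 20),
                       strategies = c("pc", "bc", "hop"), beta = 0.5,
                       replicates = 20, rng_seed = 77)
tab$winners
#>   rho i_percent        winner
#> 1   2         1            bc
#> 2  25         1            bc
#> 3   2        20 tie:bc+hop+pc
#> 4  25        20 tie:bc+hop+pc
```

`mean_time` in `tab$cells` is the average number of steps the network
took to reach 90 % percolation after immunizing the top `i` % of
non-percolated nodes by each ranking (30 = censored: the spread never
saturated).  At scarce resources (`i = 1 %`) core protection by
betweenness delays saturation longest; at plentiful resources
(`i = 20 %`) every strategy blocks the spread outright and the cells
tie at the censoring cutoff.  Percolation centrality earns its keep in
the intermediate `(rho, i)` ranges and, above all, as the time-aware
score to *monitor* during an outbreak.

A command-line interface over the same functions is installed at
`system.file("cli", "percolation", package = "percnet")` with
subcommands `centrality`, `simulate`, `intervene`, `generate`.

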