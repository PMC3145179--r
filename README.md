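# beringia

Did the *Polyommatus* blues (Lycaenidae: Polyommatini) reach the New World
through Beringia in successive waves, with the corridor's cooling climate
filtering which lineages could cross? This package implements, as tested
and reusable R code, the inference chain behind that question:

1. **Divergence dating** of colonization nodes from a phylogram, under a
   strict molecular clock and Sanderson-style penalized likelihood, across
   the published grid of four mitochondrial substitution rates
   (6.5/7.5/9.5×10⁻⁹ for COI, 11.5×10⁻⁹ for COI+tRNA+COII, in
   subs·site⁻¹·yr⁻¹) — the mean of the eight method×rate runs is the
   working age.
2. **Dispersal–extinction–cladogenesis (DEC)** maximum-likelihood
   ancestral-range reconstruction over ten biogeographic areas, with
   dispersal allowed between land neighbours plus the north-Pacific
   (Beringia) and north-Atlantic transoceanic routes, and a read-off of
   Old World → New World crossing events from the joint ML history.
3. **Ancestral thermal tolerances**: the coldest- and warmest-locality mean
   annual temperatures of extant taxa evolve as two correlated Brownian
   characters with Pagel λ/δ/κ transforms and an optional directional
   trend (model B vs random-walk model A); fitting is by
   Metropolis–Hastings MCMC, ancestral ranges by per-draw GLS conditioning.
4. **Beringian paleotemperature**: a δ¹⁸O series smoothed by a 50-point
   running mean and calibrated exactly through three anchors (−9 °C today,
   4 °C at 9 Ma, 11 °C at 14 Ma).
5. **Gateway tests**: an exhaustive permutation test of the cooling trend
   in ancestral cold tolerance, a tolerance-vs-paleotemperature match
   report per colonization event, and Fitch/MPR parsimony for ancestral
   hostplant families.

Everything runs on seeded simulators with known ground truth plus a
hand-encoded genus-level fixture carrying the published backbone topology,
colonization ages (10.7, 9.3, 2.4, 1.1, 1.0 Ma), area codings and
hostplant families.

## Worked example

The whole chain on the fixture, at desk MCMC scale:

```r
library(beringia)

fx <- fixture_polyommatus()
inputs <- list(chronogram = fx$chronogram, phylogram = fx$phylogram,
               tolerances = fx$tolerances, tip_ranges = fx$tip_ranges,
               hostplants = fx$hostplants, d18o = sim_delta18o(seed = 5))
res <- run_pipeline(inputs, out_dir = "results/gateway", seed = 20,
                    mcmc = mcmc_config("desk", iterations = 5e4),
                    stages = c("dec", "thermal", "paleo", "gateway"))
res$events
```

prints the five colonization events, all via the north-Pacific route, with
their reconstructed tolerance ranges:

```
   clade node age_ma     t_cold    t_warm         route
1 node21   21   10.7   5.221327 19.770806 north_pacific
2 node29   29    7.0   3.350244 17.465229 north_pacific
3 node33   33    2.4  -4.255008 12.371324 north_pacific
4 node36   36    1.1  -9.070776  7.842179 north_pacific
5 node37   37    1.0 -10.094515  6.748801 north_pacific
```

`res$trend` gives the exact one-sided permutation test of "younger
colonizers are more cold-adapted" (here r = 0.960, p = 1/120 ≈ 0.0083 —
the smallest p-value attainable with five events, and below 0.01), and
`res$match` compares each ancestor's tolerance interval with the
calibrated Beringian temperature at its crossing age, reporting matches
and distances for the near-misses. `fitch_mp` on the same fixture
reconstructs Fabaceae as the hostplant family of the three oldest
colonizing ancestors and Primulaceae / Ericaceae for the *Agriades* and
*Vacciniina* ancestors.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` … `06_gateway.R`), writing tables under
`results/`.

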