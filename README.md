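# bloodmealnets

Weighted bipartite networks of blood-feeding Diptera and their
vertebrate hosts: build them from blood-meal records, measure their
structure, and test how that structure varies with latitude and
anthropogenic habitat modification.

Molecular identification of insect blood meals yields interaction
records — one count per (fly species, host species) pair at a site. This
package turns such records into per-study, per-habitat interaction
matrices and provides the analysis around them, aimed at vector
ecologists and disease ecologists working with compiled blood-meal data:

* **Interaction evenness**: IE = *H* / ln *L*, the Shannon entropy *H* of
  the link-weight proportions over the log number of links *L*. IE = 1
  when all fly-host links carry equal weight; low IE means few species
  pairs dominate (both denominator conventions — realized links and all
  matrix cells — are implemented and labelled).
* **H2' network specialisation**: the observed entropy standardised
  between the minimum and maximum achievable by any integer matrix with
  the observed marginal totals, H2' = (H2max − H2)/(H2max − H2min); 0 =
  interactions match the random (proportional) expectation, 1 = maximal
  specialisation. The integer-feasible extrema are found by
  proportional-fill and greedy-packing heuristics refined with a 2x2
  swap search, verified in the tests against exhaustive enumeration.
* **Domestic-host removal null model**: remove humans and domesticated
  animals from each network, compare the resulting IE to 100 random
  removals of equally many host species, and report a z-score.
* **Incidence-based rarefaction** (q = 0): interpolation/extrapolation of
  host, fly and interaction richness against blood-meal effort, with
  Chao2 asymptotes.
* **Gaussian GLMs** for IE and H2' against habitat, |latitude|, richness
  S, log matrix size and dominant fly family, with nested-model deviance
  tests, Tukey HSD habitat contrasts and richness-vs-latitude models.
* A **Dirichlet-multinomial synthetic-data generator** that emulates the
  structure of compiled blood-meal datasets (47 networks in three
  habitat classes, cattle-dominated agricultural networks, five fly
  families), so the entire pipeline is testable end to end without any
  external download.

## Worked example

A small agricultural network dominated by Diptera-cattle feeding:

```r
library(bloodmealnets)

w <- matrix(c(48, 2, 1,
              12, 0, 3,
               5, 1, 0), nrow = 3, byrow = TRUE,
            dimnames = list(c("Culicoides imicola", "Culicoides obsoletus",
                              "Culex pipiens"),
                            c("Cattle", "Human", "Turdus merula")))
net <- interaction_matrix(w, row_family = c("Ceratopogonidae",
                                            "Ceratopogonidae", "Culicidae"),
                          study_id = "S01", habitat = "Agricultural",
                          latitude = -23.5)
network_summary(net)[, c("IE", "H2prime", "S", "m", "L",
                         "dominant_family", "abs_latitude")]
#>          IE   H2prime S  m L dominant_family abs_latitude
#> 1 0.5678156 0.1779537 6 72 7 Ceratopogonidae         23.5
```

IE = 0.57: the 48-meal Diptera-cattle link dominates the seven links.
H2' = 0.18: given how skewed the marginals already are, the cell pattern
is close to the proportional expectation — a generalised network.

Removing the domestic hosts (cattle, human) and comparing with random
two-host removals:

```r
run_null_model(net, n_reps = 100, seed = 1)
#> null_model_result S01::Agricultural: k = 2, IE targeted = 0.811, z = 0.032
```

The targeted removal changes evenness no more than random removals do
(z near 0).

A full synthetic study, end to end:

```r
sim <- generate_dataset(default_scenario(1))
ns  <- split_networks(sim$records)
ns
#> network_set: 47 networks (0 excluded), 1731 records, 9148 meals

met <- summarise_networks(ns)
round(tapply(met$IE, met$habitat, mean), 3)
#> Agricultural  NearNatural VillageUrban
#>        0.688        0.859        0.856

term_significance(metrics_table(met), "IE", "habitat")
#>      term deviance_change df      p_value      p_chisq     p_raw
#> 1 habitat       0.1208653  2 5.991683e-05 2.787159e-06 0.9413572
```

Agricultural networks are markedly less even — their interactions
concentrate on cattle — and the habitat term is significant after
controlling for richness, network size and fly family (`p_value` is the
exact Gaussian F test; the two chi-square treatments of the same
deviance change are shown alongside). `run_all(run_config(...))` drives
the same stages from a records CSV or a simulation scenario and writes
per-stage CSVs plus a manifest.

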