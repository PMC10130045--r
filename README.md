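# preyselect

Prey availability, stable-isotope diet inference, and prey selectivity
for marine predators.

`preyselect` implements the quantitative core of a trophic-ecology
question: *what does an elusive predator eat, and is it selecting prey
by abundance or by quality?* It was built around the Rice's whale
(*Balaenoptera ricei*), a critically endangered baleen whale endemic to
the Gulf of Mexico whose diet cannot be observed directly, but every
stage is generic: a trawl survey describes the prey field, skin-biopsy
stable isotopes constrain the diet, and proximate composition describes
prey quality.

The pipeline:

1. **Availability** — per-species occurrence, percent by number and
   percent by biomass from a haul × species catch table
   (%Oᵢ = nᵢ/N·100, %Nᵢ = xᵢ/X·100, %Bᵢ = bᵢ/B·100), with
   haul-resampling percentile bootstrap intervals.
2. **Diet** — a Bayesian mass-balance mixing model over two tracers:
   X_jt ~ N(Σᵢ pᵢ(μᵢₜ+λₜ), √vₜ), Dirichlet prior on the diet simplex p,
   trophic enrichment factor λₜ ± τₜ, hierarchical source moments, and a
   multiplicative residual error vₜ = ξₜ·Σᵢ pᵢ²(σᵢₜ²+τₜ²) (an additive
   structure is available as an option). Sampling is blocked
   Metropolis-within-Gibbs written in plain R, with Gelman–Rubin and
   Geweke diagnostics; any R̂ > 1.05 is flagged, never swallowed.
3. **Validity** — Monte-Carlo mixing-polygon simulation: 1500 convex
   hulls of TEF-corrected source draws, point-in-polygon with on-edge
   counted inside, consumers retained when their inside probability is
   ≥ 0.05 (the 95% mixing region).
4. **Quality** — dry/wet energy-density conversion via moisture,
   protein = 6.25 × nitrogen, ANOVA/Tukey or Kruskal–Wallis
   comparisons with a Shapiro–Wilk normality gate.
5. **Selection** — Chesson's index αᵢ = (rᵢ/pᵢ)/Σⱼ(rⱼ/pⱼ) with the
   1/m random-feeding threshold, and Pianka's overlap
   O = Σ pᵢApᵢB / √(Σ pᵢA² Σ pᵢB²).

A seeded synthetic-data module (zero-inflated negative-binomial trawl
surveys, forward-simulated consumers, proximate-composition records)
gives every stage a ground-truth recovery test, and bundled
`gom_*()` reference tables carry the published Gulf of Mexico summary
inputs so the whole analysis reruns from a clean install with no
external data.

## Worked example

```r
library(preyselect)

fit <- fit_mixing_model(gom_consumers(seed = 42), gom_prey_sources(),
                        gom_tef(),
                        mixing_config(draws = 30000, burnin = 20000,
                                      seed = 42))
fit
#> Bayesian stable-isotope mixing model (4 sources, 10 consumers)
#> error structure: residual_process | hierarchical sources
#> 3 chains, 30000 retained draws; mean acceptance 0.248
#> max R-hat: 1.0098 (converged)
#>
#> Posterior mean diet proportions (%):
#>                source mean   sd
#>         Ariomma bondi 66.7 15.9
#>     Diaphus dumerilii 17.1 14.8
#>   Doryteuthis pealeii  7.3  5.9
#>  Maurolicus weitzmani  8.9  6.9
```

Two-thirds of the diet is *Ariomma bondi*, a schooling driftfish that
makes up only ~1.2% of trawled individuals — and the polygon check
confirms the model is geometrically admissible for every whale:

```r
region <- simulate_mixing_region(gom_prey_sources(), gom_tef(),
                                 gom_consumers(seed = 42),
                                 iterations = 1500, seed = 42)
sum(region$retained)
#> [1] 10
```

Selectivity against percent-by-number availability, and overlap against
percent-by-biomass availability:

```r
av <- availability(gom_catch_table(), boot_reps = 0)
p  <- map_trawl_to_sources(av, gom_source_mapping(), basis = "pct_number")
classify_selection(chesson(coef(fit), p[names(coef(fit))]))
#> Chesson's selectivity (ratio form, m = 4, random-feeding threshold 1/m = 0.25)
#> Rule: threshold_1_over_m
#>               species diet_r avail_p alpha selection
#>         Ariomma bondi  0.667   0.013 0.768  Positive
#>     Diaphus dumerilii  0.171   0.014 0.187  Negative
#>   Doryteuthis pealeii  0.073   0.025 0.044  Negative
#>  Maurolicus weitzmani  0.089   0.949 0.001  Negative

pb <- map_trawl_to_sources(av, gom_source_mapping(), basis = "pct_biomass")
pianka(pb[names(coef(fit))], coef(fit))
#> Pianka niche overlap O = 0.814 (0 = no overlap, 1 = complete overlap)
```

α far above 1/m for *A. bondi* means the whale takes it wildly out of
proportion to its numerical availability: selection is active, and the
prey-quality tables (`gom_proximate_summary()`, `group_compare()`) show
the selected species is also the most energy-dense. See the methods
vignette (`vignettes/prey-selection-methods.Rmd`) for the model,
its error-structure options, and every documented design choice.

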