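# mortCA

Cattle age-at-death mortality profiles and correspondence analysis of
Dirichlet deviates, for zooarchaeologists studying husbandry strategies
(milk vs meat production) from dental remains.

## The problem

Slaughter management leaves a demographic signature: dairy herds cull
calves around weaning (6–15 months, "post-lactation") or before 6 months
("intensive milk"), while meat production peaks at prime weight (3–6
years). The signature is read from mandibular teeth (dP4, M1, M2, M3)
scored by eruption, replacement and wear, binned into seven ordinal age
classes: 0–6, 6–15, 15–26, 26–36 months, 3–6, 6–8 and >8 years.

Archaeological assemblages are fragmented, so isolated teeth dominate and
many can only be placed in a *run* of classes. Three statistical problems
follow, and this package solves each:

1. **Attribution.** A tooth compatible with classes *i..j* is divided
   among them in proportion to class durations *d_k* (months):
   *w_k = d_k / Σ d*, so a stage spanning 6–15 and 15–26 months (9 and 11
   months) counts 0.45 and 0.55 of a tooth. Splitting conserves teeth
   exactly; counts are carried fractionally. The open terminal class uses
   a nominal 24-month duration.
2. **Uncertainty.** Per-context proportions get equal-tailed credible
   intervals from the Dirichlet posterior: with fractional counts *n* and
   prior concentration α₀ = 0.5 per class, draw 2000 deviates from
   Dirichlet(n₁+α₀, …, n₇+α₀) and take empirical 2.5/97.5% quantiles.
3. **Comparison.** Correspondence analysis of the *stacked deviates*
   (contexts × 2000 rows, each a proportion vector): SVD of the
   standardized residuals S = D_r^{-1/2}(P − rcᵀ)D_c^{-1/2}, principal
   inertias λ_a = σ_a², column contributions Ctr_ka = 1000·c_k·G_ka²/λ_a
   (‰). Reference husbandry profiles are projected as *supplementary
   points* (f_a = Σ_k p_k γ_ka with standard coordinates γ = G/σ) and
   contribute nothing to the inertia; each context is classified by its
   nearest reference in the F1–F2 plane.

A synthetic-assemblage generator (multinomial ages mapped to consistent
wear stages, with a controllable fraction of ambiguous multi-class
stages) makes the full pipeline testable without archaeological
collections.

## Worked example

```r
library(mortCA)
refs <- schematic_reference_set()     # synthetic Milk1/Milk2/IntenseMilk/Meat
map  <- demo_stage_map()              # demonstration wear-stage lookup

spec <- simulation_spec(
  context_id = c("siteA", "siteB", "siteC"),
  model      = c("Milk1", "Meat", "IntenseMilk"),
  n_teeth    = c(45, 50, 40), ambiguity_rate = 0.3, seed = 42)
ds  <- generate_dataset(spec, refs, map)
tab <- build_count_table(ds$records, map)

prof <- mortality_profiles(tab, alpha0 = 0.5, nsim = 2000, seed = 42)
prof[[2]]
#> Mortality profile 'siteB' (N = 50 teeth, 2000 deviates, prior 0.5)
#>    0-6 months 6-15 months 15-26 months 26-36 months 3-6 years 6-8 years
#> %         2.0         1.8         15.3         21.7      36.3      15.8
#> lo        0.2         0.2          7.2         11.4      22.4       7.4
#> hi        8.3         8.3         26.4         34.3      47.6      26.2
#>    >8 years
#> %       7.0
#> lo      2.1
#> hi     15.5
```

siteB was simulated from the meat model and shows the expected 3–6 year
slaughter peak (36.3%, CI 22.4–47.6%). The CA of the stacked deviates,
with context means and references supplementary:

```r
act   <- stack_deviates(tab, alpha0 = 0.5, nsim = 2000, seed = 42)
means <- context_mean_profiles(act)
sup <- c(lapply(seq_len(nrow(means)), function(i) means[i, ]),
         lapply(refs, `[[`, "proportions"))
names(sup) <- c(rownames(means), names(refs))
res <- correspondence_analysis(act, supplementary = sup,
                               orient_anchors = default_orientation())
res
#> Correspondence analysis: 6 axes, total inertia 0.4008
#>   principal inertias: F1 = 0.2549 (63.6%), F2 = 0.0651 (16.2%), F3 = 0.0211 (5.3%)
#>   supplementary points: siteA, siteB, siteC, Milk1, Milk2, IntenseMilk, Meat

axis_summary(res, axes = 2)
#>          class mass_permille coord_F1 ctr_F1_permille coord_F2 ctr_F2_permille
#> 1   0-6 months           139   -0.882             423    0.340             246
#> 2  6-15 months           170   -0.508             173   -0.410             440
#> 3 15-26 months           117    0.348              56   -0.139              35
#> 4 26-36 months           155    0.405             100   -0.137              45
#> 5    3-6 years           195    0.563             242    0.214             137
#> 6    6-8 years           153   -0.077               4    0.183              78
#> 7     >8 years            71    0.104               3   -0.132              19

classify_context(res$sup_coords[1:3, ], res$sup_coords[4:7, ])[, 1:2]
#>       context_id     nearest
#> siteA      siteA       Milk1
#> siteB      siteB        Meat
#> siteC      siteC IntenseMilk
```

F1 opposes young-calf slaughter (0–6 months, Ctr 423‰) to prime-weight
slaughter (3–6 years, Ctr 242‰); every simulated context is assigned to
its true generating model. The masses column (‰ of all teeth per class)
sums to 1000 and each axis's contributions sum to 1000‰.

## Command line

```sh
Rscript -e 'mortCA::mortca_main()' simulate \
  --contexts "siteA:Milk1:45,siteB:Meat:50" --seed 42 --outdir out
Rscript -e 'mortCA::mortca_main()' profile  --records out/simulated_records.csv --outdir out
Rscript -e 'mortCA::mortca_main()' ca       --records out/simulated_records.csv --outdir out
Rscript -e 'mortCA::mortca_main()' classify --outdir out
```

Each run writes CSV outputs, optional SVG/PNG/PDF figures and a JSON
provenance record (config, seed, package version).

## Documentation

See `vignettes/mortality-profiles-ca.Rmd` for the statistical model,
parameter choices, what the synthetic generator does and does not
emulate, and known limitations.
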