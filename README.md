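# combiscreen

Design and image-based analysis of higher-order drug combination screens in
384-well format.

An *exhaustive* combination screen evaluates every non-empty subset of a
fixed drug panel — each drug at one fixed concentration — up to a chosen
order. For `N_d` drugs up to order `c` that takes

    N_w(N_d, c) = sum_{i=1..c} choose(N_d, i)

treated wells: a 9-drug screen up to order 4 needs 255, which fits on one
384-well plate next to 40+ untreated controls. `combiscreen` is for
screening groups who run such experiments with label-free time-lapse
phase-contrast imaging plus an end-point viability assay, and need the whole
path from plate design to interpretable groups of response behaviors:

* **Design** — randomized, feasibility-checked plate layouts, independently
  re-randomized per replicate plate; destination CSVs for acoustic liquid
  handlers (`design_spec()`, `randomize_layout()`,
  `export_destination_csv()`).
* **Imaging** — adaptive double-Otsu foreground segmentation; confluence
  change `ΔC` and hierarchical-pixel-histogram morphology change `ΔM` per
  well over time (`plate_features()`).
* **Counting** — a linear matched filter (`w = s − b` for a prototype patch
  `s`) with two counting algorithms (taboo peak-picking and interval
  projection) and cross-validated threshold tuning with an overfit abort
  (`build_filter()`, `tune_threshold()`, `well_counts()`).
* **QC** — intra-plate well exclusion on first-frame morphology features;
  inter-plate outlier rejection of conditions whose replicate growth curves
  span too much area, thresholded at the 95th percentile of a resampling
  null (`intra_plate_qc()`, `null_variability_distribution()`,
  `plate_qc()`).
* **Synergy** — survival index `S = (f − f̃_blank)/(f̃_control − f̃_blank)`,
  higher-order Bliss `B = Π S(c_i) − S(c_n)` and scaled Bliss
  `B_S = B · [1 − min{Π S(c_i), S(c_n)}]` with bootstrap significance and
  BH-FDR (`plate_synergy_table()`).
* **Mining** — fusion of the four readouts into `4n`-vectors, top-down
  multilevel K-means (K-means++/Lloyd, best-of-R, 20% SSE-drop K selection)
  and the smallest non-redundant representative set per group — the
  antichain of subset-minimal combinations that disentangles higher- from
  lower- and single-drug effects (`mine_responses()`,
  `nonredundant_subset()`).
* **Fixtures** — seeded generators for backgrounds, planted objects, growth
  curves and whole replicate plates with ground truth, so every stage runs
  and is tested without microscope data (`simulate_plate()`).

Functions take data frames first and return tibbles; fitted objects have
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`/`plot_*()`
visualizations. A thin command-line wrapper with `design`, `fixtures`,
`features`, `mf`, `qc`, `synergy`, `mine` and `run` subcommands ships in
`inst/cli/combiscreen.R`.

## Worked example

```r
library(combiscreen)
library(dplyr)

panel <- drug_panel(
  c("Apr", "Min", "Aur", "Cap", "Cel", "Dis", "Itr", "Ser", "Que"),
  c(2.6, 0.44, 0.15, 0.12, 1.6, 0.67, 0.3, 0.5, 3))

n_wells(9, 4)
#> [1] 255

spec <- design_spec(panel, max_order = 4, replicates = 4, seed = 1)
check_feasibility(spec)
#> # A tibble: 1 × 7
#>   n_treated min_untreated capacity feasible n_plates per_plate note
#>       <int>         <int>    <int> <lgl>       <int>     <int> <chr>
#> 1       255            40      384 TRUE            1       255 fits on one plate

layout <- randomize_layout(spec, replicate_id = 1)
count(layout, order)
#> # A tibble: 6 × 2
#>   order     n
#>   <int> <int>
#> 1     0    53
#> 2     1     9
#> 3     2    36
#> 4     3    84
#> 5     4   126
#> 6    NA    76
```

255 treated wells (9 singles, 36 pairs, 84 triples, 126 quadruples) and 53
untreated controls are placed at random wells; the remaining 76 wells are
blanks. Replicates 2–4 get independent randomizations of the same condition
multiset.

Scaled Bliss separates real from hollow synergy. Both calls below have the
same expected survival (≈0.81–0.87); the first kills cells (observed 0.41),
the second barely does (observed 0.85):

```r
scaled_bliss(c(0.9, 0.9), 0.41)
#> [1] 0.236
scaled_bliss(c(0.95, 0.92), 0.85)
#> [1] 0.0036
```

The inter-plate QC threshold comes from resampling untreated wells across
replicate plates:

```r
curves <- simulate_growth_curves(n_wells = 53, n_plates = 4, seed = 1)
null <- null_variability_distribution(curves, n_sims = 10000, seed = 1)
null
#> <variability_null> 10000 simulations, tau_95 = 1.99375
```

A condition whose replicate growth curves span more than `tau_95` is an
outlier and is not merged. Finally, the subset search reduces a response
group to its lowest-order drivers:

```r
nonredundant_subset(c("Dis", "Apr+Dis", "Dis+Min", "Apr+Dis+Min", "Min+Ser"))
#> [1] "Dis"     "Min+Ser"
```

Every combination containing Dis is explained by Dis alone; `Min+Ser` stays
because neither Min nor Ser is in the group by itself.

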