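# edgotyper

Missense and nonsense mutations disturb the human protein interactome in
different ways: a nonsense mutation truncates the protein and removes the
node outright, while a missense mutation can be harmless
(**quasi-wildtype**), sever the specific interactions whose interface it
sits in (**edgetic**), or destabilise the fold enough to remove the node
and all its edges (**quasi-null**). `edgotyper` is an R package for
structural systems biologists who want to classify variants into these
edgotypes on a structurally resolved interactome and quantify how much
more frequent node-removal outcomes are among disease-causing mutations
than among benign polymorphisms.

The package covers the full pipeline:

- **Structural interactome / proteome assembly** — reference-edge
  filtering, best-alignment selection (E-value < 1e-5), interfacial
  residue detection (any atom pair within 5 Å), template selection
  (resolution ≤ 3.5 Å, bitscore ≥ 50, ≥ 50% of interfacial residues
  aligned, deterministic tie-breaks), and alignment threading.
- **Variant mapping** — re-anchoring catalog records from source-protein
  coordinates onto canonical sequences by exact matching of the ±10
  residue flank, with indel-tolerant position shifts, ambiguity handling,
  deduplication, and structural-coverage filtering.
- **Biophysics backends** — per-mutation folding ΔΔG, per-interaction
  binding ΔΔG and Shrake–Rupley relative solvent accessibility, either
  from a deterministic synthetic backend or parsed from external
  energy-tool output (`read_energy_table()`).
- **Edgotype classification** — the decision cascade: binding ΔΔG
  > 0.8 kcal/mol on any covering interaction ⇒ edgetic; otherwise folding
  ΔΔG ≥ 2 kcal/mol ⇒ quasi-null, else quasi-wildtype; burial at
  RSA ≤ 0.25.
- **Deleteriousness statistics** — the **fold difference**

  FD = (k_case / n_case) / (k_control / n_control),

  the ratio of the node-removal fraction in the disease cohort to that in
  the control cohort, with binomial fraction standard errors and a
  delta-method ratio SE; threshold sweeps over folding ΔΔG (1–45
  kcal/mol) and RSA cutoffs with OLS best-fit lines; allele-frequency
  bins; positional distributions; coverage-ratio confounder analysis; and
  per-edgotype mean BLOSUM62 scores.
- **Synthetic data** — a fully seeded generator (toy proteome, dimer
  coordinates with programmed interfaces, indel-perturbed source
  sequences, case/control catalogs with ground-truth energies and labels)
  so the entire pipeline runs and is tested without any downloads.

Everything is tibble-first: functions take and return data frames, fitted
objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(edgotyper)

run <- run_pipeline(synthetic_config(seed = 1))
run
#> edgotyper pipeline run (truth backend)
#> # A tibble: 5 × 2
#>   stage                   n
#>   <chr>               <int>
#> 1 catalog              9150
#> 2 mapped               8680
#> 3 covered              8680
#> 4 classified_missense  8234
#> 5 structural_ppis        40
#>
#> Fold differences:
#> # A tibble: 2 × 5
#>   type       f_case f_control    fd    se
#>   <chr>       <dbl>     <dbl> <dbl> <dbl>
#> 1 quasi_null  0.2      0.0618  3.24 0.343
#> 2 nonsense    0.400    0.0200 20.0  1.82
```

The generator's defaults emulate the real study's cohort structure (722
disease and 8428 control nonsynonymous records; programmed quasi-null
fractions 19.3% vs 6.5%), so the run reproduces its headline result: the
fraction of quasi-null mutations is about **3-fold** higher among
disease-causing missense mutations than among benign ones, and the
nonsense fraction about **20-fold** higher — node removal by fold
destabilisation is strongly deleterious, and outright truncation far more
so. `run$calls` holds the per-mutation calls, `run$af_profile` the
allele-frequency bin fractions, and `mapping_report(run$mapped)` the
mapping attrition counts.

Sweeping the quasi-null folding threshold shows the fold difference
growing with the severity of destabilisation:

```r
case <- tibble::tibble(folding_ddg = sample_ddg(5000, c(meanlog = 2, sdlog = 1.3)))
ctrl <- tibble::tibble(folding_ddg = sample_ddg(5000, c(meanlog = 1, sdlog = 1.3)))
sw <- ddg_sweep(case, ctrl, thresholds = c(1, 2, 5, 10), definition = "ddg_only")
tidy(sw)
#> # A tibble: 4 × 7
#>   threshold k_case n_case k_control n_control    fd     se
#>       <dbl>  <int>  <int>     <int>     <int> <dbl>  <dbl>
#> 1         1   4649   5000      3870      5000  1.20 0.0103
#> 2         2   4197   5000      2979      5000  1.41 0.0186
#> 3         5   3044   5000      1576      5000  1.93 0.0458
#> 4        10   2014   5000       807      5000  2.50 0.0912
```

`autoplot(sw)` draws the profile with its OLS line. See the methods
vignette (`vignettes/edgotyping-methods.Rmd`) for the model, the
threshold semantics, the generator's calibration, and the package's
numerical choices.

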