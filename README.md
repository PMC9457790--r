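# nrfopart

Partition ferrous-iron oxidation in nitrate-reducing Fe(II) oxidation
(NRFO) incubations into its **enzymatic** (nitrate-coupled) and
**abiotic** (chemodenitrification) contributions by stoichiometric mass
balance — and validate that estimator by parameter recovery against a
kinetic forward model of the experiment.

## Who this is for

Geomicrobiologists and biogeochemists running anoxic batch incubations
of nitrate reducers with and without an Fe(II) amendment, who need to
say how much of the observed Fe(II) loss was coupled to microbial
nitrate reduction versus the chemical reaction of Fe(II) with biogenic
nitrite.

## The method

Two reactions consume Fe(II):

```
NO3- + 2 Fe2+ + 2 H+  ->  2 Fe3+ + NO2- + H2O        (enzymatic NRFO)
2 NO2- + 4 Fe2+ + 6 H+ ->  N2O + 4 Fe3+ + 3 H2O      (chemodenitrification)
```

With a paired Fe-free control sharing the same endogenous carbon
reserve, the excess nitrate consumed in the amended setup,
`delta_NO3 = dNO3(with Fe) - dNO3(without Fe)`, is attributed to
Fe(II)-driven enzymatic reduction, so

```
Fe_enz  = 2 * delta_NO3
Fe_chem = Fe_tot - Fe_enz          (Fe_tot = Fe(II) consumed, with-Fe setup)
N2O_chem_predicted = Fe_chem / 4   (consistency check)
```

`partition_fe()` does this arithmetic with validation, clipping and
bootstrap uncertainty; `simulate_incubation()` is a seeded ODE model of
the 240-h incubation (Monod kinetics, carbon exhaustion, second-order
chemodenitrification, encrustation-driven Hill inactivation) whose exact
ground-truth partition lets `run_recovery()` measure estimator bias —
including under deliberate violations of the paired-control assumption.
See the vignette `vignettes/mass-balance-partition.Rmd` for the model
and the design decisions.

## Worked example

The built-in demo applies the estimator to the two bounds of a reported
incubation bookkeeping (nitrate consumed 1.08/1.61 mM with Fe(II) and
0.67/1.06 mM without; 3.80 mM Fe(II) oxidized):

```r
library(nrfopart)
run_demo()
#> Mass-balance partition of Fe(II) oxidation (worked example)
#>  bound delta_no3 enzymatic_fe abiotic_fe total_fe_ox frac_enzymatic_pct
#>  lower      0.41         0.82       2.98         3.8                 22
#>  upper      0.55         1.10       2.70         3.8                 29
#>  frac_abiotic_pct frac_no3_fe_driven_pct n2o_predicted_chem
#>                78                     38              0.745
#>                71                     34              0.675
```

Reading: of the 3.80 mM Fe(II) oxidized, 0.82–1.10 mM (22–29%) was
coupled to microbial nitrate reduction and 2.70–2.98 mM (71–78%) was
chemical; 34–38% of the nitrate consumed was Fe(II)-driven; the abiotic
pool predicts a 0.68–0.75 mM N2O excess over the control.

End-to-end on simulated data:

```r
pair <- make_paired_setups(kinetic_params(), noise_model(seed = 1))
est  <- partition_fe(pair$with_fe, pair$without_fe)
est$frac_enzymatic           # ~0.25 under the default preset
ground_truth(kinetic_params())
#> [1] 0.2502359
```

## Command line

A thin wrapper (installed at `inst/cli/nrfopart.R`) exposes the same
pipeline:

```sh
Rscript inst/cli/nrfopart.R simulate  --out sim/ --seed 5
Rscript inst/cli/nrfopart.R partition --with-fe sim/with_fe.csv \
    --no-fe sim/without_fe.csv --bootstrap 500 --seed 5 --out est.json
Rscript inst/cli/nrfopart.R recover   --out report.csv --reps 50 --seed 5
Rscript inst/cli/nrfopart.R demo
```

Time courses are long-format CSV
(`setup_id,strain,replicate,time_h,analyte,value,unit`; analytes
`Fe2, NO3, NO2, N2O`, mM). Every output embeds provenance (inputs, seed,
config hash, version) and is byte-identical under a fixed seed.

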