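# fluxkin

Expression-constrained metabolic flux analysis and enzyme-inhibition
kinetics, built around the computational workflow of a DHODH-inhibitor
study: what happens to pyrimidine de novo synthesis when dihydroorotate
dehydrogenase (DHODH) is pharmacologically suppressed, which gene
knockouts would push the perturbed metabolic state back toward baseline,
and how the inhibitor itself behaves in vitro (potency, mechanism,
target engagement).

It is aimed at computational biologists who want the individual method
steps — model curation, GPR-based expression integration, FVA,
MOMA knockouts, IC50/Ki fitting, thermal-shift analysis — as tested,
composable R functions rather than a monolithic black box.

## What it computes

**Constraint-based side.** A metabolic model (stoichiometry `S`, flux
bounds, GPR rules, biomass objective `c`) is curated by dead-end
elimination and sink insertion, then constrained per sample by

    lb(i) ← lb(i) · γ · expr(i),   ub(i) ← ub(i) · γ · expr(i)

where `expr(i)` is the sample's normalized expression mapped through the
reaction's GPR (AND → min, OR → max by default) and `γ = 2`. Flux
variability analysis solves, for every reaction i,

    min / max  v_i
    s.t.  c'v = α·f_max ,  S v = 0 ,  lb ≤ v ≤ ub

with `α = 1` (biomass pinned at its optimum `f_max`). Treated and
control FVA intervals are summarized by midpoints and compared as fold
changes. Gene knockouts are predicted by MOMA
(`min ‖v − v_ref‖²` subject to the same constraints plus zeroed
reactions) and ranked by a worst-case transformation score
(`min` of MOMA-based and FBA-based scores) measuring how far each
knockout moves the treated flux state toward the control state.

**Kinetics side.** Dose–response curves are fitted to
`V = Vmax / (1 + (I/IC50)^h)`; competitive inhibitors are recognized by
an IC50 that rises with substrate (`IC50 = Ki(1 + S/Km)`, Cheng–Prusoff)
and uncompetitive ones by the falling trend (`Ki(1 + Km/S)`); melting
temperatures come from the 350/330 nm fluorescence ratio by derivative
or Boltzmann-sigmoid methods, with ΔTm = Tm(holo) − Tm(apo).

All inputs are also producible synthetically: a 16-reaction toy
pyrimidine network (de novo + salvage + glycolysis + glutathione),
condition-labeled expression profiles, assay tables and melt curves.

## Worked example

A 5-fold DHODH knockdown (expression effect 0.2) in the toy network,
integrated at γ = 2 and analyzed by FVA at α = 1:

```r
library(fluxkin)

model <- build_toy_pyrimidine_model()
model
#> Metabolic model: 16 reactions, 12 metabolites, 9 genes
#>   objective: BIOMASS
#>   sink reactions: 2

profiles <- simulate_expression_profiles(model, c(DHODH = 0.2),
                                         noise_cv = 0, n_replicates = 1)
rep <- run_differential_flux(model, profiles, out_dir = "out",
                             gamma = 2, alpha = 1)
head(rep$table[order(rep$table$fold_change),
               c("reaction_id", "control_mid", "treated_mid",
                 "fold_change", "flag")], 5)
#>   reaction_id control_mid treated_mid fold_change flag
#> 9    sink_oro         6.2           0    4.19e-06   ok
#> 2         CAD        12.2           4    3.28e-01   ok
#> 3       DHODH        12.2           4    3.28e-01   ok
#> 4         ETC        12.2           4    3.28e-01   ok
#> 5        UMPS        11.0           4    3.64e-01   ok
```

The knockdown collapses flux through the whole de novo branch (DHODH
fold change 0.33) and shuts the orotate sink (net orotate overflow drops
to zero), while the salvage branch compensates upward — the same
directional signature the treated-versus-control comparison is designed
to reveal. Ranking knockouts of the treated state
(`run_knockout_screen()`) puts the salvage kinase gene `UCK2` first: it
is the knockout that best reverts the compensatory flux.

On the kinetics side:

```r
I <- c(0, 10^seq(-1, 3, length.out = 8))
fit <- fit_dose_response(I, 100 / (1 + I / 10))
fit
#> Dose-response fit: Vmax = 100, IC50 = 10 uM, h = 1 (RSS 5.39e-29)

classify_inhibition_mode(S = c(100, 1000), ic50 = c(3.67, 18.7), Km = 120)
#> Inhibition mode: competitive (IC50 fold shift 5.1 over S = 100 -> 1000 uM)
#>   Cheng-Prusoff Ki = 2.003 uM (Km = 120 uM)
```

The IC50 grows with substrate concentration, so the inhibitor competes
with the substrate for the site, and the two measurements agree on a
single Ki — the internal consistency check for a competitive call.

A thin command-line wrapper over the same functions ships at
`inst/scripts/fluxkin_cli.R` (subcommands `simulate`, `diff-flux`,
`knockout-screen`, `kinetics`).

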