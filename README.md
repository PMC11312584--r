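# luxscreen

Analysis of dual-luciferase reporter screens for selective protein-production
boosters — and a calibrated simulator of the underlying plate assays.

## The problem

A Firefly luciferase (FF) fused to a protein of interest is co-expressed
with a free Renilla luciferase (REN) control, first across a library of
yeast *ribosomal variant strains* (each heterozygously depleted for one
ribosomal-protein gene, 137 genes = 19 single-copy + 59 duplicated pairs,
of which 9 deletions are non-viable, leaving 128 strains + 1 wild-type
vehicle), then in small-molecule dose panels. The screen looks for
*selective* perturbations: FF up, REN unchanged. luxscreen is for screening
groups who need this analysis reproducible end to end — readout validation,
outlier QC, normalization, hit calling, compound triage — plus a synthetic
generator so the whole pipeline is testable without instrument data.

## The model in brief

Counts are multiplicative-lognormal around calibrated wild-type means
($1.0\times10^4$ FF / $8.0\times10^7$ REN counts for the screen assay;
$2.5\times10^3$ / $1.7\times10^5$ for the homogeneous compound assay), with
per-measurement CV 0.24 split between culture-level and technical noise.
Readouts are screened per group with the two-sided Grubbs test
($G = \max_i |x_i-\bar x|/s$ against
$\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/2n,\,n-2}/(n-2+t^2)}$), applied on
log counts. Each strain becomes a point
$(\mathrm{FF}_\text{fold}, \mathrm{REN}_\text{fold})$ of means normalized
to the wild type; strains within the inert circle of radius
$r = 2\,\mathrm{SD}(\text{normalized WT FF}) \approx 0.48$ around $(1,1)$
are unchanged, and a **selective hit** needs
$\mathrm{FF}_\text{fold}-1 > r$ with $q_\mathrm{FF}\le\alpha$ while REN
stays inside its band with $q_\mathrm{REN}>\alpha$ (BH-adjusted
hierarchical tests on log counts). Compounds are normalized to the
untreated control per dose; activity requires a significant top-dose FF
increase **and** a significant positive trend of log signal vs
$\log_{10}$ dose, with REN deciding selective vs minor. See the vignette
(`vignettes/dual-reporter-screening.Rmd`) for assumptions and design
rationale.

## Worked example

```r
library(luxscreen)

manifest <- library_manifest()            # 137 strains, 129 usable vehicles
table <- simulate_screen(manifest,
                         list(effect_spec("RPL40A", ff_multiplier = 2.7)),
                         sim_config(seed = 1))
res <- run_screen(table, manifest)
res
#> Dual-luciferase screen result
#>   vehicles analysed: 128 strains + WT
#>   reporter concordance rho: 0.485
#>   inert radius: 0.501 (50.1%)
#>   classes: inert=124, q1_ren_up=0, q2_both_up=3, q3_ff_up=0, q4_both_down=0, selective_hit=1
#>   selective hits: RPL40A
```

The planted strain (FF raised 2.7-fold, REN untouched) is recovered as the
sole selective hit; the reporter concordance ρ = 0.485 reflects the
culture-level noise both reporters share; the estimated inert radius
(0.501, i.e. ~50%) sits at twice the per-measurement CV; 124 of 128
strains are inert, 3 moved both reporters up, none is a false selective
hit. `tidy(res)` gives the per-strain table, `glance(res)` the one-row
summary, `autoplot(res)` the fold-space correlation plot.

The compound stage mirrors this:

```r
cfg <- sim_config(assay = "dual_glo", seed = 1)
panel <- simulate_dose_panel(default_panel_compounds(29), cfg)
run_compound_panel(panel)
#> Compound dose-panel result
#>   compounds: 29
#>   classes: selective_hit=1, minor_active=2, inactive=26
#>   active: C17, C25, C7
```

The panel plants one selective compound (C17: FF 1.7-fold at the 100 µM
top dose, REN flat), two unselective actives (C7, C25) and 26 nulls, and
the triage recovers exactly that composition for this seed.

A thin command-line wrapper covers the same pipelines:

```sh
exec/luxscreen simulate-screen --out sim --seed 1
exec/luxscreen analyze-screen --readouts sim/readouts.csv \
    --manifest sim/manifest.csv --out analysis
```

`analyze-*` subcommands write a CSV report, a JSON run summary (ρ, radius,
class counts, hit list, exclusions) and a plot.

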