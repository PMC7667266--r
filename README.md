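# chelscreen

Screening of metal-ion chelating agents by conditional stability constants.

## The problem

Soil-washing remediation (and, more generally, any metal-scavenging
application) needs a quick, defensible answer to the question: *which
chelator, at which pH and at which dose, will actually strip a given metal
ion from solution?* Running titrations or full speciation studies for every
candidate ligand is slow and expensive. But for the polyamino carboxylic
chelators used in practice (EDTA, NTA, EDDS, GLDA, ...) two sets of numbers
are already tabulated in the stability-constant literature: the ligand's
cumulative protonation constants and the 1:1 metal–ligand formation
constant. `chelscreen` turns those numbers into decision tables.

## The method

For the equilibrium M + L ⇌ ML with totals M₀ and L₀ = R·M₀, the effective
(conditional) constant needed to drive a fraction *f* = [ML]/M₀ of the metal
into the complex is

    K_req(f) = f / (M₀ · (R − f) · (1 − f))

Protons compete with the metal for the ligand's basic sites. The ligand
side-reaction polynomial

    D(H) = 1 + Σⱼ βⱼ [H⁺]ʲ      (βⱼ: cumulative protonation constants)

discounts the stoichiometric constant into the pH-dependent effective
constant, log β_eff(pH) = log β_ML − log D(H). Screening reduces to the
curve

    F(H) = log D(H) + log K_req(f)

whose intersection with the horizontal line log β_ML is the pH at which the
fraction *f* is reached. The interval between the 25 % and 99 %
intersections is the pair's **complexation window**; tabulating it over a
panel of metals and ligands is the screen. A closed-form speciation engine
(M, ML, LHⱼ, optional mononuclear M(OH)ₖ) reproduces the corresponding
distribution diagrams, and mg/kg soil-contamination levels convert to
suspension molarities (level / atomic weight, at 1 kg soil per litre) to
build realistic scenarios.

## Worked example

Cadmium against NTA (log β_CdNTA = 9.8) in the reference scenario
M₀ = 2×10⁻⁵ mol/L, R = 50:

```r
library(chelscreen)
db <- builtin_table4()
complexation_window(db, "Cd", "NTA", scenario())
#> <window Cd-NTA: 2.79-5.05>
#>     f   ph status
#>  0.25 2.79     ok
#>  0.50 3.15     ok
#>  0.75 3.57     ok
#>  0.99 5.05     ok
```

Read: a quarter of the cadmium is complexed at pH 2.79, half at 3.15, and
essentially all (99 %) by pH 5.05 — NTA is useful for Cd from mildly acidic
conditions upward. The full screen over the classic eight-metal,
five-ligand panel:

```r
scr <- screen(db, metals = c("Fe","Hg","Cu","Pb","Zn","Cd","Mn","Ca"),
              ligands = c("NTA","HIMDA","EDDG","EDDS","EDTA"))
format_screen_text(scr)
#> metal  NTA        HIMDA      EDDG         EDDS       EDTA
#> Fe     0.30-1.15  1.13-2.30  2.68-3.37    1.60-2.12  <0-0.28
#> Hg     1.12-2.10  5.64-8.29  2.43-3.09    3.10-3.94  0.43-1.06
#> Cu     1.31-2.38  1.09-2.22  3.55-4.43    1.99-2.59  1.27-1.95
#> Pb     1.94-3.55  2.10-4.15  5.12-6.40    4.20-5.37  1.48-2.18
#> Zn     2.26-4.18  3.15-5.57  4.40-5.53    3.35-4.29  1.90-2.70
#> Cd     2.79-5.05  3.91-6.39  5.05-6.32    4.65-5.88  1.90-2.70
#> Mn     4.93-7.41  5.57-8.19  6.07-7.78    5.47-6.82  2.74-3.83
#> Ca     5.80-8.29  6.54-n.a.  > 10.0-n.a.  8.08-n.a.  4.13-5.39
```

Rows are ordered by how early (in pH) the reference ligand binds each
metal; `n.a.` marks fractions unattainable at any pH under the scenario,
`> 10.0` and `<0` mark crossings beyond the display range. EDTA's columns
sit lowest for essentially every metal — it is the strongest generalist —
while HIMDA's weak windows disqualify it for remediation. Soil arithmetic:

```r
soil_to_molar(530, 200.59)   # Hg at its intervention level, 1 kg soil / L
#> 2.642205                   # ~2.6 mM in the washing suspension
```

A command-line interface wraps the same functions
(`required-k`, `curve`, `window`, `screen`, `speciate`, `soil`,
`db-validate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/chelscreen.R", package="chelscreen"))')" \
    soil --metal Hg --level 530
#> Hg 530 mg/kg (x 1 kg/L) -> 2.6 mM
```

## Scope

1:1 ML complexes only, concentration scale, no activity or medium
corrections, no solids, no polynuclear species, no soil-matrix competition
(optional mononuclear hydroxide competition is supported when hydrolysis
constants are supplied). See the methods vignette
(`vignettes/chelator-screening.Rmd`) for assumptions, numerical choices and
limitations.
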