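---
title: "Screening chelating agents by conditional stability constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chelating agents by conditional stability constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelscreen)
```

## The model

`chelscreen` answers a screening question: given literature protonation and
complex-formation constants, at which pH — and with how much ligand — does a
chelator bind a target metal ion? Everything rests on three relations.

**Required constant.** For M + L ⇌ ML with total metal M₀ and total ligand
L₀ = R·M₀, the equilibrium constant written in totals,
K = [ML] / ((L₀ − [ML])(M₀ − [ML])), rearranges for a target complexed
fraction f = [ML]/M₀ into

$$K_\mathrm{req}(f) = \frac{f}{M_0\,(R - f)\,(1 - f)}.$$

It rises steeply as f → 1 (the last percent of metal is the hardest to
capture) and falls with ligand excess R and with concentration M₀ — dilute
problems are intrinsically harder.

**Proton side reaction.** A polyprotic ligand is mostly protonated at low
pH. With cumulative protonation constants $\beta_j$ for L + jH⁺ ⇌ LH$_j$,
the fraction of uncomplexed ligand that is actually free is $1/D(H)$ with

$$D(H) = 1 + \sum_{j=1}^{n} \beta_j\,[\mathrm{H}^+]^j,$$

the familiar side-reaction coefficient $\alpha_{L(H)}$ of conditional-
constant titration theory. The conditional constant available at a given pH
is therefore

$$\log \beta_\mathrm{eff}(\mathrm{pH}) = \log \beta_{ML} - \log D(H).$$

One published presentation typesets this relation as a product
($\beta_\mathrm{eff} = \beta_{LM} D(H)$), but its own worked example
(log β_eff = 2.53 at pH 2.79, where log D = 7.27 and log β_CdNTA = 9.8) is
only consistent with the quotient; the quotient convention is what this
package implements.

**The screening curve.** Complexation of a fraction f happens where
$\log \beta_\mathrm{eff}(\mathrm{pH}) = \log K_\mathrm{req}(f)$,
i.e. where the curve

$$F(H) = \log D(H) + \log K_\mathrm{req}(f)$$

crosses the horizontal line $\log \beta_{ML}$. Since log D is strictly
decreasing in pH the crossing is unique, and curves for different f are
exact vertical translations of one another. The 25–99 % crossing interval
is reported as the pair's *complexation window*; a matrix of windows over a
metal and ligand panel is the screen.

```{r fh-example, fig.width = 6.5, fig.height = 4.5, eval = FALSE}
db <- builtin_table4()
plot_fh_curves(db, "NTA", scenario(), metals = c("Fe", "Cd", "Ca"))
```

## Parameters that matter

* `m_total` (M₀, mol/L): total metal in the washing solution. Default
  `2e-5` — the reference screening condition used throughout the bundled
  tables, representative of a dilute contaminated suspension.
* `ratio` (R = L₀/M₀, dimensionless): chelator dosing. Default `50`, a
  comfortable excess; `min_ratio_for_fraction()` inverts the model to find
  the smallest dose achieving a target, which is the economically
  interesting direction.
* `target_fractions`: defaults to 25/50/75/99 %. The 25 % boundary ranks
  ligands ("where does binding start"), the 99 % boundary marks practical
  completeness.
* `p_kw` (speciation only): −log₁₀ of the water ionic product, default
  14.00 at the 25 °C convention of the bundled constants; configurable
  because published hydrolysis constants are medium-dependent.
* Display cap/floor (`cap = 10`, `floor = 0`): windows beyond these pH
  values are reported as `"> 10.0"` / `"<0"` in formatted tables, the
  convention of printed screening tables; raw numbers stay available.

## The bundled constants and their media

`builtin_table4()` ships nine amino carboxylic chelators and ten metals
with 65 formation constants collected from the critical literature. The
sources span ionic strengths 0.1–1.0 M and 20–30 °C. **No thermodynamic
correction between media is applied**: the constants are compared as
printed, which is the screening method's own pragmatic stance, and
`screen()` emits a note whenever a comparison mixes media. Five atomic
weights (Hg, Cd, Pb, Cu, Ni) are the regulatory-table values; the remaining
five are standard IUPAC weights supplied by this package. Pairs without a
literature constant are *absent records*: screening skips them rather than
guessing. No hydrolysis constants are bundled — the sources commonly used
for them are compilations users should cite themselves — so hydroxide
competition is off unless `metal_record(hydrolysis = ...)` is provided.

## Numerical choices

* **log-sum-exp evaluation of log D.** Cumulative constants reach ~30 and
  the solvers probe pH −2, so β_j[H]^j spans hundreds of orders of
  magnitude; D(H) is evaluated as a base-10 log-sum-exp and never
  overflows.
* **Cancellation-safe quadratic.** The 1:1 mass-balance system reduces to
  x² − (L₀ + M₀ + 1/β_cond)x + L₀M₀ = 0 for x = [ML]; the smaller root is
  computed as 2L₀M₀ / (s + √(s² − 4L₀M₀)), stable across the ~20 orders of
  magnitude β_cond takes over a screen, and degrading gracefully to x = 0
  as β_cond → 0.
* **Bisection on [−2, 14], |ΔpH| ≤ 10⁻⁴.** The bracket covers windows that
  begin below pH 0 (strong Fe³⁺ binders). Outcomes outside the bracket are
  *typed*, not thrown: `unattainable` (the constant is below the
  requirement — no pH helps), `below_range`, `above_range`.
* **Closed-form speciation.** At each grid point the conditional constant
  β_cond = β_ML /(D(H)·α_M(OH)) folds both side reactions into one
  quadratic; free metal and ligand are back-substituted and distributed
  over LH_j and M(OH)_k. Mass balances then hold to floating-point
  accuracy by construction (the validation suite demands ≤ 10⁻⁹ relative).
  An independent damped fixed-point solver of the two balances exists in
  the test suite as an oracle; the package itself never iterates, which
  keeps output deterministic and fast.
* **Rounding discipline.** pH and log values print to 2 decimals,
  millimolar soil concentrations to 1 decimal; all formatting funnels
  through the same helpers so tables reproduce identically across runs.
* **Default pH grid** for speciation: 0–14 in 0.01 steps, the visual
  resolution of published distribution diagrams.

## The synthetic ligand generator

Property tests run on randomly generated but chemically plausible ligands:
`synthesize_ligand(seed, n)` draws n stepwise protonation constants
uniformly in [1, 11] and sorts them into normal ordering (each successive
protonation harder than the last), then accumulates. This emulates the
shape of real polyamino carboxylic acids — a basic amine step followed by
progressively weaker carboxylate steps — but deliberately not their
chemistry: no electrostatic correlation between steps, no medium effects,
no relation between protonation behaviour and metal affinity. Tests passing
on these fixtures therefore demonstrate numerical correctness (mass
balance, monotonicity, inversion, overflow safety) on realistic magnitudes;
they say nothing about the accuracy of any particular literature constant.

## Design decisions taken where the design was open

* **Species set**: M, L, LH_j, ML, plus optional mononuclear M(OH)_k only.
  No protonated complexes MLH, no ternary ML(OH), no polynuclear hydroxides,
  no solids. That is the assumption under which the screening algebra is
  exact; for ligands known to form protonated complexes (HIMDA with Fe³⁺,
  for instance) the window is an approximation.
* **Cumulative storage.** Constants are stored as cumulative log β exactly
  as compilations print them; `stepwise_log_k()` derives stepwise values
  one-way. This avoids silent re-derivation errors when databases are
  round-tripped.
* **Ten metals.** The screening tables use nine metals; Ni carries no
  formation constants but is included for the regulatory soil arithmetic,
  where it appears with its intervention and target levels.
* **Ranking key**: the 25 % boundary, tie-broken by window width (narrower
  = stronger). This matches the qualitative reading that a lower onset pH
  means a stronger chelator.
* **Row order of screens**: ascending 25 % boundary of a reference ligand
  (first ligand of the panel by default), so the most easily bound metal
  (Fe³⁺ in the bundled data) comes first.

## Known limitations, and two data caveats

The model neglects everything the screening method itself neglects:
competition by soil organic matter and mineral surfaces, precipitation,
kinetics, multi-metal competition in one solution (each pair is screened
independently), ionic-strength and temperature corrections, and
biodegradability or toxicity of the ligand. Windows computed here are
*optimistic bounds*: a ligand that fails the screen will not work in the
field; one that passes still needs bench confirmation.

Two caveats on the reference data shipped with the package. First, the
published screening table that the bundled constants reproduce was
evidently compiled partly by reading intersections off plots: its HIMDA
column is internally inconsistent (two metals with different constants are
printed with identical windows), and recomputation from the printed
constants shifts those cells by up to ~0.3 pH. The package follows the
mathematics. Second, one published narration quotes 75 % complexation of
Cd–NTA at pH 3.87 from a speciation plot while the same system's F(H)
analysis gives 3.58; the two quantities are identical by construction, and
this package computes ≈3.57 from either route.

## Problem sizes used in the validation suite

The test suite checks mass-balance conservation and the closed-form-versus-
iterative-oracle agreement on 200 randomly generated speciation systems at
29 grid points each, inversion consistency on 100 random ligand/scenario
draws, and full-resolution (1401-point) grids for the reference cadmium
system — sizes chosen to exercise every code path at interactive runtimes.
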