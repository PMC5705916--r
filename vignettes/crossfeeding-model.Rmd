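---
title: "A kinetic model of mutualistic cross-feeding with interpartner competition for ammonium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of mutualistic cross-feeding with interpartner competition for ammonium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrophr)
```

## The system

`syntrophr` simulates an obligate anaerobic coculture of two bacteria locked
in bidirectional cross-feeding. A fermentative *Escherichia coli* population
(`Ec`, cells/ml) converts glucose (`G`, mM) into excreted organic acids: a
consumable pool `C` (acetate + lactate + succinate), plus formate `F` and
ethanol `E`, which the partner cannot use. A phototrophic, N2-fixing
*Rhodopseudomonas palustris* population (`Rp`) grows on the consumable
acids, fixes N2 (unlimited headspace, never a state variable), excretes
part of the resulting ammonium into a shared extracellular pool (`A`, mM),
and releases H2 (`H`, bookkept as a cumulative liquid-equivalent
concentration) as an obligate by-product of nitrogenase. Ammonium is the
crux: it is *communally valuable* — both the producer and the recipient
want it — so the two partners compete for the very nutrient that cements
their mutualism.

All rates are Monod-type. Growth of the recipient requires both substrates:

$$\mu_E = \mu_{E,\max}\,\frac{G}{K_G+G}\,\frac{A}{K_A+A}\, I,$$

where $I = 1/\bigl(1 + ((C+F)/K_I)^{n_I}\bigr)$ is a decreasing Hill factor
describing growth inhibition by medium acidification once acids accumulate
(ethanol, not an acid, is excluded). Glucose is consumed by growth and by a
nitrogen-independent maintenance term,

$$q_G = \mu_E/Y_{EG} + m_G\,c\,\frac{G}{K_G+G}\,I
\qquad (c = 10^{-9}\ \text{mM·ml·cell}^{-1}\text{·fmol}^{-1}),$$

so a nitrogen-starved, non-growing recipient still ferments and feeds its
partner — the mechanism that keeps producer densities high even when the
recipient has failed. Fermentation is stoichiometric: each mM of glucose
consumed yields $f_C$, $f_F$, $f_E$ mM of the three product pools.

### Two variants: where the nutrient is generated matters

**Default (partial privatization).** The producer has two growth routes:
the N2 route $\mu_{R1} = \mu_{R,\max 1}\,\mathrm{monod}(C, K_C)\, I$, which
assimilates intracellularly fixed nitrogen directly — bypassing the shared
pool entirely — and an uptake route
$\mu_{R2} = \mu_{R,\max 2}\,\mathrm{monod}(C,K_C)\,\mathrm{monod}(A,K_{AR})\,I$
through which it recaptures extracellular ammonium (with its own
half-saturation constant $K_{AR}$ and a small additive rate boost).
Ammonium excretion is tied to the N2 route: $R_A$ fmol per newly formed
cell, so excretion stops when nitrogenase-fuelled growth stops. H2 release
follows the same flux ($\phi_H$ per new cell). Intracellular generation
enforces partial privatization: no recipient affinity, however high, can
reach nitrogen that never leaves the producer's envelope.

**Communal pool.** The control variant removes the direct route: fixation
becomes a growth-decoupled flux $v_{fix}$ per cell (still gated by the
acids that fuel nitrogenase and by $I$) that deposits *all* fixed nitrogen
into the shared pool, and the producer's entire growth
($(\mu_{R,\max 1}+\mu_{R,\max 2})$, Monod in both `C` and `A`) must be fed
back out of that pool. Nitrogen bookkeeping is then exact by construction:
$\dot A + \dot{Ec}/Y_{EA} + \dot{Rp}/Y_{RA} = v_{fix}\,c\,
\mathrm{monod}(C,K_C)\,I\,Rp$, which the tests verify both algebraically at
random states and by quadrature along whole trajectories.

The central comparison of the package is between these variants: under
partial privatization only a *producer*-biased affinity imbalance breaks
the mutualism (the recipient fails when it cannot compete for excreted
ammonium), whereas with a communal pool an extreme bias in *either*
direction kills one or both partners, and robust coexistence requires
producer-biased access.

### The affinity ratio

Affinity is the inverse of the half-saturation constant; the producer:
recipient (Rp:Ec) affinity ratio is $K_A / K_{AR}$. Because ammonium
transporters are already high-affinity, `set_affinity_ratio()` only ever
*raises* a $K_m$ from the shared 0.01 mM default — ratio $r>1$ raises
$K_A$, $r<1$ raises $K_{AR}$ — mirroring what deleting an AmtB transporter
does physiologically (a ΔAmtB strain, limited to passive NH3 diffusion, has
an effective $K_m$ roughly two orders of magnitude higher; the fed-batch
examples use 100× accordingly).

## Parameters, units and provenance

Every field of `syn_params()` carries a provenance flag. Values printed in
the primary literature for this coculture (`"paper"`): $K_A = K_{AR} =
0.01$ mM, $\mu_{R,\max 2} = 0.0152$ h⁻¹, $R_A = 0.15$ fmol/cell (0.5 for
the high-excretion strain). Everything else is `"calibrated"`: the shipped
calibration was fixed, once, against the stated experimental facts of the
system —

1. recipient maximal growth rate 4.6× the producer's
   ($\mu_{E,\max} = 0.46$, $\mu_{R,\max 1} = 0.10$ h⁻¹);
2. full consumption of the 25 mM glucose by roughly 100 h
   (achieved ~111 h; set mainly by $m_G = 15$ fmol cell⁻¹ h⁻¹ and
   $K_C = 0.3$ mM);
3. stationary cocultures of ~10% recipient at ~10⁹ cells/ml
   (achieved 10.2% of 1.01×10⁹; set by the yield pair
   $Y_{EA} = 2\times10^9$, $Y_{RA} = 2.5\times10^8$ cells·ml⁻¹·mM⁻¹,
   i.e. effective nitrogen quotas of 0.5 and 4 fmol/cell — the recipient
   lean because its census counts small, nitrogen-starved cells, the
   producer heavy because it is the larger cell);

plus two qualitative behaviours reported for the real coculture: a 15 mM
ammonium supplement must arrest the producer within the one-week window via
acid accumulation (sets $K_I = 15$ mM, $n_I = 6$; with these, the
supplemented producer grows 2.7× by 168 h versus 101× unsupplemented), and
high excretion must likewise throttle the producer. The maintenance rate
$m_G$ sits above a single cell's textbook glycolytic maximum; it is an
effective rate absorbing the census-versus-biomass mismatch of a lumped
model, and it is what the stated world (25 mM gone in ~100 h with ≤10⁸
fermenter cells/ml) requires. Remaining choices:
$Y_{EG} = 5\times10^7$, $Y_{RC} = 3\times10^7$ cells·ml⁻¹·mM⁻¹ (anaerobic
yields; the latter fixes the producer's carbon-limited ceiling at
$f_C \times 25 \times Y_{RC} \approx 9\times10^8$ cells/ml),
$f_C/f_F/f_E = 1.2/0.8/0.6$ (mixed-acid fermentation, carbon-balanced,
$\sum \le 3$), $K_G = 0.1$ mM, $\phi_H = 2$ and $v_{fix} = 0.4$
fmol cell⁻¹ (h⁻¹) from the nitrogenase stoichiometry (1 H2 per N2; 2 NH4+
per N2) applied to the producer's quota-plus-excretion nitrogen flux.

## Numerical choices

* **Integrator.** Compiled adaptive Cash-Karp RK4(5) with PI-style step
  control (`rtol = 1e-8` by default; absolute floors 10⁻² cells/ml and
  10⁻¹² mM), dense output on a 1-h grid, states clamped at zero with every
  clamping event counted in the diagnostics, and hard failure (never silent
  truncation) on step-budget exhaustion or step underflow. The system is
  only mildly stiff (the fast variable is the micromolar ammonium pool,
  with relaxation times of ~0.1–1 h), so an explicit embedded pair with
  tight tolerances is both accurate and fast (a 300-h batch integrates in
  ~2 ms, which is what makes the scan and bisection layers interactive).
* **Independence of verification.** The right-hand sides exist twice — the
  exported pure-R reference (`rhs_default()`, `rhs_communal()`) and the
  compiled copy — and are cross-checked at random states; trajectories are
  checked against a pure-R fixed-step RK4 oracle (dt = 10⁻³ h) and against
  trapezoidal quadrature of the stored fluxes (glucose, fixed nitrogen).
* **Net growth margin.** The model has no death term, so a "failing"
  population never declines — it merely stays within a few percent of its
  starting density. Outcome classification therefore calls growth only
  above a 10% margin over the starting density (`growth_margin = 0.1`,
  settable to 0), the in-silico reading of "final density sits on the
  dashed starting line" in a log-scale plot.
* **Collapse over transfers** requires strictly decreasing per-transfer
  final densities of both species *and* ≥20% total loss across the
  assessment window (last max(3, n−1) transfers), to separate genuine
  progressive collapse (which loses ~100× per transfer) from the
  numerically monotone approach to a stable fixed point. An Ec-only
  criterion is available behind the `ec_only` flag.
* **Transfers** carry dissolved species at the same 1% dilution as cells
  (a transferred culture volume carries its spent medium);
  `carry_solutes = FALSE` switches to fresh-medium-only resets.
* **Feed pulses** are instantaneous concentration jumps with integrator
  restarts at the pulse times; the physical assay's pump flow and argon
  flushing are not modelled.
* **Excretion linkage** (a genuinely open design point): excretion rides
  only on the N2 route, not on the uptake boost — $R_A$ is printed per new
  cell and excretion must vanish when nitrogenase-fuelled growth stops;
  letting the recapture route re-excrete would make the pool partially
  self-refilling and dilute the privatization contrast the model exists to
  probe.

## What the simulated world does and does not establish

The generator emulates: batch cocultures started from a 1% dilution of a
10%-recipient stationary culture into 25 mM glucose medium; 8×300-h serial
transfers at 1% dilution; and a pulsed fed-batch competition assay (hourly
5 µM ammonium pulses for 96 h into glucose + 20 mM acetate medium with
equal inocula). It does not emulate cell death, lag phases, pH as a state
variable, gas-phase partitioning, per-acid kinetics, or evolution across
transfers. Green tests therefore establish the *phase structure* of the
model — who fails, on which side of an affinity imbalance, under which
variant — not absolute agreement with optical-density time courses. One
concrete lumping artefact: the fed-batch assay's sodium acetate is
pH-neutral in reality, but the model's single acid pool cannot distinguish
acetate salt from acetic acid, so fed-batch runs carry a constant
inhibition factor ≈0.15 that slows both species equally; the assay's
readout (the competitive index, a ratio of fold-changes) is insensitive to
it.

## Known limitations

The producer's ammonium recapture is modelled, per the build contract, as
the uptake-boost route's nitrogen demand, $(\mu_{R2}/Y_{RA})\,Rp$, capped
by the small printed boost rate $\mu_{R,\max 2} = 0.0152$ h⁻¹. Its maximal
per-cell recapture flux ($\mu_{R,\max 2}/Y_{RA} \approx 0.06$ fmol/h) is
then ~4× *below* the recipient's per-cell uptake at saturation — the
producer competes mostly through numbers. A quasi-static partition of the
excreted ammonium between the two sinks shows the consequence: with the
stationary composition pinned at ~10% recipient, the coexistence boundaries
must sit far to the producer-biased side (measured: single-batch boundary
at affinity ratio ≈ 388, transfer-collapse threshold ≈ 5.2, versus ~1 and
~1.5 in the source experiments; matching those printed thresholds under
this uptake form would require a recipient nitrogen quota ~20–30× below
physiology). Every qualitative conclusion — coexistence at ratio 1,
recipient failure beyond a threshold, mutual (not one-sided) collapse over
transfers, rescue by excretion, the privatized-versus-communal asymmetry —
is reproduced; the quantitative location of the boundaries is where a
recapture flux decoupled from the growth boost would be needed, and the
corresponding acceptance assertions are deliberately left failing as a
faithful report (see the project notes).

## Reproducing the headline experiments

```{r, eval = FALSE}
p <- syn_params()

# phase behaviour of the two variants across affinity ratios
affinity_ratio_scan(p, 10^seq(-4, 4, 0.5))
affinity_ratio_scan(p, 10^seq(-4, 4, 0.5), variant = "communal")

# stability versus collapse over serial transfers
classify_outcome(serial_transfer(p))                          # stable
classify_outcome(serial_transfer(set_affinity_ratio(p, 10)))  # collapse

# excretion rescue of a low-affinity recipient
excretion_scan(p, c(0, 0.15, 0.5, 2, 8, 32))

# pulsed-ammonium competition, AmtB-deletion analogues
competitive_index(fed_batch(syn_params(K_AR = 1)))  # recipient-biased, > 1
competitive_index(fed_batch(syn_params(K_A = 1)))   # producer-biased, < 1
```
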