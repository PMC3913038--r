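---
title: "Models and methods behind ldbridges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ldbridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldbridges)
```

ldbridges implements the quantitative toolbox needed to study how proteins
reach the lipid droplet (LD) surface: a random-placement null for
colocalization of punctate protein signals with LDs, a diffusion-limited
kinetic model of ER-to-LD targeting through membrane bridges, FRAP-based
diffusion estimation, drop-weight tensiometry, and LD size-distribution
summaries. This vignette records the models, their assumptions, the defaults,
and the numerical decisions, in that order of importance.

## The binomial colocalization null

Fluorescent protein foci (channel A, radius $r_A$) are compared with LDs
(radius $r_{LD}$) in the same field of area $\mathrm{area}_f$. Under the null
hypothesis the foci fall uniformly at random. A focus whose centre lies
within $r_{LD} + r_A$ of an LD centre overlaps it, so the single-focus hit
probability is the field fraction covered by the LDs after dilating each by
$r_A$:

$$s = \frac{\operatorname{area}\bigl(\bigcup_i \mathrm{disk}(x_i, r_{LD,i} + r_A)\bigr)}{\mathrm{area}_f}.$$

The number of colocalized foci out of $n_A$ is then
$\mathrm{Binomial}(n_A, s)$; its mode $n_s$ is the most probable colocalized
count under randomness, and the observed count $n_\mathrm{exp}$ (the number
of non-positive signed nearest-neighbour distances) is assessed against the
exact tails: *enriched* when $P(X \ge n_\mathrm{exp}) \le \alpha$, *excluded*
when $P(X \le n_\mathrm{exp}) \le \alpha$, else *random-consistent*. The
default $\alpha = 0.01$ matches the significance level used for the
condition-level comparisons.

Three design points deserve note:

* **Union, not sum.** Summing $\pi (r_{LD}+r_A)^2$ over LDs double-counts
  overlaps and can exceed 1 in crowded fields. The package computes the
  rasterized union clipped to the field so $s$ is always a valid
  probability, and attaches the naive sum as the `s_sum` attribute; the two
  agree when LDs are sparse, which is the regime the verdict is designed
  for.
* **Closed boundary.** A signed distance of exactly zero (boundary contact)
  counts as overlap, the convention "negative distances mean overlap" made
  closed. Generation-side planting uses the same centre-to-centre rule, so
  simulated truth and analysis agree by construction.
* **Ties in the mode** are broken toward the smaller count, which is
  conservative for enrichment calls.

`aggregate_fields()` pairs, per field, $n_\mathrm{exp}/n_A$ with $n_s/n_A$
and applies a two-sided paired $t$ test. Because $n_s$ is a mode of a
discrete law, it sits up to about $0.5/n_A$ below the null mean; the test is
therefore only calibrated when fields carry enough expected colocalization
($n_A \cdot s \gg 1$). The test suite demonstrates this with dense
calibration fields (200 foci), and degenerate inputs (identical observed and
null fractions everywhere) raise an explicit degenerate-variance error
rather than a silent NaN. When every field shows the *same nonzero*
difference the paired $t$ statistic diverges; the limit ($t = \pm\infty$,
$p = 0$) is reported rather than refused.

## Bridge kinetics and connection counting

GPAT4-class hairpin proteins reach LDs by diffusing from the ER through
membrane bridges. With ER concentration $C_0$ held constant (the ER is a
large reservoir; depletion is out of scope), the amount $N(t)$ on an LD of
surface $S = 4\pi R^2$ fed by $n_c$ bridges obeys

$$\frac{dN}{dt} = n_c\,k L\,(C_0 - N/S), \qquad k = D/l,$$

where $l$ is the bridge length, $L$ the section length of the bridge, and
$D$ the protein's diffusion coefficient in the ER. The solution is the
saturating exponential $N(t) = C_0 S (1 - e^{-t/\tau})$ with
$\tau = l S / (n_c D L)$. A single bridge would need
$\tau_\mathrm{bulk} = (l/L)\, 4\pi R^2 / D$ (i.e. $8\pi R^2/D$ at the
default $l/L = 2$; the ratio is configurable within its plausible 1.5–3
range), so the observed targeting time converts to a bridge count
$n_c = \tau_\mathrm{bulk}/\tau$. With the experimentally motivated
$\tau = 3.6$ min and bulk times of 21–31 min this gives roughly 5.8–8.6
connections. $\tau_\mathrm{bulk}$ depends on the LD radius actually imaged,
which is not pinned down; `bulk_time()` therefore exposes $R$ (and $D$,
$l/L$) as parameters rather than hard-coding a bulk-time range.

Fitting decisions: the onset lag after cell–cell fusion varies between
experiments (of order 1–25 min), so `fit_targeting()` treats `lag` as a free
parameter instead of requiring a manual onset call; curves are fitted raw
with the plateau free (normalization optional upstream). Time is in minutes,
lengths in µm and $D$ in µm²/s throughout, with the single conversion done
inside `bulk_time()`/`simulate_flux()` — the formulas invite s/min mistakes,
so the conversion lives in exactly one place. Weak identifiability (records
ending mid-rise) is flagged via the tau standard error, not treated as
failure. `estimate_connections()` refuses only when the SE exceeds the
estimate itself.

`simulate_flux()` provides the module's oracle pair: the ODE route
integrates the flux law directly (deSolve, `rtol = 1e-10`) and must agree
with the closed form to within $10^{-6}$ relative; the particle route draws
independent molecules whose first crossing of one of the $n_c$ absorbing
bridges is exponential with rate $1/\tau$ — for a linear flux law with a
constant reservoir this *is* the model's stochastic counterpart — and is
checked against the ODE within Monte-Carlo error.

## FRAP

ER tubules are quasi-one-dimensional, so the package models recovery after a
rectangular bleach of width $w$ and depth $\beta$ as pure 1-D diffusion on
an infinite line. At the bleach centre,

$$F(t) = 1 - \beta\,\operatorname{erf}\!\left(\frac{w}{4\sqrt{D t}}\right),$$

which starts at $1-\beta$ and recovers fully (single mobile pool; an
optional immobile fraction caps recovery at $1 - \beta\,f_\mathrm{imm}$ and
defaults to 0 because near-complete recovery is the observed regime).
Two-dimensional spot models are deliberately out of scope. `fit_frap()`
fits $D$ (and $\beta$) by nonlinear least squares with a diffusive starting
guess from the half-recovery time; it refuses curves recovering less than
10% of the deficit, where $D$ is not meaningfully constrained.

The independent oracle `simulate_frap_fd()` integrates the same physics by
explicit finite differences (grid 0.05 µm, time step at half the FTCS
stability limit, reflecting far boundaries on a 40 µm domain, partial-pixel
initial condition at the bleach edges). Fits to the oracle's output recover
$D$ to well within 5% across the 0.01–0.1 µm²/s decade, which brackets the
~0.035 µm²/s magnitude typical of ER membrane proteins; that magnitude is
used as a default only, since no raw recovery data are bundled.

## Drop-weight tensiometry

When a drop detaches from a tube of inner diameter $d$, its weight balances
the vertical surface-tension force up to the empirical Harkins–Brown factor
$f$: $\gamma = m g / (\pi d f)$ with $m = v\,\Delta\rho$. The factor depends
on $r/V^{1/3}$ (tube radius over cube-root drop volume). The classical
calibration table covers $r/V^{1/3} \in [0.30, 1.20]$ and is embedded
verbatim; interpolation is shape-preserving (Hyman) cubic per monotone
branch, so table nodes are reproduced exactly and interpolants stay between
neighbouring nodes.

Fine tubes at low interfacial tension — a 250 µm tube with
phospholipid-covered oil/water interfaces of a few mN/m, the regime of
interest here — give $r/V^{1/3}$ of order 0.03–0.15, *below* the classical
table. The package extends the curve on $(0, 0.30)$ by the same monotone
interpolation anchored at the thin-tip limit $f(0) = 1$ (for a vanishing
tip, the whole ideal drop detaches). This extension is approximate and is
documented as such; it does not affect the generator–analyzer round trip
(both sides use the same curve), only the absolute calibration in that
regime. Ratios beyond the tabulated domain raise an error naming the valid
range rather than extrapolating.

On the analysis side $f$ follows directly from each measured volume, so no
iteration is needed; the self-consistency (detachment volume depends on $f$
depends on volume) is genuinely implicit only in the *generator*, where
`sim_drop_series()` solves the force balance by bracketed root finding
(relative tolerance $10^{-12}$). Gravity defaults to the standard
9.80665 m/s².

## LD size distributions

`ld_density()` wraps a Gaussian KDE with Silverman's rule-of-thumb bandwidth
(the customary default of stock density functions; configurable) and
renormalizes the evaluated grid to integrate to exactly 1. Modes are local
maxima filtered by **topographic prominence** — height above the deepest
saddle separating a peak from higher terrain — with a floor of 5% of the
global maximum. A pure height floor is not enough: undersmoothed KDEs grow
twin micro-peaks on one true mode, which a prominence criterion removes
without losing genuinely separated modes. The module works in diameters
(µm) throughout.

The three population generators emulate the phenotypes seen in cultured
cells: `bimodal` (75% small LDs, log-normal around 0.4 µm, plus 25% large
expanding LDs around 3.5 µm), `monodisperse` (narrow log-normal with mean
1.3 µm, the Arf1/COPI-depletion phenotype), and `giant` (heavy-tailed
log-normal). These component parameters are descriptive choices, not
measured claims.

## What the synthetic data do and do not emulate

`sim_field()` plants anti-aliased disks (LDs) and puncta (foci) with
additive zero-mean Gaussian noise — the simplest model consistent with
fluorescence readout at realistic SNR. Foci are planted colocalized with
probability `enrichment` using the same overlap rule the analysis applies;
the rest fall uniformly. Particles are rejected-and-resampled to lie fully
inside the field (no periodic boundary), and LDs are kept from mutually
overlapping so each is a resolvable object. Deliberately **not** modelled:
3-D stacks, the microscope PSF (focus intensity profiles are free
parameters, not claims), photobleaching during acquisition, camera-specific
noise, and touching/merging LDs. Consequently, green tests establish the
statistical machinery — calibration of the null, parameter recovery,
oracle agreement — not robustness to segmentation pathologies of real
micrographs. Segmentation itself (Otsu threshold, connected components,
intensity-weighted centroids, equivalent radius $\sqrt{\mathrm{area}/\pi}$,
minimum-area filter) is delegated to EBImage and kept deliberately simple:
touching LDs are not watershed-split because the null model only needs total
dilated area.

## Numerical choices and problem sizes

* Dilated-union raster: 0.05 µm spacing by default (0.01–0.02 µm in
  accuracy-critical tests), with linear edge antialiasing; the union takes
  the per-pixel maximum coverage.
* Nonlinear fits use Levenberg–Marquardt (minpack.lm) with non-negativity
  bounds; the targeting model's kink at `t = lag` is handled by `pmax`, and
  noiseless curves are recovered to $10^{-6}$ relative.
* The verdict calibration studies run on ground-truth tables
  (`render = FALSE`), skipping image synthesis: 1000 uniform fields for the
  type-I rate and Monte-Carlo check of $s$, and 200 fields for power, sizes
  chosen to give tight binomial error bars while keeping the default test
  run fast.
* Seeded runs are bit-reproducible; `run_pipeline()` hashes its config and
  stamps every output with the hash, seed and package version.

## Known limitations

* The binomial null ignores spatial structure beyond area (no clustering or
  exclusion point processes); it tests randomness of placement only.
* The bridge model assumes a constant ER reservoir, time-invariant bridge
  number, and lumps geometry into $l/L$; bridge formation/closure dynamics
  and spatially resolved ER networks are out of scope.
* The Harkins–Brown small-ratio extension is an interpolation to a
  theoretical limit, not a measured calibration.
* The paired field-level $t$ test inherits the mode-vs-mean discreteness
  bias discussed above; prefer many foci per field when near the null.
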