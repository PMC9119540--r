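---
title: "Methods: from fused imagery to continuous daily evapotranspiration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fused imagery to continuous daily evapotranspiration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldET)
```

## The problem

Daily, field-resolving evapotranspiration (ET) maps for irrigated
cropland require three things no single satellite provides: fine spatial
resolution, daily revisit, and a thermal observation on every day.
fieldET chains four components to get there: spatiotemporal image
fusion, a two-source energy balance (TSEB) on clear days, an
evaporative-fraction daily upscaling, and a canopy-resistance
reconstruction for cloudy days. This vignette states each model, its
assumptions, the tunable parameters, and the numerical choices, and is
explicit about what the synthetic test scenes do and do not demonstrate.

## Image fusion

`starfm_fuse()` implements a single-base-pair STARFM-style blend. For a
centre pixel $p$ the prediction on the target date is

$$F_t(p) = F_b(p) + \sum_c w_c\,[C_t(c) - C_b(c)],$$

a weighted mean of the coarse temporal change over spectrally similar
pixels $c$ in a moving window, added to the fine base value. Candidates
must lie within `spectral_tolerance * sd(F_b) / n_classes` of the
centre's base value; weights are inverse products of the fine/coarse
spectral difference, the coarse temporal difference, and relative
distance, normalised per pixel.

Writing the prediction as the *centre* base value plus a weighted
temporal increment (rather than a weighted mean of neighbour base
values plus increments) is a deliberate design choice: it makes two
properties hold exactly rather than approximately — when the two coarse
images agree the output *is* the fine base image, and a uniform coarse
change passes through additively. Both are asserted in the test suite,
along with equivalence against an exhaustive per-pixel reference
implementation on grids up to 15×15.

Defaults (`fusion_params()`): window half-size 12 fine pixels, 4
classes, spectral tolerance multiplier 2, no cap on similar pixels.
These are conventional mid-range choices for fields-scale NDVI/LST
work; the same code path blends both variables, differing only in the
units tag. Coarse images are block-replicated onto the fine grid; no
point-spread function is modelled.

## Clear-day energy balance

Per pixel, with broadband albedo $\alpha$, emissivities
$\varepsilon_a, \varepsilon$, and radiometric temperature $T_{rad}$:

$$R_n = (1-\alpha) S_d + \varepsilon_a \sigma T_a^4
      - \varepsilon \sigma T_{rad}^4$$

is partitioned over leaf area index by Beer's law with extinction
coefficient $k$ (default 0.45, typical for cereal canopies) at the
solar zenith $\theta_z$:
$R_{nc} = R_n [1 - e^{-k\,\mathrm{LAI}/(2\cos\theta_z)}]$, and the soil
heat flux is a fixed fraction $G = 0.35\,R_{ns}$.

The canopy temperature starts from the Priestley–Taylor relation

$$T_c = T_a + \frac{R_{nc}\, r_{a,c}}{\rho C_p}
        \left(1 - \alpha_{PT} f_g \frac{\Delta}{\Delta+\gamma}\right),
  \qquad \alpha_{PT} = 1.26,$$

the soil temperature is recovered from the composite
$T_{rad}^4 = f_c T_c^4 + (1-f_c) T_s^4$, and the sensible heat fluxes
run through a series resistance network:
$H_c = \rho C_p (T_c - T_a)/r_{a,c}$,
$H_s = \rho C_p (T_s - T_a)/(r_{a,c} + r_{a,s})$. If the implied soil
latent heat $LE_s = R_{ns} - G - H_s$ is negative — the unstressed
assumption overestimated transpiration — $\alpha_{PT}$ is stepped down
by 0.1 (configurable) and the pixel re-solved; the step sequence ends
at 0, after which the standard completion sets $LE_s = 0$,
$H_s = R_{ns} - G$, recovers the temperatures from the fluxes, and
flags the pixel. Energy closure is enforced algebraically on every
path, so `tseb_solve()` returns budgets that close to machine
precision; the composite-temperature identity holds exactly on all
non-fallback paths.

Resistances follow the neutral logarithmic profile with displacement
$0.65h$ and roughness $0.125h$, and a soil-surface resistance
$1/(a' + b' u_s)$ with $a' = 0.004$, $b' = 0.012$ and the in-canopy
wind attenuated by $0.45\,\mathrm{LAI}^{2/3}$ over the relative depth
of the canopy. No Monin–Obukhov stability correction is applied; the
neutral form keeps the solver free of a second iteration level and is
adequate for the daytime overpass conditions the pipeline targets.
Canopy height is tied to LAI by a simple allometry
(`canopy_height_from_lai()`, 0.2 m per LAI unit, floor 0.05 m) so both
the generator and the pipeline see identical roughness.

## Daily upscaling and cloudy-day reconstruction

The evaporative fraction $EF = LE/(R_n - G)$ at the overpass is assumed
constant over the daytime, giving $ET_{24} = EF \cdot R_{n24}/L$ with
$L = 2.45$ MJ m⁻² mm⁻¹ and the daily mean soil heat flux taken as
zero. $R_{n24}$ combines the daily shortwave sum with an FAO-56-type
net longwave term (Stefan–Boltzmann on the daily temperature, a vapour
pressure emissivity factor, and a cloudiness factor from the relative
shortwave fraction); the longwave term is switchable because some
forcing sources provide net radiation directly.

For each cloudy day the nearest clear day (earlier on ties, for
determinism) supplies a canopy resistance by inverting Penman–Monteith
at the daily scale — daily-mean $\Delta$, VPD, aerodynamic resistance,
and the daily available energy converted to W m⁻². The cloudy-day
resistance is

$$R_{c,unc} = \frac{\mathrm{LAI}_{clr}\, R_{c,clr}}
  {\mathrm{LAI}_{unc}\; m(T_{min})\; m(\mathrm{VPD})},$$

with linear stress ramps between the cropland thresholds
$T_{min}$: open 285.17 K / close 265.15 K, VPD: open 0.65 kPa / close
4.3 kPa, floored at 0.05 so the reconstruction stays finite when both
scalars saturate. Penman–Monteith then runs forward with the cloudy
day's meteorology. Reconstruction is refused beyond a 5-day gap
(configurable): the leaf-area scaling assumes the resistance-LAI
relation drifts slowly, and beyond several days that assumption — not
the algebra — is the binding error source; such pixels stay nodata
rather than extrapolate.

The daily timestep for the inversion is a design choice the method
leaves open; using daily means on both the inversion and forward side
makes the pair exactly self-inverse, which the tests exploit
(round-trip identity to $10^{-8}$ relative).

## NDVI time series and canopy state

Fused NDVI series carry cloud gaps, so the pipeline linearly
interpolates gaps, then applies a Savitzky–Golay filter (window 15
days, order 3 by default — wide enough to suppress single-scene jitter,
short enough to track green-up; shorter seasons shrink the window
automatically). The filter's edge handling fits shifted full-length
windows, so polynomials up to the order pass through exactly
everywhere. LAI is linear in NDVI (slope 6, intercept −0.6 by default;
a site calibration in real use), fractional cover follows Beer's law
capped at 0.99 so the composite-temperature inversion never divides by
zero, surface emissivity blends 0.98 (vegetation) with 0.95 (soil) by
cover, and broadband albedo either comes from band reflectances
(`broadband_albedo()`) or a linear NDVI darkening
(`albedo_from_ndvi()`) when no reflectances are carried.

## Environmental factor diagnostics

`jarvis_factors()` provides the standard multiplicative [0, 1]
constraint scalars — radiation ramp, soil-moisture ramp between wilting
(0.09) and critical (0.33) moisture, linear VPD decline (0.2 kPa⁻¹),
and a quadratic temperature response centred on the 298 K crop
optimum. They are a sensitivity overlay for stage-wise interpretation
(`stage_summary()`, with a built-in wheat/maize rotation calendar) and
deliberately do not feed back into the ET computation.

## Station validation utilities

Eddy-covariance records typically under-close the energy balance; the
Bowen-ratio correction redistributes $R_n - G$ over $H$ and $LE$ while
preserving their ratio, with nighttime and non-positive-flux records
passed through flagged. Remaining gaps are filled by the mean diurnal
variation method (same time-of-day mean within ±7 days by default).
The correction is applied before filling, and the order is recorded in
the outputs. Agreement metrics follow the usual definitions; the
percent-bias sign convention is $100\,\Sigma(obs - sim)/\Sigma obs$,
so model overestimation gives negative values.

## The synthetic generator: what it shows and what it cannot

`generate_season()` builds a full rotation season on a seeded RNG:
double-logistic NDVI phenology (autumn wheat establishment, spring
regrowth to an April–May peak, harvest, June–September maize), AR(1)
meteorology around a North China Plain annual cycle, scene-level cloud
gaps of bounded length, and coarse scenes as exact block means of the
fine ones.

Truth is constructed *through the model's own forward relations*:
canopy temperature at the unstressed Priestley–Taylor value, soil
temperature from a prescribed wetness field via the soil energy
budget, the radiometric temperature composited from both (with the
radiation budget iterated to its fixed point, under-relaxed at 0.3 to
keep the strongly coupled dry-canopy cases convergent), and cloudy-day
truth built by the same nearest-clear-day resistance reconstruction the
pipeline uses. Consequently the pipeline acceptance checks measure
*recovery of known truth through the full plumbing* — fusion,
smoothing, resistance inversion, reconstruction — not physical realism.
Passing them demonstrates internal consistency and correctness of the
algebra and bookkeeping; it says nothing about accuracy against real
eddy-covariance data, sensor noise structure, spatially correlated
cloud masks, row-crop geometry, or stability effects, none of which the
generator emulates. The injected scene noise and station closure
deficit are simple i.i.d./multiplicative models.

Problem sizes: unit tests run 12×12 to 24×24 grids over 40–120 days;
the end-to-end recovery checks use 60×60 pixels over a full 365-day
season, clear-sky and cloud-gapped, which completes in seconds per
season on one CPU.

## Numerical and interface choices

- All budgets are closed by algebraic construction, never by residual
  dumping into an unreported term; the fallback path is flagged in the
  output rather than silent.
- The Priestley–Taylor decrement (0.1) bounds the iteration at 14
  steps; the sequence is non-increasing by construction.
- The evaporative fraction is stored raw; values outside [0, 1.1] are
  flagged, not clipped (daily ET itself is floored at zero).
- Clear/cloudy is decided per pixel-date by validity of the (fused)
  LST; with scene-level gaps this reduces to a scene flag.
- Rasters are carried by a minimal in-memory grid class
  (`raster_grid`) with plain-text ASCII-grid I/O and CSV tables — a
  deliberately dependency-light interface; reprojection beyond affine
  bilinear resampling is out of scope.
- Every physical constant and threshold is overridable through
  `et_constants()` / the parameter objects; defaults are documented
  with their units where they are defined.

## Known limitations

No atmospheric-stability correction (switchable designs would add it
behind `aerodynamic_resistances()`); no two-pair fusion or
point-spread-function modelling; the LAI–NDVI relation, emissivities
and extinction coefficient are site calibrations with documented
defaults rather than retrieved quantities; cloudy-day reconstruction
degrades when crop condition changes abruptly inside a gap (hence the
5-day cutoff); and the synthetic acceptance evidence is, by design,
self-consistency rather than field validation.
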