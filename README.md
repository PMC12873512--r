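# cuticular

Leaf cuticle water permeability, slope microclimate and Raman chemometrics
for alpine plant ecophysiology.

Dwarf shrubs on contrasting north- and southeast-facing alpine slopes live
a few metres apart under radically different irradiance and temperature
loads, and respond with measurably different cuticles: thickness, layered
chemistry (cutin, triterpenoids, flavonoids, waxes) and water permeability.
`cuticular` provides the full computational chain for such studies, for
ecophysiologists who have 1-min microclimate loggers, a laboratory balance
and a confocal Raman microscope:

* **Effective irradiance on tilted canopies.** Solar position (NOAA/Meeus
  equations, ≤ 0.5° contract), beam reconstruction from horizontal PPFD by
  `PPFD / sin(elevation)` above a 10° cutoff, and projection onto the
  canopy surface normal via the scalar product with the sun direction.
* **Minimum diffusive conductance (g_min).** The mass-loss-of-detached-leaves
  (MLD) technique: per weighing interval, transpiration
  `E = Δm / (M_w · A · Δt)` and conductance `g = E / VPD_mol`, with the VPD
  as a mole fraction from the Magnus saturation vapour pressure; plateau
  detection after stomatal closure; g_min as mean ± SD over the plateau.
* **Exponential temperature response.**
  `g_min(T) = g_min(0 °C) + A · exp(R0 · T)` fitted by bounded
  Levenberg–Marquardt least squares, with tidy()/glance()/autoplot()
  methods.
* **Raman hyperspectral chemometrics.** Crop (120–1810 cm⁻¹) → cosmic-ray
  removal → asymmetric-least-squares baseline, 1452 cm⁻¹ band-integration
  imaging, non-negative spectral unmixing with noise-component rejection,
  per-transect layer thickness, and band assignment against a cuticle
  constituent table (cutin 1443/1306, triterpenoids 463–746, flavonoids
  1570/1250, cinnamic acids 1630/1170, crystalline alkanes
  1064/1133/1297 cm⁻¹).
* **The statistical battery.** Two-way ANOVA + Tukey HSD with Levene and
  Shapiro–Wilk checks, KS-gated t / Mann–Whitney comparisons,
  Kruskal–Wallis with Dunn–Holm post hoc and compact letter display.
* **Synthetic data with ground truth** for every input — microclimate
  series, drying curves from a forward conductance model, layered Raman
  cubes, thickness datasets — so the whole pipeline is testable end to end,
  plus `run_study()` to reproduce the complete synthetic study from one
  seeded configuration.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe.

## Worked example

Simulate one bench-drying run of a stem-sealed shoot whose true cuticular
conductance is 1.78 mmol m⁻² s⁻¹ (the 25 °C north-slope calibration), then
estimate g_min back from the noisy weighings:

```r
library(cuticular)

p   <- drying_params(true_gmin = 1.78, ambient_temp = 25, seed = 42)
exp <- generate_drying_experiment(p, sample_id = "N-25-01", site = "N")
estimate_gmin(exp)
#> <gmin_estimate> g_min = 1.784 +/- 0.719 mmol m-2 s-1 (plateau intervals 8-72, n = 65)
```

The estimator found the plateau from interval 8 (≈ 2.5 h, after stomatal
closure) to the end of the 24 h run and recovered the true conductance to
0.4%; the ± SD reflects per-interval balance noise, which largely cancels
in the mean. `autoplot()` on the estimate shows the phase-labelled drying
curve.

The irradiance contrast between slopes comes from geometry alone. With the
same week of weather, projecting the beam flux onto the two canopy normals
(35°/135° southeast vs 45°/350° north):

```r
scen <- kalmia_site_scenarios()
mc   <- generate_microclimate(scen$S, "2023-06-01", "2023-06-08", step = 1, seed = 1)

daily_max <- function(s) {
  effective_ppfd_series(mc, s$latitude, s$longitude,
                        s$normal_elevation, s$normal_azimuth) |>
    daily_maxima("ppfd_effective", tz = s$tz)
}
mean(daily_max(scen$S)$max)  #> 1810 µmol photons m-2 s-1
mean(daily_max(scen$N)$max)  #> 959 µmol photons m-2 s-1
```

The southeast-facing surface receives roughly twice the peak photon flux of
the north-facing one under identical sky conditions — the mechanism behind
the contrasting leaf temperatures and cuticle phenotypes.

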