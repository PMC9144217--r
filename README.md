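# thzenac

Terahertz (THz) spectral analysis of ion-channel inhibition, from both
sides of the bench: cell-suspension absorption spectra and molecular-dipole
dynamics from simulation. The motivating system is the epithelial sodium
channel (ENaC) blocked by amiloride, where blocking stiffens the channel
and measurably changes its sub-THz absorption slope — but every stage is a
general-purpose tool.

## What it computes

**Experimental branch** — for suspension spectra (frequency, absorbance):

- baseline translation to a common origin (1 a.u. at 0.18 THz) and
  THz ⇄ wavenumber conversion (ν̃ = f·10¹²/c);
- solvent subtraction under the additive model
  A_sample = (1 − f)·A_solvent + A_cells, with the displaced solvent
  volume fraction f = ρ·(π/6)d³ from the cell density ρ and diameter d
  (3×10⁷ cells/mL of 20 µm spheres → f ≈ 0.1257, i.e. ~12.56%);
- linear slope fits over a frequency range and one-sided Welch comparison
  of slope samples between conditions.

**Simulation branch** — for dipole time series µ(t):

- THz/IR spectral density via Wiener–Khinchin (periodogram of the
  mean-removed dipole; equals the FFT of the autocorrelation, which is a
  tested identity, not an assumption), with Blackman–Harris/Hann/no
  apodization, over running 1-ns windows (5000 frames at 0.2 ps);
- spectral convergence by exact band-constrained dynamic time warping
  (cDTW, Sakoe–Chiba band, squared local cost, Euclidean path distance)
  and by FastDTW, with a percentile-based convergence verdict and the raw
  distance range.

**Trajectory analyses** — Kabsch superposition, RMSD series (align on one
selection, measure another), RMSF about the mean structure, radial pair
distribution functions g(r) with minimum-image support, pairwise
Coulomb + Lennard-Jones interaction energies (332.0636·qᵢqⱼ/r;
ε[(Rmin/r)¹² − 2(Rmin/r)⁶], switched cutoff), and per-segment energy
statistics.

**State decomposition** — a ligand RMSD series is histogrammed (0.05 Å
bins), fitted with a sum of Gaussians A/(σ√2π)·exp(−(x−x_c)²/2σ²), and
state occupancies are read from the fitted areas (normalized to 100%);
frames nearest each center become the representative structures.

**Synthetic data** — generators for every input (suspension spectra
quartets, stationary dipole mode combs, Markov-dwell multi-state RMSD
series, jittered toy trajectories), so the full pipeline runs and is
tested without instrument data or MD trajectories.

## Worked example

```r
library(thzenac)
report <- run_demo(seed = 1)
report$experimental$slope_table
#>               role slope intercept r_squared
#> 1          solvent 6.000   -0.0800         1
#> 2  solvent_blocker 6.100   -0.0980         1
#> 3 sample_untreated 6.446   -0.1603         1
#> 4   sample_treated 6.933   -0.2480         1
#> 5  cells_untreated 1.200    0.1000         1
#> 6    cells_treated 1.600    0.1000         1
```

The synthetic quartet was composed with cell slopes 1.2 (untreated) and
1.6 (treated) on top of a solvent of slope 6 at displaced fraction
0.12566; the subtraction recovers both cell slopes exactly (R² = 1 on
noiseless fixtures) and the verdict is `"treated > untreated"` — the
direction observed experimentally for amiloride-blocked cells.

```r
report$simulation$slope_p_value
#> [1] 3.511857e-32
round(report$states$centers, 2)
#> [1] 3.20 6.30 8.34 9.27
sum(report$states$occupancy)
#> [1] 100
```

The simulation branch compares a stiff (spectral envelope ~f^1.6) against
a soft (~f^1.0) dipole process: the stiff condition's normalized spectra
have mean slope 0.317 vs 0.036, one-sided p ≈ 3.5×10⁻³². The state
decomposition of a synthetic four-state series recovers the generator
centers (3.19, 6.30, 8.33, 9.26 Å) to within ~0.01 Å; fitted occupancies
(here 10.8/26.2/16.2/46.8%) track the dwell epochs the particular seed
realized, and always sum to 100%.

A command-line front end covering all stages ships in
`inst/cli/thzenac`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "thzenac", package = "thzenac"))')
Rscript "$CLI" fixtures --out fx --seed 2
Rscript "$CLI" subtract --sample fx/spectrum_GM_cells.csv --solvent fx/spectrum_GM.csv --out cells.csv
#> displaced fraction: 0.1257
Rscript "$CLI" states --rmsd fx/rmsd_ligand.csv --n 4
#> state 1: center 3.19 +/- 0.01 A, sigma 0.30 A, occupancy 8.60%
#> ...
```

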