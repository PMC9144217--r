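---
title: "Methods: THz spectral analysis of channel inhibition from dipole dynamics and cell-suspension spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: THz spectral analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzenac)
```

# Scope and model

`thzenac` packages the computational side of a combined
experiment/simulation THz study of epithelial sodium channel (ENaC)
inhibition by amiloride. Two independent routes lead to the same kind of
observable — a sub-THz absorbance curve that rises approximately linearly
with frequency — and the package implements both, plus the trajectory
analyses that explain differences between conditions.

**Experimental route.** Cell suspensions are measured in transmission; the
observable is absorbance vs frequency on 0.18–1 THz. Two corrections are
applied:

* *Common origin.* Spectra are shifted additively so that absorbance at
  0.18 THz equals 1 a.u. (`translate_to_origin()`). Translation leaves
  slopes untouched, which is why slopes — not absolute absorbances — are
  the quantity compared between conditions.
* *Solvent subtraction.* Assuming cell and solvent contributions add, a
  suspension absorbs as $(1-f)\,A_\mathrm{solv} + A_\mathrm{cells}$, where
  $f$ is the solvent volume displaced by the cells. Approximating a cell
  as a sphere of diameter $d$ at density $\rho$,
  $f = \rho \frac{\pi}{6} d^3$. At the standard $\rho = 3\times 10^7$
  cells/mL and $d = 20\,\mu$m, $f \approx 0.1257$ (the cells displace
  ~12.56% of the solvent). `subtract_solvent()` inverts the forward model
  exactly; `gen_suspension_pair()` is that forward model, so the pair is
  tested as an exact round trip.

**Simulation route.** The THz/far-IR spectral density of a molecular
system is obtained from the fluctuating total dipole moment
$\boldsymbol\mu(t)$: by the Wiener–Khinchin theorem the Fourier transform
of the dipole autocorrelation equals the squared modulus of the signal's
Fourier transform, so `spectral_density()` computes the one-sided
periodogram of the mean-removed signal in $O(N\log N)$ and the
equivalence with the direct autocorrelation route is a test, not an
assumption. Conventions:

* sampling 0.2 ps over 1-ns windows (5000 frames/window), frequency
  resolution $1/(N\,\Delta t)$, grid reported in cm$^{-1}$, default
  truncation 80 cm$^{-1}$;
* the mean dipole is removed — only fluctuations absorb — and the unknown
  absolute prefactor (quantum correction, unit conversion) is deliberately
  omitted because downstream normalization at 0.029 THz divides it out;
* default apodization is the three-term Blackman–Harris window, matching
  the post-processing applied to the measured spectra; `none` and `hann`
  are selectable, and the window is power-normalized so Parseval-type
  scaling (doubling the amplitude quadruples the density) survives
  apodization. Exact Parseval conservation holds for `none` only and is
  tested there.

Simulated spectra are normalized to their value at the first resolved
anchor (0.029 THz) and compared through their fitted linear slopes over
0.029–1 THz, mirroring the experimental 0.18–1 THz fit range.

# Convergence of windowed spectra

Whether 1-ns windows are long enough is decided by comparing consecutive
window spectra with dynamic time warping. The package provides

* `dtw_distance()` — exact dynamic programming under a Sakoe–Chiba band of
  half-width `ceil(band_fraction * max(n, m))` (default fraction 0.1),
  local cost = squared difference, reported distance = square root of the
  accumulated cost, i.e. the Euclidean distance along the optimal warping
  path;
* `fastdtw_distance()` — the multiresolution approximation (coarsen by
  pairwise averaging, solve, project the path, dilate by `radius`, refine;
  default radius 1). It can never undercut the exact optimum, and with a
  radius at least the series length it *is* the exact optimum; both facts
  are tested.

The published analysis reports, per method, a "confidence interval" and
the min/max Euclidean distance, but the rule producing the confidence
figure is not public. The package therefore defines a documented stand-in:
spectra are *converged* when the empirical 95th percentile of the pairwise
distances is at or below a tolerance, and the reported confidence level is
the largest of 90/95/99 whose percentile bound passes. When no tolerance
is supplied, 3× the median distance is used — a scale-free heuristic that
holds for stationary window sequences with moderately skewed distance
distributions but can fail (report "not converged") when the distance
distribution has a heavy upper tail even though the process is stationary;
the raw distances are always returned so any other criterion can be
applied. Distances are computed on spectra normalized at the stated anchor
(0.029 THz for simulated spectra): normalizing at an unresolved noise bin
instead makes distances meaninglessly large, which is why
`convergence_report()` exposes `anchor_freq`.

# Ligand state decomposition

The ligand's RMSD time series (frames aligned on the channel's TM2
helices, RMSD measured over the ligand) dwells in quasi-stable states.
The decomposition pipeline is: histogram at 0.05 Å bins
(`histogram_counts()`); nonlinear least squares of a sum of
area-parameterized Gaussians
$\sum_i \frac{A_i}{\sigma_i\sqrt{2\pi}} e^{-(x - x_{c,i})^2/2\sigma_i^2}$
to the counts (`fit_peaks()`); occupancies as fitted areas normalized to
100% (the area convention — occupancy from the curve, not from hard
assignment — with label-based occupancies available for comparison via
`assign_states()`); representative frames as the frames whose RMSD is
nearest each fitted center, earliest frame on ties
(`representative_frames()`).

Numerical choices, all of which were genuinely open:

* The optimizer is BFGS on a transformed parameter vector — centers raw,
  $\log(\sigma_i - \sigma_\min)$, $\log A_i$ — which builds in the bounds
  $\sigma_i \ge \sigma_\min = $ bin width / 2 (prevents delta-spike
  degeneracy) and $A_i > 0$ without a constrained solver. Center standard
  errors come from the Gauss–Newton covariance $s^2 (J^\top J)^{-1}$ with a
  numeric Jacobian. `stats::nls()` proved fragile on histogram counts with
  near-empty tail bins, and no Levenberg–Marquardt package is assumed.
* When no initial centers are given they are taken as local maxima of a
  5-bin moving-average smoothed histogram, keeping maxima of at least 5%
  of the tallest peak (below that, sparse tail noise creates spurious
  components). The number of detected maxima is then the default component
  count; a fixed count (the published analysis used 4, chosen by
  inspection) can be forced.
* Assignment ties (a value exactly equidistant between two equal-weight,
  equal-width states) break deterministically to the lower-center state.

# Synthetic data: what it emulates, what it does not

All pipeline inputs can be generated (`write_fixtures()`), with defaults
chosen once to match the stated experimental/simulation conditions:

* *Suspension quartet.* Linear-in-frequency absorbances; the solvent slope
  (6 a.u./THz) dominates the cell slope (1.2/1.6 a.u./THz for
  untreated/treated), and the treated cells are constructed steeper — the
  direction the experiment found. Composition uses the exact forward model
  with $f$ from the 3×10⁷ cells/mL, 20 µm suspension.
* *Dipole series.* `gen_dipole()` realizes
  $\mu(t) = \sum_i a_i e^{-\gamma_i t}\cos(2\pi f_i t)\,\hat e_i +$ noise.
  Damped modes give closed-form (Lorentzian) oracles for single-window
  tests, but a damped cosine is a one-shot transient — windows after the
  first see only noise — so *stationary* fixtures use undamped mode combs
  (`mode_comb()`): modes every 0.05 THz with amplitudes $f^{p/2}$, giving
  a spectral envelope $\propto f^p$. The stiffer (blocker-bound) condition
  uses a larger $p$ (1.6 vs 1.0), which is what makes its normalized slope
  larger. A mode sits exactly at the 0.029 THz anchor so normalization is
  stable across windows.
* *State series.* A Markov chain with transition matrix
  $p\,I + (1-p)\,\mathbf 1 \pi^\top$ has stationary distribution $\pi$
  (the target occupancies) for any persistence $p < 1$, while visiting
  states in contiguous epochs as real binding trajectories do. Default
  $p = 0.999$ per 0.2 ps step (mean dwell 200 ps). Tests of *occupancy
  convergence* use smaller $p$ (more dwell events per series) or $p = 0$
  (iid mixture draws, as in the acceptance target) — with $p = 0.999$ and
  $10^5$ frames only ~100 dwells occur and empirical occupancies scatter
  by several points, which is a property of the stated world, not a
  defect. The published occupancy percentages sum to 99.97% (rounding);
  inputs within 1% of a proper distribution are renormalized.
* *Toy trajectories.* Rigid-motion + isotropic jitter around a uniform
  reference configuration. Under isotropic jitter $\sigma$ the per-atom
  RMSF tends to $\sigma\sqrt3$ (minus a small superposition-absorbed
  fraction $\approx 6/(3N)$ of the variance). Ideal-gas RDF tests use
  *independent* uniform configurations per frame, because jittering one
  frozen configuration leaves its particular pair-distance noise in every
  frame.

What a green test does **not** establish: the synthetic world has no
force field, no hydration shells, no instrument optics (étalon fringes,
Fresnel losses) and no 1/f instrument noise. Printed values from the real
system — the simulated slope pair 10.56/11.77, the published DTW distance
ranges, interaction-energy means such as −29.95 ± 4.38 kcal/mol — require
the original 320k-atom trajectories and are treated as annotations, not
reproduction targets; the corresponding machinery is verified against
analytic anchors (Coulomb constant 332.0636 kcal·Å/(mol·e²), LJ minimum
−ε at $R_{\min}$) and brute-force oracles instead.

# Degenerate inputs and tie-breaks

* Off-grid anchor frequencies resolve by linear interpolation (instrument
  grids differ between runs); anchors outside the grid span are errors.
* Normalization at a zero anchor value is an error, not an Inf spectrum.
* Spectral windows are half-open $[t_0, t_0 + w)$; boundary frames belong
  to the later window; window count = $\lfloor(\mathrm{range} -
  \mathrm{width})/\mathrm{stride}\rfloor + 1$.
* DTW backtracking prefers the diagonal on cost ties, giving the shortest
  of the optimal paths.
* `rdf()` without a box estimates density from the bounding box of the
  coordinates (floored at one bin width per dimension) — adequate for
  locating structure, not for absolute $g(r)$ scale; with a box,
  minimum-image is applied and $r_\max$ beyond half the box is an error.
* `nonbonded_energy()` refuses pair distances below 0.01 Å rather than
  returning astronomically large energies.

# Known limitations

* The convergence "confidence level" is this package's documented
  criterion, not the unpublished original; published distance ranges are
  not desk-reproducible.
* FastDTW inherits the accuracy/radius trade-off of the original
  algorithm; only the upper-bound property and radius→exact limits are
  guaranteed.
* The energy calculator is a toy-system analogue (no PME, no bonded
  terms); `rmsd_series_traj()` reads only multi-frame XYZ (+PDB metadata).
* One-sided Welch on window slopes is this package's choice for "the
  slopes are significantly larger ($p$-value 0.05)"; the original test is
  unnamed, and overlapping windows make the effective sample size smaller
  than the window count, so the $p$-value is anti-conservative for
  strongly overlapping strides.
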