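---
title: "Dynamic scattering of intense X-ray pulses by organic nanoclusters: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic scattering: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A femtosecond XFEL pulse carrying ~10^12 photons turns any nanoscale
sample into a transient plasma while the diffraction image is being
recorded. Near an absorption edge the interplay is especially violent:
once inner-shell ionization and Auger decay open vacancies in the valence
shell, the pulse can resonantly pump core electrons into those vacancies
(a *transient resonance*), multiplying the absorbed dose and collapsing
the coherent scattering response. `dynscat` models this end to end for
sucrose (C12H22O11) nanoclusters, the benchmark organic sample: an atomic
Hartree-Fock-Slater (HFS) engine supplies cross sections and complex form
factors for every electronic configuration; a Monte-Carlo rate-equation
sampler coupled to classical molecular dynamics propagates the full
electron/nuclear state through the pulse; and time- and
bandwidth-resolved scattering integrals turn trajectories into cross
sections. The *dynamic scattering efficiency* (DSE) condenses the result:
theoretically the ratio of the damaged to the undamaged scattering cross
section, experimentally the ratio of the fitted incident fluence of the
brightest hits to the beamline peak fluence.

# The atomic engine

Each atom/ion is solved in the self-consistent central-field
approximation with Slater X-alpha local exchange on a logarithmic radial
grid (3000 points, 1e-6 to 50 bohr; Numerov integration in compiled
code), with the Latter tail correction enforcing the correct -(q+1)/r
asymptotics. From a converged configuration the engine produces:

* orbital energies and relaxed (delta-SCF) ionization thresholds — the
  difference of total self-consistent energies between the configuration
  and the corresponding ion, which places the oxygen K threshold at
  551 eV (eigenvalues alone would misplace it below 530 eV and wrongly
  open direct K ionization at the water-window operating point);
* photoionization cross sections from length-gauge dipole matrix elements
  with energy-normalised continuum partial waves in the same potential
  (WKB amplitude matching at a radius where the radial grid still
  resolves the continuum oscillation; above a per-subshell cap the
  tabulated cross section continues with a fitted power-law tail);
* dipole bound-bound transitions with delta-SCF transition energies,
  statistical-vacancy oscillator strengths
  f = (2/3) omega R^2 (l_max/(2 l_v + 1)) N_v H_u / cap_u,
  and natural linewidths from the Auger width of the final core-hole
  state;
* complex form factors f(q, omega) = f0(q) + f'(omega) + i f''(omega):
  f0 as the Fourier transform of the radial density, f'' from the optical
  theorem (continuum plus Lorentzian lines), f' by a principal-value
  Kramers-Kronig transform of the tabulated continuum plus the analytic
  dispersion partner of each line.

## Calibration of the one free parameter

The HFS model leaves the exchange weight `alpha` open; standard practice
spans the Kohn-Sham value 2/3 to Slater's original 1. We fix
`alpha = 0.717` once, by requiring the bandwidth-convolved oxygen 1s->2p
resonant absorption cross section at the 530-eV operating point (1%
Gaussian bandwidth) to match its literature anchor of 1.2 Mbarn. This
places the delta-SCF 1s->2p line at 532.2 eV — inside the observed
sucrose 1s->pi* band (530-535 eV), which the atomic 1s->2p channel
stands in for — and simultaneously gives a combined 2s+2p valence
photoionization cross section of 0.032 Mbarn at 530 eV and a
resonant-to-nonresonant ratio of ~38, in line with the ~40-fold
enhancement expected at this edge. These numbers are recomputed from
scratch by `scripts/acceptance.R`.

## Oxygen core-hole lifetime

Two named presets exist, 4 fs and 5 fs, both quoted for the oxygen K
hole in the literature. The 4-fs value anchors the resonance-cycling
argument and is the default (`hfs_control(lifetimes = ...)` switches).
Carbon and nitrogen default to 10 fs and 7 fs; argon L holes to 5 fs.
K fluorescence yields for Z <= 18 are far below the Auger branch and
default to zero, but the fluorescence channel remains in the rate
structure and can be enabled.

# Ionization dynamics

Transitions between configurations proceed through six channels —
photoionization, Auger decay, fluorescence, resonant excitation,
electron-impact ionization and recombination. Field-driven rates are
sigma x j(t) with the instantaneous Gaussian flux; Auger/fluorescence are
field-free; impact ionization uses the Lotz formula over the HFS binding
energies; recombination is a classical three-body capture in the MD (see
below). Sampling is per-step Bernoulli with p = Gamma dt at the MD step
dt = 10 as — justified because all rates here are far below 1/dt, and
validated against the exponential-decay and Poisson closed forms in the
test suite. The engine refuses to run when p exceeds 0.25 rather than
silently distorting statistics. Rate tables are memoised per
configuration (and per 64-per-decade intensity bin at the R interface);
the compiled engine consumes the same tables and returns control to R
whenever an atom reaches a configuration whose atomic data have not been
built, so atomic structure is always computed exactly once per
configuration and photon energy.

# Nanoplasma molecular dynamics

All nuclei/ions and delocalized electrons move classically under softened
pairwise Coulomb forces (velocity Verlet, default 10-as steps). The
softening length defaults to 0.05 nm: it both keeps classical collisions
finite and is the scale at which a 10-as step still resolves the closest
electron-ion encounters - with much smaller softening, sub-softening
flybys are integrated too coarsely and visibly heat the classical
subsystem (the energy audit below measures this). Photo- and Auger electrons are
born isotropically at their atom with kinetic energy omega - B or the
delta-SCF Auger energy; impact-ionization secondaries start essentially
at rest and the projectile pays the binding energy. An electron is
*escaped* once it is beyond the interaction radius (3x the initial
cluster radius, at least 2 nm) with positive energy in the cluster
monopole field; it is then dropped from the force sum and counted.
Recombination captures an electron into the outermost vacancy of an ion
when it is inside the capture radius (0.02 nm) with negative relative
energy — the classical stand-in for three-body recombination in the
dense nanoplasma; together with Lotz reionization this produces the
churn of cold electrons cycling on and off highly charged ions that
drives energy redistribution.

Three numerical conventions keep this plasma model honest:

* electrons are born with the *asymptotic* energy convention — the
  binding energy already accounts for the ion's attraction, so the
  classical well at the birth point is compensated and the electron is
  launched outward, rather than being spuriously re-bound at its birth
  offset;
* an electron may impact-ionize only when its *total* energy in the
  full cluster field (kinetic plus potential, accumulated at no extra
  cost inside the force loop) exceeds the target's binding energy, and
  the Lotz cross section is evaluated at that spare energy. Deeply
  trapped electrons carry large local kinetic energy that is owed to
  the cluster well; letting them spend it on neighbours drives an
  unphysical stripping runaway, while with the total-energy criterion
  they thermalize through recombination instead;
* one collision, one chance: after an impact ionization the
  electron-atom pair is re-armed only once the electron has left three
  impact radii, so a single flyby spanning several 10-as steps is not
  double counted; and each atom undergoes at most one configuration
  transition per step, which also makes the event stream bit-for-bit
  reproducible regardless of how the atomic-data cache was warmed.

The two-body Kepler oracle bounds the integrator drift (< 1e-6 relative
over 1e4 steps), and a running energy audit (injection at births and
charge-changing events, removal at escapes, captures and binding-energy
payments) closes the classical bookkeeping to a few percent in
integrator-resolved regimes (photoemission without dense-plasma churn).
In the fully developed nanoplasma, residual heating from the most
violent encounters amounts to ~20 percent of the audited throughput at
the default softening - a known limitation of fixed-step classical
nanoplasma models; the audit quantifies it per run, and the package
asserts DSE orderings and trends, which are robust against it, rather
than absolute plasma energetics.

# Scattering integrals

The damaged differential cross section averages instantaneous patterns
|F_c(q,t)|^2 + N_e(t) over the pulse (snapshots every 0.5 fs, nearest
snapshot per quadrature time, weighted by j(t)) and over the Gaussian
bandwidth (Gauss-Hermite nodes, 5 by default), normalised per incident
photon and multiplied by the unpolarized Thomson factor. Free electrons
inside the interaction region enter incoherently (the +N_e term): by the
time they matter most have left the coherent volume, so their amplitudes
do not add in phase. Numerical choices worth knowing:

* orientation structure is sampled with a fixed Fibonacci direction set
  (12 directions by default) per momentum-transfer shell; the undamaged
  reference can instead use the exact orientation average (Debye
  formula). `theoretical_dse()` uses the *same* direction set for the
  damaged and undamaged cross sections so the sampling bias cancels in
  the ratio, and the frozen-dynamics limit returns DSE = 1 to machine
  precision;
* the bandwidth enters through the anomalous form factors; the
  sub-percent geometric spread of the q mapping across a 1% bandwidth is
  neglected;
* narrow bound-bound lines are broadened by the bandwidth in the
  *coherent amplitude*: within a broadband pulse only the
  bandwidth-averaged amplitude stays phase-coherent across the cluster,
  and the residual natural-linewidth response is Auger-dominated
  resonance fluorescence, which does not contribute to the coherent
  image. Absorption rates always keep the natural linewidth;
* total cross sections integrate the full scattering sphere by default
  (a configured q_max aperture is available and errors out loudly if it
  exceeds 4 pi / lambda).

Scaled-down study conditions: the pulse-duration and photon-energy sweeps
run 10-molecule clusters (450 atoms, 1820 electrons) at 25 uJ/um^2,
integrating at a 20-as step (cross-checked against the default 10-as
step: the DSE values agree to about ten percent and all orderings are
unchanged) —
the smallest size in which the resonant Auger cycling, plasma churn and
expansion all appear — and the lambda^2 reference check uses a static
100-molecule cluster, large enough that the coherent forward lobe
dominates the atomic large-q tail (a genuine finite-size effect that
decays like N^(-1/3) and reaches the few-percent level there). At these
sizes the DSE magnitudes sit well above the production-scale values (a
10-nm-class particle traps less of its plasma than a 50-nm one); the
package asserts orderings and trends at desk scale and accepts the
full 185,193-molecule configuration without special-casing it.

# Sphere model and image analysis

The linear single-shot model treats the particle as a homogeneous sphere:
expected photons per pixel I0 D_QEgeo (6 pi V |dn| / lambda^2)^2
|(sin s - s cos s)/s^3|^2 with s = (2 pi d / lambda) sin(theta) — note
this model's q convention, |q| = (2/lambda) sin(theta), is kept exactly
as stated so that s = pi d |q|. The refractive decrement comes from the
summed forward form factors of the constituent atoms at the sucrose mass
density 1581 kg/m^3. Fitting proceeds on the azimuthally averaged radial
profile with a Poisson likelihood; the amplitude (incident fluence) is
profiled out analytically, the diameter is located by a global
log-spaced scan plus local refinement (which also guards against
fringe-order aliasing), and a missing first minimum inside the aperture
flags the fit as low-confidence instead of failing silently. The
experimental DSE filters fitted shots to sizes within one standard
deviation of the mean *before* selecting the brightest 5% — the ordering
matters and is fixed here.

The synthetic shot generator emulates the geometry of a hit ensemble —
Gaussian size spread, focal-volume fluence distribution (1/F density for
a Gaussian focus), Poisson counting noise, and a known injected damage
factor. It does not emulate detector artefacts (gain nonuniformity,
charge sharing, saturation), background scatter, non-spherical particles
or beam pointing jitter; recovery tests therefore demonstrate the
correctness of the estimator, not robustness to instrument systematics.

# Two-level resonance estimate

For few-femtosecond pulses the rate picture breaks down and stimulated
cycling matters. `rabi_two_level()` solves the rotating-wave two-level
Schroedinger equation with the Gaussian field envelope and upper-level
Auger decay. The transition dipole uses the collective convention
d = sqrt(N_1s) x radial integral (the two equivalent K electrons couple
coherently to the aligned field); with the 4-fs Auger preset at
25 uJ/um^2 and 5 fs this gives a peak-Rabi-to-Auger ratio of ~92,
consistent with the ~87-fold enhancement expected at these parameters.
At fixed fluence the peak field — and hence the peak Rabi frequency —
scales as tau^(-1/2); the package documents and tests this scaling (a
quartered duration doubles the peak Rabi frequency), and anchors the
estimate at the stated operating point rather than relying on any
duration-scaling claim.

# Known limitations

* Atoms are independent: molecular orbitals, chemical shifts and the
  real 1s->pi* structure are represented only through the atomic 1s->2p
  channel; no vibrational broadening.
* Compton scattering is excluded (small total cross section in this
  energy range); coherent treatment of quasi-free electrons is out of
  scope — they enter strictly incoherently.
* The classical plasma (softened Coulomb, Lotz, capture-radius
  recombination) reproduces channel bookkeeping and gross energetics,
  not detailed electron thermodynamics.
* Desk-scale runs (tens to thousands of molecules) reproduce orderings
  and trends of the production-scale study, not absolute DSE magnitudes
  at 50 nm.
* The radial solver's continuum is trusted to a per-subshell energy cap
  (the tabulated tail beyond it is a fitted power law); anomalous terms
  outside 5 eV - 30 keV raise an error rather than extrapolate.

# Reproducing the headline numbers

```{r, eval = FALSE}
library(dynscat)

ad <- solve_hfs("O", ground_configuration("O"))
resonant_cs(ad, "1s", "2p", omega_x_ev = 530, bandwidth_fwhm_ev = 5.3) / 1e6
total_photoionization_cs(ad, 530, c("2s", "2p")) / 1e6
oxygen_rabi_estimate()$ratio_to_auger

cl <- build_cluster(10, seed = 1)
res <- theoretical_dse(cl, pulse_spec(530, 30, 25), seed = 11)
res$dse
```

`scripts/acceptance.R` recomputes the three cross-section/Rabi anchors
from scratch against the installed package.
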