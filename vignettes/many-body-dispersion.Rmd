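---
title: "Coupled-oscillator dispersion and collective charge fluctuations"
author: "mbdtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled-oscillator dispersion and collective charge fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdtools)
```

## The model

`mbdtools` implements the many-body dispersion (MBD) picture of van der
Waals binding.  Each atom $A$ contributes one charged quantum harmonic
oscillator — a "Drude pseudoelectron" of unit charge in a harmonic well —
whose static polarizability $\alpha_{0,A}$ and characteristic frequency
$\omega_A$ summarize the atom's long-range valence response.  The
oscillators interact through the dipole–dipole potential; because the
resulting Hamiltonian is biquadratic in the mass-weighted displacements
$\boldsymbol\xi_A$,

$$
H = \tfrac12 \sum_A \left(\dot{\boldsymbol\xi}_A^2
    + \omega_A^2 \boldsymbol\xi_A^2\right)
  + \tfrac12 \sum_{A \ne B} \omega_A \omega_B
    \sqrt{\alpha_{0,A}\,\alpha_{0,B}}\;
    \boldsymbol\xi_A^\top \mathbf T^{\mathrm{lr}}_{AB} \boldsymbol\xi_B ,
$$

it is solved exactly by one dense diagonalization.  The eigenvalues give
coupled fluctuation frequencies $\tilde\omega_i$ and the dispersion
(long-range correlation) energy follows from the plasmon-pole formula

$$
E = \tfrac12 \sum_i \tilde\omega_i - \tfrac32 \sum_A \omega_A .
$$

The pipeline from an input geometry to this energy has three stages, each
its own module surface:

1. **Parameterization** (`scale_vdw_params`): free-atom reference values
   $(\alpha_0^{\mathrm{free}}, C_6^{\mathrm{free}},
   R_{\mathrm{vdw}}^{\mathrm{free}})$ are scaled by the per-atom Hirshfeld
   volume ratio $v_A$ (computed externally from a DFT density):
   $\alpha_{0,A} = v_A\alpha_0^{\mathrm{free}}$,
   $C_{6,A} = v_A^2 C_6^{\mathrm{free}}$,
   $R_{\mathrm{vdw},A} = v_A^{1/3} R_{\mathrm{vdw}}^{\mathrm{free}}$.
   The Drude closure $\omega_A = \tfrac43 C_{6,A}/\alpha_{0,A}^2$ makes
   the single-pole Lorentzian
   $\alpha_A(i\omega) = \alpha_{0,A}/(1+(\omega/\omega_A)^2)$ reproduce
   $C_{6,A}$ exactly under the Casimir–Polder integral — the property
   that ties the plasmon-pole and RPA routes together.
2. **Self-consistent screening** (`screen_parameters`): the short-range
   part of the dipole coupling dresses the atomic polarizabilities via
   the Dyson equation
   $B(i\omega) = (A(i\omega)^{-1} + \mathbf T^{\mathrm{sr}})^{-1}$,
   solved by dense linear algebra at every node of an
   imaginary-frequency grid.  Row-summing each atom's block row of $B$
   and taking a third of the trace gives the screened
   $\bar\alpha_A(i\omega)$, from which screened $\bar C_6$, $\bar\omega$
   and $\bar R_{\mathrm{vdw}}$ follow by the same closure.  The sum of
   all blocks of $B(0)$ is the molecular polarizability tensor, and the
   interfragment blocks of $B(0)$ expose the intermolecular correlation
   structure (`interfragment_block`).
3. **Diagonalization and energies** (`mbd_system`, `mbd_energy`,
   `rpa_energy`): the screened parameters enter the Hamiltonian together
   with the long-range tensor; interaction energies subtract fragment
   energies from the complex energy.

## Range separation and its parameters

The bare point-dipole tensor in this package is
$\mathbf T_{AB} = (\mathbf 1 - 3\hat R\hat R^\top)/R^3$ (so
$T_{zz} = -2/R^3$ for a z-aligned pair; this is the Hessian of the
Coulomb kernel with respect to the two positions, and the coupling enters
the Hamiltonian with a plus sign).  The short-range tensor uses Gaussian
charge distributions of width
$\sigma_A(i\omega) = (\sqrt{2/\pi}\,\alpha_A(i\omega)/3)^{1/3}$ — the
oscillators are not point dipoles but carry a natural width, which keeps
the screening finite at close approach.  A Fermi switching function

$$
f(R_{AB}) = \frac{1}{1 + e^{-a\,(R_{AB}/S_{AB}-1)}},
\qquad S_{AB} = \beta\,(R_{\mathrm{vdw},A} + R_{\mathrm{vdw},B}),
$$

splits the coupling: $\mathbf T^{\mathrm{lr}} = f\,\mathbf T$ (point
dipoles, used in the Hamiltonian with *screened* vdW radii in the
damping) and $\mathbf T^{\mathrm{sr}} = (1-f)\,\mathbf T^{gg}$ (Gaussian
widths, used in the screening).  Defaults are $a = 6$ and $\beta = 0.83$,
the published range-separation value calibrated for use on top of the
PBE functional; both are plain arguments and CLI flags.  Because the
Gaussian widths depend on frequency through $\alpha(i\omega)$, the
short-range tensor is rebuilt at every quadrature node.

Interaction-energy trends shift by roughly a percentage point per few
hundredths of $\beta$; all quantitative statements in the README and the
test suite are made at the defaults.

## RPA formulation and a sign convention worth stating

The identical energy is obtained from the random phase approximation.
Writing $C$ for the Hamiltonian matrix and $\Omega^2$ for its uncoupled
diagonal, the characteristic-polynomial identity

$$
\det\!\left(\mathbf 1 + A(i\omega)\,\mathbf T^{\mathrm{lr}}\right)
 = \frac{\det(C + \omega^2)}{\det(\Omega^2 + \omega^2)}
$$

together with $\int_0^\infty \ln\frac{u^2+a^2}{u^2+b^2}\,du = \pi(a-b)$
yields

$$
E = \frac{1}{2\pi}\int_0^\infty
    \operatorname{Tr}\ln\!\left(\mathbf 1 + A(i\omega)
    \mathbf T^{\mathrm{lr}}\right) d\omega
  = \tfrac12\sum_i \tilde\omega_i - \tfrac32\sum_A \omega_A .
$$

Note the **plus** sign: it is tied to this package's tensor convention
($T_{zz} = -2/R^3$).  In the convention with the opposite tensor sign the
familiar $\ln(1-AT)$ form is recovered.  The two differ only beyond pair
systems — a single pair has a symmetric coupling spectrum — which makes
this an easy convention slip to miss; the equivalence is therefore
enforced to $10^{-8}$ Ha on fifty random clusters in the test suite.
Expanding the logarithm gives the series in orders of the coupling; the
$n=2$ term is the pairwise London limit, and `many_body_decomposition`
reports the percentage by which the full many-body energy is reduced
relative to that second-order term — defined against the second order of
the *same screened* series, not against the unscreened TS baseline,
which is reported separately (`pairwise_ts_energy`).  The TS baseline
damps the energy with a single Fermi factor, while the second-order term
carries $f^2$ from the tensor; the two coincide only once damping has
saturated ($f \to 1$).

## Wavefunction analysis

The coupled ground state is Gaussian, with mass-weighted covariance
$\langle\boldsymbol\xi\boldsymbol\xi^\top\rangle = \tfrac12\sum_i
\tilde{\boldsymbol\xi}_i\tilde{\boldsymbol\xi}_i^\top/\tilde\omega_i$.
With unit charges, masses follow from
$m_A = 1/(\bar\alpha_{0,A}\bar\omega_A^2)$, and the charge density is a
sum of normalized anisotropic Gaussians centred on the atoms
(`charge_density`).  Subtracting fragment densities gives the
vdW-induced charge polarization $\Delta\rho$; its integral vanishes and
the integral over accumulating regions (all strictly positive voxels —
no isovalue cutoff) is the displaced charge.

Two analysis conventions deserve explicit statement:

* **Fixed parameters for differences.**  The density difference and the
  fragment-mode projection compare the complex against fragments
  evaluated at the *same* (complex-screened) per-atom parameters
  (`rescreen = FALSE`), so that $\Delta\rho$ and the mode expansion
  isolate the effect of the long-range correlated coupling.
  Re-screening each fragment in isolation instead folds the change in
  short-range screening into the difference; for the constructed benzene
  dimer that roughly doubles the displaced charge.  Interaction
  *energies* default to isolated-fragment re-screening, which is the
  physically consistent reference for binding.
* **Collectivity.**  Complex modes are expanded over the embedded
  fragment modes, $c_{ij} = \tilde{\boldsymbol\xi}_i^{\mathrm{complex}}
  \cdot \tilde{\boldsymbol\xi}_j^{\mathrm{fragment}}$ (an orthogonal
  matrix, since the fragments partition the atoms).  The collectivity of
  mode $i$ is the inverse participation ratio $1/\max_j c_{ij}^2$: an
  equal-weight three-component expansion gives exactly 3, a pure
  fragment mode gives 1, and the value is bounded by the mode count.
  The literal reading "inverse of the largest coefficient"
  ($1/\max|c|$, giving $\sqrt3$ for the same example) is also computed
  and reported by the CLI for comparison, but the squared convention is
  the one consistent with the equal-three-component example value of 3.
* **Per-mode binding contributions.**  $\Delta E_i = \tfrac12
  (\tilde\omega_i - \sum_j c_{ij}^2 \omega_j^{\mathrm{frag}})$ is a
  defined convention, chosen as the unique per-mode charge consistent
  with row normalization that sums exactly (to $10^{-10}$ Ha in the
  tests) to the interfragment energy at fixed parameters.

## Numerical choices

* **Imaginary-frequency grid**: 15-point Gauss–Legendre mapped by
  $\omega = \omega_0(1+u)/(1-u)$, $\omega_0 = 0.5$ Ha.  For Lorentzian
  integrands this converges geometrically: the Casimir–Polder closure is
  exact to $\sim 10^{-11}$ relative at 15 nodes, and doubling the grid
  moves screened $C_6$ by less than $10^{-6}$ relative.  Equivalence
  tests against the plasmon-pole route use denser grids (20–30 nodes)
  only because the log-det integrand is less benign than a Lorentzian
  product.
* **Eigensolver conventions**: eigenvalues ascending; any
  $\lambda \le 10^{-12}$ is a hard "imaginary coupled frequency" error
  (reporting the closest atom pair) rather than a silent truncation;
  mode signs are fixed by making each mode's largest-magnitude component
  positive.  Within *degenerate* subspaces the eigenvector basis is
  still solver-dependent; statements like "every complex mode is a
  single fragment mode at zero coupling" are therefore only
  deterministic for non-degenerate fragments, and the tests use
  asymmetric clusters for that limit.
* **Gaussian tensor stability**: the damping factor
  $\mathrm{erf}\zeta - (2\zeta/\sqrt\pi)e^{-\zeta^2}$ cancels
  catastrophically for $\zeta \lesssim 0.05$ and is replaced there by
  its Taylor series; the $R \to 0$ limit is the finite isotropic value
  $4/(3\sqrt\pi\sigma_{AB}^3)$.
* **Density grids**: 0.4 Bohr spacing with 4 Å padding by default, which
  converges the benzene-scale displaced charge to well under 1% (halving
  the voxel edge changes it by <1%); each atomic Gaussian is evaluated
  within 8 standard deviations.  A grid coarser than the narrowest
  covariance direction triggers a recorded warning.
* **Indexing**: all atom and fragment indices are 1-based, R's native
  convention, in code and in file outputs alike.

## Synthetic data and what the tests do and do not show

The generator (`generate_fixture`) produces dimers, chains, rings,
stacked ring pairs and random clusters with a minimum-distance floor
(default 1.8 Bohr), plus volume ratios drawn from a stated interval, all
deterministically from one integer seed.  The constructed benzene dimer
(`benzene_dimer`) uses an idealized geometry — C–C 1.3915 Å, C–H
1.087 Å; parallel-displaced: 3.47 Å interplane, 1.75 Å slip; T-shaped:
4.96 Å center distance — with *synthetic representative* Hirshfeld
ratios (C 0.85, H 0.66) typical of aromatic hydrocarbons.  These are
stand-ins chosen once, not DFT results: with them the package computes a
many-body reduction of 7.8% (parallel-displaced) and 3.4% (T-shaped) and
a displaced charge of 0.0089 e, against published MBD values of 8%, 3%
and 0.0097 e for relaxed geometries with density-derived ratios.

Passing tests on these fixtures demonstrate the correctness of the
machinery (oracle equivalences, conservation laws, closed forms,
published benzene-scale observables within their stated tolerances).
They do not validate predictions for systems whose response departs from
the fixtures — heteroatom-rich, metallic (zero-gap), or periodic systems
— nor do they substitute for real Hirshfeld ratios on production
geometries.  Test problem sizes were chosen at benzene-dimer scale
(24 atoms, ~240k voxels) and below; the dense-algebra implementation
itself handles a few hundred atoms comfortably.

## Known limitations

* Hirshfeld volume ratios are consumed, never computed — they require an
  external DFT density.
* Dipole coupling only; no higher multipoles, no periodic boundary
  conditions or Ewald summation.
* The model's total binding energies in practice accompany a
  semi-local DFT calculation; this package reports the dispersion side
  only.
* Fully delocalized metallic response (type-C non-additivity) is outside
  the model's reach.
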