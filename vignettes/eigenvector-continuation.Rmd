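---
title: "Interpolating many-electron wave functions across molecular geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating many-electron wave functions across molecular geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`evcont` interpolates a correlated many-electron wave function — not the
potential energy — across molecular geometries. A full configuration
interaction (FCI) state in an $L$-orbital basis is a tensor of probability
amplitudes $C_{n_1,\dots,n_L}$ over occupation configurations
$\lvert n_1,\dots,n_L\rangle$. Both the amplitudes and the orbitals change
as atoms move; the trick is to pick an orbital representation in which the
amplitudes change as little as possible, and to keep that representation
orthonormal at every geometry so that the amplitudes can be carried over
verbatim between Hilbert spaces.

The symmetrically (Löwdin) orthogonalized atomic orbitals (SAOs),
$\chi_i = \sum_\alpha [S^{-1/2}]_{\alpha i}\,\phi_\alpha$ with $S$ the AO
overlap matrix, are the orthonormal set closest in the least-squares sense to
the atom-centred AOs, hence maximally atomic-like. Training states solved at
a few geometries are stored through their SAO amplitudes. For $N$ training
states the model keeps only geometry-independent pairwise data:

* transition two-body reduced density matrices
  $\Gamma^{ijkl}_{ab} = \langle\Psi^{(a)}\vert\,
  \hat c_i^\dagger \hat c_j^\dagger \hat c_l \hat c_k\,
  \vert\Psi^{(b)}\rangle$ (spin-summed; note the $k,l$ operator order, which
  the package fixes once and validates through an energy-reconstruction
  identity rather than trusting any printed convention),
* overlaps $\mathcal S_{ab} = \sum_{\mathbf n} C^{(a)}_{\mathbf n}
  C^{(b)}_{\mathbf n}$.

At a test geometry $R$ the electronic Hamiltonian is condensed into the
reduced two-body tensor
$$K_{ijkl}(R) = \tfrac12\langle ij\vert kl\rangle(R) +
\frac{1}{2(N_\mathrm{elec}-1)}\left(\delta_{jl}h^{(1)}_{ik}(R) +
\delta_{ik}h^{(1)}_{jl}(R)\right)$$
in the SAO basis of that geometry, so that
$\mathcal H_{ab}(R) = \sum_{ijkl}\Gamma^{ijkl}_{ab}K_{ijkl}(R) +
\mathcal S_{ab}E_\mathrm{nuc}(R)$ and the inferred state solves the
$N\times N$ generalized eigenproblem
$\mathcal H X = E\,\mathcal S X$. Inference therefore costs
$\mathcal O(N^2 L^4)$ — the exponential objects never reappear after
training. Because the ansatz is variational and linear in the training
states:

* the inferred energy is an upper bound to FCI at every geometry,
* it is exact at every training geometry (for exact training states),
* adding a training state can only lower the inferred surface, everywhere.

These three properties are asserted throughout the test suite and drive the
active-learning convergence monitor.

## Forces

The training amplitudes do not respond to geometry and the subspace
coefficients are variationally optimal, so $dE/dR$ has no response terms:
it is the inferred 2-RDM contracted with $dK/dR$, plus the nuclear-repulsion
derivative. $dK/dR$ combines (i) analytic AO-integral derivatives from the
exponent-ladder relation in the McMurchie–Davidson engine, and (ii) the
derivative of the orthogonalizer, $d(S^{-1/2})/dR$ — the Pulay term —
evaluated in the eigenbasis of $S$ through the divided-difference
(Daleckii–Krein) kernel
$-1/\bigl(\sqrt{\lambda_p\lambda_q}(\sqrt{\lambda_p}+\sqrt{\lambda_q})\bigr)$,
which has a finite limit at degeneracies and is equivalent to the Sylvester
relation $S^{1/2}X + XS^{1/2} = -S^{-1/2}\,dS\,S^{-1/2}$. Correctness is
defined operationally: every gradient path is validated against central
finite differences (default step $10^{-4}$ bohr for energies, $10^{-5}$ for
integrals), and the translational sum rule (zero net force) is checked to
$10^{-8}$.

## What is computed where

* **Integrals** (`compute_ao_integrals`, `compute_dipole_integrals`,
  `compute_integral_derivatives`): contracted-Gaussian s/p shells via
  Hermite (McMurchie–Davidson) recurrences; Boys function by series below
  argument 35 and closed form/upward recursion above. Basis data
  (STO-3G, STO-6G, 6-31G for H; STO-3G/6-31G s,p for C, N, O) live as plain
  text under `inst/extdata/basis`. Other bases or higher angular momenta go
  through `register_integral_backend()`.
* **FCI** (`fci_ground_state`): determinant CI over alpha/beta occupation
  strings; dense diagonalization up to dimension 2000, otherwise Davidson
  with a direct sigma build (compressed orbital-pair dgemm) and thick
  restarts. For $M_s=0$ singlet ground states the determinant-transpose
  symmetry halves the string work (`spin_symmetric`, on by default for
  single-root solves; disable it to target $M_s=0$ triplets).
* **Training data** (`transition_rdms`, `add_training_state`): spin-summed
  $\gamma$ and $\Gamma$ via $\langle a\vert E_{ik}E_{jl}\vert b\rangle$
  matrices assembled from contiguous string operations and one dgemm.
* **Dynamics** (`run_bomd`): velocity Verlet, NVE by default; Berendsen
  weak-coupling rescaling for NVT with $\lambda$ clamped to $[0.8, 1.25]$
  per step to avoid kicks at near-zero instantaneous temperature. Internal
  units are atomic (1 a.u. of time = 0.02418884254 fs); XYZ I/O is Å.
* **Active learning** (`active_learn_loop`): new training geometries
  maximize the minimum Hamiltonian distance
  $D(R,R') = \sum_{ij}\lvert h^{(1)}_{ij}(R)-h^{(1)}_{ij}(R')\rvert^2 +
  \tfrac12\sum_{ijkl}\lvert h^{(2)}_{ijkl}(R)-h^{(2)}_{ijkl}(R')\rvert^2$
  over SAO-basis integrals, so the measure inherits the model's translation
  and rotation invariance. Convergence is declared when the maximum
  variational lowering along the trajectory stays below $10^{-3}$ hartree
  for two consecutive enlargements.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tol` (Davidson) | 1e-9 | residual-norm convergence of training solves; energy error scales as residual²/gap, so looser values (1e-5, 1e-6) are used for survey-scale scans |
| `cutoff` (`infer_state`) | 1e-10 | relative overlap-eigenvalue cutoff of the canonical orthogonalization regularizing near-linear-dependent training sets; retained size is reported in `condition_report` |
| `dense_cutoff` | 2000 | determinant dimension below which dense diagonalization replaces Davidson |
| `fd_step` | 1e-4 / 1e-5 bohr | central-difference steps (energy / integral oracles) |
| `energy_tol`, `patience` | 1e-3 Eh, 2 | active-learning stopping rule |
| `dt` | 5 a.u. | MD timestep (0.121 fs) |
| Berendsen `tau` | — | thermostat time constant; 250 a.u. is a typical gas-phase choice |

## Warm starts

Davidson convergence in the SAO basis is slower than in canonical molecular
orbitals — localized orbitals spread the ground state over many
determinants, weakening the diagonal preconditioner, much as in Hubbard
chains. The package leans on two warm-start strategies instead: chained
starts along geometry scans/trajectories, and `continuation_guess()`, which
uses the inferred state $\sum_a X_a C^{(a)}$ of the current model as the
starting vector for the next training solve — the better the model, the
cheaper its own refinement.

## The synthetic study systems

All test systems are generated programmatically; nothing is downloaded.

* **Hydrogen chains** (`symmetric_stretch_series`): equidistant collinear
  H$_n$ chains — the standard strong-correlation benchmark. The H$_{10}$
  training set for the distortion study uses the equilibrium spacing
  (≈1.79 bohr) ± 0.5 and ± 1.0 bohr. Distorted configurations
  (`random_distortion_set`) displace every atom by a fixed magnitude along
  an independent uniform random direction, sampled per atom and per
  realization.
* **Water** (`water_geometry`): experimental equilibrium structure
  (r(OH) = 0.9572 Å, 104.52°); vibrational MD starts from a 10% symmetric
  O–H stretch, at rest.

These fixtures emulate the strong-correlation physics the method targets
(stretched bonds, distorted chains) but not everything in real molecular
data: no thermal ensembles of sizes beyond desk scale, no basis sets beyond
s/p shells, no solvent or nuclear quantum effects. Passing tests demonstrate
the variational structure, the gradient algebra, and convergence with a
handful of training states on these systems — not chemical accuracy in
large bases.

## Study sizes used by the test suite and acceptance script

Chosen as the smallest sizes that still exercise every claim: H$_6$ grids of
20 points over spacings 1.2–2.6 bohr with 3 training points; an H$_{10}$
stretch scan at 0.025-bohr resolution with spline interpolation of the
minimum; 20–100 random H$_{10}$ distortions of magnitude ≤ 0.4 bohr;
water/6-31G active learning to N = 6 with 25-step trajectories at
dt = 10 a.u. and FCI validation at 20 sampled frames; H$_2$ NVE runs of
2000–4000 steps for conservation and integrator-order checks.

A note on energy conservation: velocity Verlet is symplectic, so its total
energy shows a *bounded* oscillation of relative size
$\sim(\omega\,dt)^2/8$ around the true value plus an essentially vanishing
secular trend. The test suite checks the two separately — the secular drift
(difference of start/end window means) against an absolute bound, and the
oscillation envelope for the characteristic $dt^2$ scaling (a factor ≈ 4
when the timestep is halved).

## Design choices where the design was open

* **Conditioning of the subspace problem.** Nothing prescribes how to handle
  near-linear-dependence among training states; canonical orthogonalization
  with a relative 1e-10 cutoff is standard generalized-eigenproblem
  practice, keeps exactness at training points, and is reported rather than
  silent.
* **Operator-order convention of Γ.** The two printed orderings of the
  transition-RDM operator string differ by a transposition; the package
  fixes $\hat c_i^\dagger\hat c_j^\dagger\hat c_l\hat c_k$ and pins it down
  by requiring $\sum K\Gamma + \mathcal S E_\mathrm{nuc} = \langle a\vert
  \hat H\vert b\rangle$ to $10^{-10}$ in tests.
* **SAO ordering.** Atom-major, fixed by the input atom order; atomic
  permutations are deliberately not symmetrized (the representation is not
  permutation invariant, and pretending otherwise would corrupt amplitude
  transfer).
* **Degenerate ground states** are returned as produced by the
  deterministic solver (unit start vector on the lowest-diagonal
  determinant), making training-state selection reproducible but
  basis-dependent in degenerate sectors.
* **Model files** are versioned JSON: portable, diffable, and lossless at
  full double precision; CI amplitudes are intentionally excluded, so a
  loaded model infers but cannot be extended.
* **Distortion sampling.** Displacement directions are drawn independently
  per atom and per realization (normalized 3-D normal draws), with a
  counter-based seed so sample $i$ is independent of the sample count.

## Known limitations

* Only the dense determinant-FCI training backend is implemented; training
  states from matrix-product-state or active-space solvers are out of
  scope (the training interface accepts any `ci_vector` in the SAO basis).
* The built-in integral engine stops at p shells and ~30 basis functions
  (dense ERI storage); heavier systems need an external integral backend.
* Training and inference require the same orbital-space dimension: the
  model does not transfer across system sizes.
* No excited-state dynamics: only the lowest root is propagated, though the
  full inferred spectrum is exposed for diagnostics.
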