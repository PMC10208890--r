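---
title: "Mapping allosteric coupling from backbone electrostatics and NMR observables"
author: "allomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping allosteric coupling from backbone electrostatics and NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomap)
```

## The problem

A point mutation at one end of a protein can silence an active site tens of
angstroms away without visibly changing the average structure. Detecting
that kind of allosteric coupling requires looking at *fluctuations*: which
residues move together, which hydrogen bonds breathe together, which amide
resonances shift or broaden together. `allomap` implements a coherent set
of per-residue fluctuation analytics for backbone MD ensembles and solution
NMR data, all reduced to the same currency — per-residue profiles,
variant-minus-wild-type differences, and sigma-based significance calls —
so structural and spectroscopic evidence can be laid side by side in one
report.

This vignette documents the models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Backbone hydrogen-bond electrostatics

The elementary quantity is the Kabsch–Sander electrostatic estimate of a
backbone hydrogen-bond energy between a donor amide (N–H of residue *j*)
and an acceptor carbonyl (C=O of residue *i*):

$$E_{KS} = q_1 q_2 f \left(\frac{1}{d_{ON}} + \frac{1}{d_{CH}}
- \frac{1}{d_{CN}} - \frac{1}{d_{OH}}\right)$$

with partial charges $q_1 = 0.42\,e$ (carbonyl), $q_2 = 0.20\,e$ (amide),
dimensionality factor $f = 332$ kcal·Å/mol, distances in Å, and energy in
kcal/mol. The product $q_1 q_2 f = 27.888$ kcal·Å/mol. The energy is a
dipole–dipole coupling: it vanishes when $d_{ON} = d_{CN}$ and
$d_{CH} = d_{OH}$, and is homogeneous of degree −1 in the distances.

Amide hydrogens are never taken from the input file; they are always
rebuilt as $H(i) = N(i) + \hat{u}(O_{i-1} \to C_{i-1})$, a 1.0 Å N–H bond
anti-parallel to the preceding carbonyl (the classic DSSP reconstruction).
This keeps crystal-seeded and synthetic inputs on an identical footing.
Chain-start residues and prolines have no amide H and cannot donate.

Decisions where the convention was open:

* **Sequence-adjacent pairs** ($|i-j| = 1$ within a chain) are masked — no
  backbone H-bond is possible between covalent neighbors, matching standard
  DSSP practice.
* **Inter-chain pairs are evaluated by default** (`include_interchain`),
  because in oligomers the termini often pack against neighboring subunits
  and their coupling is precisely what one wants to see. A toggle removes
  them.
* **Steric clashes** (any distance below 0.5 Å) yield an `NA` sentinel plus
  an entry in a clash report, rather than DSSP's fixed minimum-energy
  clamp, so that downstream correlation statistics are not distorted by an
  arbitrary floor. `clash = "clamp"` restores the DSSP behavior for
  compatibility checks.

The full evaluation produces an R×R×F tensor indexed
[donor, acceptor, frame]. For long trajectories,
`residue_energy_series()` can consume the trajectory directly and
accumulate per-residue series frame by frame without materializing the
tensor; the two routes are tested to be identical.

## Secondary structure

Per frame, H-bonds below −0.5 kcal/mol (the standard Kabsch–Sander cutoff;
the threshold is exposed as `cutoff`) define n-turns (i accepts from
i+3/4/5), helices (two consecutive turns of matching stride), and
parallel/antiparallel bridges extended into ladders. The priority cascade
is reduced to H > E > G > I > B, and the 8-state alphabet collapses to
three classes: H,G,I → helix; E,B → strand; everything else → coil. Bend
and turn states are deliberately not distinguished — they are coil in the
3-state simplification that all downstream consumers use.

This is a *minimal* DSSP: on a lysozyme test structure it agrees with an
independent reference implementation (mdtraj's DSSP) at ~97% of residues,
with the differences at helix termini and isolated-bridge tie-breaks. The
per-residue output is the fraction of frames spent in each class; the
fractions sum to one by construction, and variant-minus-wt differences sum
to zero per residue.

## Flexibility

RMSF is computed per residue about the trajectory-mean position,

$$\mathrm{RMSF}(j) = \sqrt{\tfrac{1}{N}\sum_i |x_j(i) - \langle x_j\rangle|^2},$$

on CA atoms by default (a backbone-average option exists). Because the
reference is the *mean structure*, frames are first superposed with a
two-pass protocol: fit all frames to frame 1, compute the mean of the
fitted selection, re-fit all frames to that mean. The rotation is the
SVD-based least-squares solution with the determinant correction that
forbids reflections. Under isotropic Gaussian noise of SD σ per coordinate
the expectation is σ√3, which the tests verify to within 2%.

Hotspots of a difference profile are residues at least $k\sigma$ above the
mean (default $k = 2$), with the **population** SD — the choice matters
little at realistic n but is documented and switchable (`sd_type`).

## The electrostatic eigenvector centrality network

Each residue's couplings are symmetrized,
$e_{ij}(t) = E_{KS}(i{\to}j, t) + E_{KS}(j{\to}i, t)$, and summed into a
total electrostatic energy series $E_i(t)$. The network edge weight is
$a_{ij} = |\mathrm{corr}(E_i, E_j)|$ (zero diagonal, zero-variance series
excluded with a warning). Centrality is the principal eigenvector of this
non-negative symmetric matrix, computed by *shifted* power iteration — the
iteration matrix is $A + I$, which shares A's eigenvectors but has a
strictly dominant top eigenvalue even for bipartite graphs, whose ±λ pairs
stall the plain iteration. The start vector is uniform, convergence is
declared at an infinity-norm change below 1e-10 (cap 10,000 iterations),
and the result is unit-Euclidean-norm and non-negative, so centralities
and their differences are comparable across runs.

Open-design notes:

* The choice of |Pearson correlation| of per-residue *total* energy series
  is an interpretation — "correlation of electrostatic energy between
  residues" admits several constructions. A mean-absolute-coupling mode
  (`build_adjacency(mode = "energy")`) is provided for sensitivity
  analysis; the correlation mode is the default and is what the validation
  suite exercises.
* ΔEEC hotspots are called on the increase side only (residues whose
  network importance *grows* upon mutation); decreases are reported
  separately without a threshold.

## NMR analytics

**Chemical-shift perturbations.** The composite amide shift is
$\Delta\delta = \sqrt{(\Delta\delta_H^2 + (\Delta\delta_N/5)^2)/2}$ — the
¹⁵N difference is scaled by 1/5 *before* squaring (the standard weighting
by relative dispersion; formulas sometimes print the scaling inside the
square as "/25", which is the same thing). The significance threshold is
the 10% trimmed mean plus 1.5σ, with σ computed on the trimmed set by
default (`sd_on = "full"` gives the alternative reading). Line broadening
compares intensities after rescaling the variant by the *median*
per-residue height ratio — robust to receiver-gain/concentration
differences and to a perturbed minority — and flags residues at ≤ 50% of
the wild-type intensity; peaks present in wt but absent in the variant are
"broadened beyond detection" and always flagged. Variants are ranked by
significant-shift count plus broadened count (equal weight; ties broken by
total Δδ).

**Spin relaxation.** Rates come from nonlinear least squares on
$I(t) = I_0 e^{-Rt}$ (delays in ms, rates in 1/s), initialized from the
log-linear regression of positive heights; non-convergent or non-positive
fits mark the residue unfit and it is excluded downstream with a warning.
The default delay schedule in the synthetic generator is the standard
longitudinal design (0–2500 ms with duplicates at 20 and 600 ms); a
transverse schedule constant is included. Rate uncertainty follows the
replicate-spectra logic: the relative noise SD is estimated from
duplicate-delay pairs (mean absolute pair difference scaled for the
half-normal expectation), then the rate is refit over seeded Monte-Carlo
resamples; the SD of those rates is the reported uncertainty, with the
asymptotic fit-covariance error as the no-duplicates fallback. Difference
profiles $\Delta R_1, \Delta R_2, \Delta\mathrm{NOE}$ carry a ±1.5σ
trimmed-mean band computed per Δ dataset (not on the raw parameters — the
alternative is available through the same trimming machinery), and each
significant residue is annotated with its direction: positive
$\Delta R_1/\Delta R_2$ and negative $\Delta$NOE mean the mutant is the
more flexible species. T1/T2 summaries are reported in ms, and an advisory
rotational-correlation-time estimate
$\tau_c \approx \sqrt{6\,T_1/T_2 - 7}/(4\pi\nu_N)$ is printed when
$T_1/T_2 \ge 7/6$; it is a single-field approximation and deliberately not
treated as a precise output.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be validated
against *known* ground truth. It emulates:

* **Backbone fluctuations**: isotropic Gaussian noise per atom per frame
  about a base structure (ideal helix by default), with per-residue
  amplitude overrides. Frames are independent by default — the simplest
  model under which the RMSF and adjacency ground truths are analytic; an
  AR(1) option (`ar1_phi`) adds temporal autocorrelation at the same
  stationary amplitude for realism checks.
* **Correlated blocks**: a set of residues sharing collective motion,
  scaled by a latent weight in [0, 1]. Two components are injected:
  a rigid per-frame latent 3-vector displacing all member atoms together,
  and a per-frame scalar amplitude driving a fixed *hydrogen-bond stretch
  mode* on the i,i+4 backbone H-bonds internal to the block (acceptor O
  displaced along its C=O axis, donor N along the N···O axis).
  The rigid component correlates the members' displacement magnitudes but
  leaves their internal H-bond geometry — and hence their Kabsch–Sander
  energies — essentially untouched, because the energy is a dipole–dipole
  far field with respect to rigid motion. The stretch mode is what makes a
  block visible to the electrostatic network: it coherently modulates the
  members' H-bond energies, which is exactly the physical picture of a
  collective low-frequency mode breathing a set of hydrogen bonds. For the
  same reason, a block should be chosen *closed under H-bond partnership*
  (members in donor/acceptor pairs): the symmetrized pair coupling enters
  both endpoints' series, so a modulated bond always elevates both ends,
  and a block that dangles bonds to non-members necessarily bleeds
  centrality onto them.
* **Peak lists**: wild-type shifts uniform in realistic amide windows
  (¹H 6.5–10.5, ¹⁵N 105–135 ppm), variant = wt + specified perturbations,
  attenuated intensities for a broadened set, a global intensity factor,
  and optional Gaussian noise.
* **Decays**: mono-exponential series on the standard delay schedules with
  multiplicative noise and independently noisy duplicates.

Default amplitudes: `base_sigma = 0.1` Å per coordinate, latent amplitude
2× `base_sigma`. The 0.1 Å default is a deliberate choice of regime, not a
claim about real MD amplitudes: at ~0.5 Å per coordinate the 1/d terms of
the electrostatics become heavy-tailed (rare close approaches dominate the
variance) and Pearson correlations collapse toward zero, so injected
correlation structure would be invisible to *any* correlation-based
analysis. At 0.1 Å the electrostatics respond quasi-linearly and the
generator's ground truth is recoverable. Users studying the heavy-tailed
regime can simply raise `base_sigma`.

What the generator does **not** emulate: temporal autocorrelation,
anharmonic or multi-well dynamics, solvent effects, real side-chain
packing, and chemical-exchange line shapes. Passing tests therefore
demonstrate the *correctness of the analytics* (formulas, statistics,
thresholds, network algebra) on data whose generating process is known —
not that real proteins satisfy the generator's assumptions.

## Validation problem sizes

The test suite and the acceptance script run the full synthetic pipeline at
fixed sizes chosen to make their statistical claims meaningful: RMSF
recovery on 20 residues × 10,000 frames; correlated-block recovery on a
60-residue helix with a 6-residue block, 5,000 frames, and 20 seeded
replicate pairs; relaxation-rate recovery over 1,000 seeded replicates on
the standard 11-point delay schedule; the end-to-end determinism check on a
40-residue, 150-frame configuration. All randomness flows from explicit
seeds, and generators are pure functions of (spec, seed).

## Known limitations

* The minimal DSSP omits bend/turn/PP-II states and the full tie-break
  cascade; disagreements with reference implementations concentrate at
  helix termini and isolated bridges (observed ~3% of residues on
  lysozyme).
* The adjacency construction for the centrality network is one reasonable
  reading of "energy correlation"; conclusions should be checked against
  the alternative mode on real data.
* Binary trajectory formats (DCD/XTC) are out of scope; convert to
  multi-model PDB or the plain frame-table dialect first.
* The τc estimate assumes isotropic tumbling at a single field and is
  advisory only.
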