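---
title: "Hydration-shell and chain-extension analysis of thermoresponsive polymer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell and chain-extension analysis of thermoresponsive polymer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroshell)
```

## The scientific problem

Water-soluble polymers with a lower critical solution temperature (LCST) —
poly(glycidyl ether)s with oligo(ethylene oxide) side chains are the
motivating family — phase-separate from water on heating. Molecular dynamics
studies of such polymers probe two candidate order parameters:

1. **Chain extension.** The radius of gyration
   $R_g^2 = \frac{1}{N'}\sum_n (\mathbf{R}_n - \mathbf{R}_c)^2$ and the ratio
   of the time-averaged end-to-end length to the fully extended main-chain
   length, $\bar L/L_{max}$. For an ideal (freely jointed) chain of $N$
   units, $\bar L/L_{max} = 1/\sqrt{N}$: a measured ratio above that
   reference indicates a coil, below it a globule.
2. **Hydrophobic hydration.** The radial distribution function (RDF) of
   water oxygens around the side-chain terminal carbons,
   $g(r) = \langle n(r)\rangle / (4\pi r^2\,\Delta r\,\rho)$, has a first
   peak near 3.6 Å — the hydrophobic hydration shell. Its intensity decays
   on heating; the temperature at which it falls below the bulk value
   $g = 1$ (the crossing temperature, TCRP) tracks the experimentally
   measured cloud point (TCLP).

`hydroshell` implements these computations as a reusable, tested pipeline:
trajectory I/O with role-based atom selections, chain metrics, the solvation
RDF with first-shell peak tracking and TCRP, geometric hydrogen-bond
statistics, and a command-line / config driven orchestrator. Because production
all-atom trajectories are rarely deposited, the package ships a
first-class synthetic-data module whose generators plant known statistical
structure, so every stage is verifiable against closed forms or
planted-parameter recovery.

## Conventions

Coordinates are in Å, time in ps, temperature in K (the toy simulator uses
reduced units, see below). Boxes are orthorhombic only; triclinic input is
rejected. Standard deviations use the sample ($n-1$) convention throughout,
and CV = SD/mean; both choices are validated by reproducing printed
fluctuation tables from their five per-temperature inputs. Table-style
reports round half away from zero (`round_half_up()`).

## Chain metrics

- **Ideal-chain reference.** The coil/globule reference is implemented as
  $1/\sqrt{N}$. Published tabulations of this reference are
  sometimes typeset as "1/N", but the values printed alongside equal
  $1/\sqrt{N}$ at two decimals for every chain length encountered here
  (e.g. $1/\sqrt{28} = 0.189 \to 0.19$, while $1/28 = 0.036$ contradicts
  them), so the square-root reading is adopted and documented here
  prominently.
- **$R_g$** is unweighted over the selected atoms, matching the defining
  equation; a mass-weighted variant exists behind the `masses` argument but
  is off by default.
- **$L_{max}$** has no single operational definition in the field. Two modes are
  provided: `sum_of_bonds` (the contour length; exact for the synthetic
  freely jointed chains, and the default) and `zigzag` (contour ×
  $\sin(109.47°/2) \approx 0.8165$, the all-trans projection for tetrahedral
  all-atom backbones). Neither is asserted to be what any particular
  published analysis used.
- **Periodic unwrapping.** Chains are made whole by walking the selection
  order and shifting each atom to the image nearest its predecessor; this is
  exact while consecutive bonds are shorter than half the box.
- **$R_g$ distributions** use 0.1 Å bins, Gaussian smoothing with a
  bandwidth of 2 bins, and report local maxima with prominence at least 5%
  of the maximum density; the principal peak is the global maximum and the
  quoted SD is that of the raw series (there is no canonical procedure;
  all three knobs are arguments). The global maximum takes its full height as
  prominence so a degenerate single-bin histogram still reports its peak.

## The solvation RDF and TCRP

The estimator bins minimum-image reference→target distances at
`dr = 0.1 Å` up to `min(box)/2 − dr`, normalizing by the bin-centre shell
volume and the bulk density ρ = (target count)/(mean box volume). Computing
ρ from the target selection rather than taking a user constant matches the
"bulk density" reading of the defining equation under volume fluctuation.
One consequence at synthetic test scale: a planted shell adds
$n_{ref}\cdot(A-1)\int 4\pi r^2 e^{-(r-r_0)^2/2\sigma^2}dr$ excess particles,
inflating ρ and biasing $g$ down by about 1% in the shipped test geometry —
an understood property of the stated test world, not an estimator defect.

**First-peak detection.** The naive rule — take the first local maximum
after 3-point smoothing — turns out to be unusable on real estimates: a finite-count
$g(r)$ estimate is never flat, so the approach region below the shell always
contains spurious local maxima and the literal rule latches onto noise at
$r \approx 2.2$ Å even at 3% per-bin noise (prominence filtering fails too,
because wandering noise accrues prominence over long flat stretches). The
package therefore defines the first-shell peak as the *global maximum of the
smoothed curve inside the search window* ([2.0, 5.5] Å by default, motivated
by the ~3.6 Å shell), required to be an interior local maximum of the full
curve. A monotone profile reports "no peak" — a representable outcome
distinct from an error — and exact ties resolve to the smallest $r$,
preserving the intended tie rule. If the window maximum sits on a window
edge (a curve still rising toward bulk), the detector falls back to the
highest interior local maximum, which stabilizes detection of weak
high-temperature shoulders. `first_peak()` reports both the smoothed
intensity (the default fed to TCRP) and `g_raw`, the unsmoothed value at the
detected bin: 3-point smoothing attenuates a σ = 0.3 Å Gaussian shell by
about 2.5%, so planted-amplitude recovery is asserted on `g_raw`.

**TCRP.** The crossing is located at the first adjacent temperature pair
with $g(T_i) \ge 1 > g(T_{i+1})$ and linearly interpolated inside it;
published crossings are reported at integer Kelvin without a stated
interpolation rule, so linear is declared here and integer rounding applied
only in table output. A curve that never drops below threshold yields "no
crossing" (the phenomenology of the one polymer without an observed cloud
point requires absence to be representable).

**Replicate handling.** Replicates are averaged at the level of derived
statistics; for RDFs the default averages $g(r)$ across replicates before
peak detection (the alternative order — detect, then average peaks — is
available by applying `first_peak()` per replicate).

## Hydrogen bonds

Geometric criteria: donor–acceptor distance $d(D\cdots A) \le d_{max}$ and
donor–H–acceptor angle $\ge$ `angle_min`, evaluated at the hydrogen with
minimum-image vectors, boundaries inclusive. Geometric criteria vary
across the MD literature; the defaults 3.5 Å / 150° are a documented
package choice, and absolute H-bond counts from any particular study are
deliberately **not** used as targets.
Donors are O–H and N–H by default — a pure polyether has none, so the
intrapolymer count is structurally zero, matching the reported
"almost zero"; an optional C–H donor mode supports sensitivity analysis of
that assumption. Candidate pairs come from a compiled brute-force cutoff
search (an $O(nm)$ kernel outruns R-level cell-list bookkeeping at the frame
sizes this package targets); equivalence with a pure-R all-pairs oracle is
enforced in the tests. Per-oxygen normalization divides each class mean by
the total oxygen count of that class (main-chain vs side-chain), as labelled.

## The synthetic-data module

The generators emulate the statistical structure the analyses assume —
nothing more:

- `gen_fjc()`: freely jointed chains with exact step length; the ensembles
  obey $\langle L^2\rangle = Nb^2$ exactly and
  $\langle R_g^2\rangle = \frac{N(N+2)}{6(N+1)}b^2$ (the discrete closed
  form, whose large-$N$ limit is the familiar $Nb^2/6$; at $N = 9$ the two
  differ by 10%, far beyond Monte-Carlo error, so tests assert the exact
  form and check the limit form only at $N = 100$).
- `gen_shell_cloud()`: solvent points thinned from a uniform cloud against
  $g^*(r) = 1 + (A-1)e^{-(r-r_0)^2/2\sigma^2}$ of the nearest reference;
  reference independence is enforced by a non-overlap precondition. The
  per-frame count is fixed at the expected total (bulk + shell excess) so
  trajectories keep a constant atom count while the planted profile and the
  far-field density ρ are preserved. Note that a planted amplitude $A < 1$
  is a *trough*: the correct recovery is "no peak", which the tests assert
  via the exact planted profile.
- `gen_hbond_fixture()`: acceptor/water geometries placed at exact distances
  and angles with explicit margins (default −0.2 Å / +0.3 Å / ±10°), so the
  inclusive-boundary convention is auditable down to ±10⁻⁶ margins.
- `run_toy_langevin()`: the surrogate for production MD (below).
- `write_fixture()` emits PDB + multi-frame XYZ + a role-map YAML, so
  synthetic data exercises the same I/O path as real data.

All generators are bit-reproducible under a fixed seed.

## The toy simulator and its planted crossing

`run_toy_langevin()` integrates overdamped Langevin dynamics
(Euler–Maruyama, NVT, periodic box, reduced units $k_B = m = 1$; the
per-step displacement is clamped at 0.3 σ as an overlap safeguard):
a semiflexible bead-spring chain (harmonic bonds at rest length σ = 3.4 Å,
cosine bending stiffness) in an explicit WCA solvent. Every second polymer
bead is a "terminal" bead standing in for a side-chain end group: solvent
beads feel an additional Lennard-Jones attraction of depth `terminal_epsilon`
toward it, while the *other* polymer beads repel solvent with an enlarged
WCA diameter (`backbone_sigma_factor`, default 1.1), emulating bulky
backbone/side groups that partially bury the terminal sites.

That occlusion is the planted mechanism: the measured first-shell intensity
behaves like $f\cdot e^{\varepsilon_t/T}$ with an accessibility factor
$f < 1$, so it *decreases on heating and crosses $g = 1$* at a finite
temperature — the toy analogue of hydration-shell melting — even though
$\varepsilon_t$ is fixed. Calibration of the shipped defaults
($\varepsilon_t = 0.75$, density 0.15, bend stiffness 40, friction 0.7,
16-bead chain, 200 solvent beads) puts the crossing at $T^* \approx 1.3$–1.5
in reduced units, with first-shell intensities ≈ 1.56 ± 0.07 at $T = 0.6$
and ≈ 0.86 ± 0.05 at $T = 2.4$ (32 000 steps). The acceptance experiment
therefore uses the planted bracketing pair (0.6, 2.4) and requires the
recovered crossing to fall inside it in ≥ 95% of 20 seeded replicates.
Design choices made for sampling reasons, decided once and frozen:

- the chain is semiflexible (default `bend_k = 40`) and initialized as a
  rod — a flexible chain's occlusion geometry drifts on conformational
  timescales far beyond desk-scale runs, inflating the replicate variance
  three-fold;
- simulations of 16 000–32 000 steps with frames every 10–20 steps: frame
  correlation means the error is controlled by total simulated time, not
  frame count;
- temperatures are labelled in reduced units even though the trajectory
  container nominally carries Kelvin.

What a green toy-recovery test establishes: the full pipeline (simulate →
RDF → peak curve → crossing) recovers a *planted* transition. What it does
not establish: force-field fidelity, NPT effects, electrostatics, or any
published polymer-specific TCRP value — reproducing those requires the
original tens-of-nanoseconds all-atom trajectories, which is explicitly out
of scope.

## Worked example

```{r, eval = FALSE}
library(hydroshell)

# planted hydration shell: amplitude 2.0 at 3.6 Å on bulk water density
tr <- gen_shell_cloud(r0 = 3.6, sigma = 0.3, amplitude = 2.0,
                      bulk_density = 0.0334, box = 60, n_ref = 16,
                      n_frames = 200, seed = 1)
r <- rdf(tr, select_role(tr$topology, "terminal_carbon"),
         select_role(tr$topology, "water_oxygen"), dr = 0.1, r_max = 14)
first_peak(r)        # r = 3.65, g_raw = 1.98 (one bin / 1% from planted)

# crossing temperature from a tabulated intensity curve
tcrp(gen_peak_curve(c(300, 350), c(1.2, 0.8)))   # TCRP = 325.0 K
```

## Known limitations

- No DCD reader: XYZ + PDB are the reference path (binary formats add
  nothing at the fixture scale this package targets).
- Orthorhombic boxes only.
- The RDF normalization assumes the target species' bulk density is well
  estimated by count/volume; for very small boxes with strong planted
  shells this carries the ~1% bias discussed above.
- The toy simulator is a statistical surrogate, not an MD engine: no
  barostat, no constraints, no electrostatics, pair potentials only.
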