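# hydroshell

Trajectory analysis for LCST-type thermoresponsive polymers in water —
chain-extension statistics, hydrophobic-hydration-shell RDFs with the
crossing-temperature statistic (TCRP), and polymer–water hydrogen-bond
counts — plus a synthetic-data module (ideal chains, planted hydration
shells, hydrogen-bond geometry fixtures, and an overdamped Langevin
bead-spring toy simulator) that makes the whole pipeline testable without
access to production MD trajectories.

## Who it is for

Researchers analysing molecular-dynamics trajectories of water-soluble
polymers (e.g. poly(glycidyl ether)s with oligo(ethylene oxide) side
chains) who want reproducible, unit-tested implementations of the standard
observables used to probe coil–globule behaviour and hydration-shell
melting around a phase transition.

## The statistics at its core

- **Radius of gyration** `Rg² = (1/N′) Σₙ (Rₙ − R꜀)²` over selected atoms,
  with histogram/peak analysis of the `Rg` time series.
- **Chain extension** `L̄/Lmax` — time-averaged end-to-end length over the
  fully extended main-chain length — against the ideal-chain reference
  `1/√N`: above it the chain is classed a coil, below a globule. SD and
  CV (= SD/mean, sample convention) quantify fluctuation.
- **Solvation RDF** `g(r) = ⟨n(r)⟩ / (4π r² Δr ρ)` of water oxygens around
  side-chain terminal carbons under minimum-image periodic boundaries;
  the first peak near 3.6 Å is the hydrophobic hydration shell.
- **TCRP**: the temperature at which the first-peak intensity crosses the
  bulk value g = 1, located by linear interpolation between bracketing
  temperatures of the peak-intensity curve.
- **Hydrogen bonds**: geometric criteria d(D···A) ≤ 3.5 Å and
  ∠(D–H···A) ≥ 150° (configurable), split by main-chain vs side-chain
  acceptor oxygens and normalized per oxygen.

## Worked example

```r
library(hydroshell)

# 1. a planted hydration shell: amplitude 2.0 at r0 = 3.6 Å over bulk
#    water density 0.0334 Å⁻³, sampled around 16 reference atoms
tr <- gen_shell_cloud(r0 = 3.6, sigma = 0.3, amplitude = 2.0,
                      bulk_density = 0.0334, box = 60, n_ref = 16,
                      n_frames = 200, seed = 1)
r <- rdf(tr, select_role(tr$topology, "terminal_carbon"),
         select_role(tr$topology, "water_oxygen"), dr = 0.1, r_max = 14)
first_peak(r)
#> $found
#> [1] TRUE
#> $r
#> [1] 3.65
#> $g
#> [1] 1.925121
#> $g_raw
#> [1] 1.981051
```

The detector recovers the planted shell at 3.65 Å (within one 0.1 Å bin of
the planted 3.6) with raw intensity 1.98 (1% from the planted 2.0; the
smoothed value 1.93 reflects the documented 3-point-smoothing attenuation).

```r
# 2. the crossing temperature from a peak-intensity curve
tcrp(gen_peak_curve(c(300, 350), c(1.2, 0.8)))
#> TCRP = 325.0 K (bracketed by 300 and 350 K, linear_interpolation)

# 3. ideal-chain coil/globule reference for a 28-mer
round_half_up(ideal_chain_ref(28), 2)
#> [1] 0.19
```

A multi-temperature run — trajectories on disk (PDB + multi-frame XYZ +
role-map YAML) or simulated in-memory — is orchestrated by
`run_pipeline(config)` or the CLI (`synth | simulate | rg | chain |
sidechain | rdf | tcrp | hbonds | report`):

```sh
Rscript -e 'hydroshell::hs_cli()' tcrp --curve curve.tsv     # prints 325.0
Rscript -e 'hydroshell::hs_cli()' report --config run.yaml
```

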