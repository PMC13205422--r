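# gelmesh

Computational analysis of drug retention and release in pH/temperature
dual-responsive **P(NIPAM-co-AAc) nanogels**, for researchers who study
stimuli-responsive drug carriers with molecular simulation and in vitro
release experiments.

Whether a hydrophobic drug like ibuprofen (IBU) leaves such a carrier is
governed by two coupled mechanisms: **mesh steric sieving** — can the drug
fit through the hydrated network's pore bottlenecks? — and **affinity
switching** — do protonation-dependent polymer-drug hydrogen bonds anchor
it? `gelmesh` implements the full desk-side pipeline around that question:

* **Network construction** — explicitly cross-linked P(NIPAM-co-AAc)/BIS
  topologies by iterative template-matching reaction cycles on a widening
  distance-cutoff ladder (3.5 → 5.0 Å), with surrogate-energy relaxation
  between cycles and pruning of unreacted cross-linker.
* **Pore descriptors** — the pore limiting diameter (PLD, the transport
  bottleneck: the largest probe that percolates the periodic network,
  found by distance-grid transform + Hoshen-Kopelman cluster labeling) and
  the maximum pore diameter (MPD, the largest local cavity), with a
  steric-accessibility classification against the drug's molecular
  dimensions (X = 6.78, Y = 7.47, Z = 12.03 Å for IBU).
* **Trajectory statistics** — diffusion coefficients via the Einstein
  relation `D = slope(MSD)/6`; the dissociated fraction
  `f_det = 100 · N_det/N` under the 5 Å average-minimum-distance
  criterion; geometric hydrogen-bond counts (3.5 Å / 35°) by category;
  radial number density profiles.
* **Release analysis** — cumulative release with sample-withdrawal
  correction; zero-order, first-order, Higuchi and Korsmeyer-Peppas
  (`M_t/M_inf = k·t^n`) kinetic fits with Fickian/anomalous transport
  classification; release AUC (1-24 h, trapezoidal); within-material
  centering and Spearman rank correlation of simulation descriptors with
  release.
* **Synthetic data** — seeded generators with analytic ground truth for
  every input class (Brownian ensembles, dissociation scenarios, release
  curves, pore phantoms, hydrogen-bond triplets), so the whole pipeline is
  testable without any MD output.

Reference tables for the sixteen studied systems (4 compositions × 2 pH ×
2 temperatures; descriptors and kinetic parameters) ship in
`inst/extdata/` and join freely against the
`Polymer-AAcPct-{L,H}-{298,310}` system-ID grammar (e.g. `CA-15-H-310`).

## Worked example

```r
library(gelmesh)

# Two limiting protonation states: the Henderson-Hasselbalch degree of
# deprotonation of the carboxyls (pKa 4.75) in the two media
henderson_hasselbalch(c(2.75, 7.4))
#> [1]  0.990099 99.776628

# Dissociated fraction: a constructed final-window ensemble where 11 of
# 50 drug molecules sit beyond the 5 A contact criterion
tr <- gen_dissociation_scenario(n_total = 50, n_free = 11, cutoff = 5,
                                margin = 1, seed = 1)
dissociated_fraction(tr, cutoff = 5)$fraction
#> [1] 22

# Diffusion: a 50-molecule Brownian ensemble generated at
# D = 8.61e-7 cm^2/s, recovered by the MSD/Einstein estimator
ens <- gen_brownian(D = 8.61, n_mol = 50, dt = 1, n_steps = 10000, seed = 1)
fit_diffusion(msd(ens))
#> D = 9.1 x 1e-7 cm^2/s (slope 0.05459 A^2/ps over 900-999 ps, r^2 = 1.0000)

# Pore descriptors on a phantom with a known answer: a cylindrical
# channel of radius 3 A has PLD = MPD = 6 A
ph <- gen_pore_phantom("channel", r = 3, box = 12)
g  <- distance_grid(ph, spacing = 0.4)
c(pld = pore_limiting_diameter(g), mpd = max_pore_diameter(g))
#>      pld      mpd
#> 6.000035 6.007782

# Steric state of a real descriptor pair: bottleneck narrower than the
# drug's width, but cavities larger than its length
classify_steric_state(5.88, 12.46)
#> [1] "bottleneck_with_free_pockets"

# Kinetics round trip: regenerate a release curve from the bundled
# Korsmeyer-Peppas parameters of CA-20-H-298 and refit it
ref  <- release_kinetics_reference()
row  <- ref[ref$system_id == "CA-20-H-298", ]
prof <- gen_release_curve("korsmeyer_peppas", list(kKP = row$kKP, n = row$n),
                          times = c(1, 2, 4, 8, 12, 24), seed = 1)
fit_kinetics(prof, "korsmeyer_peppas")
#> korsmeyer_peppas fit: kKP = 0.37, n = 0.256; r2 = 1.000; mechanism: Fickian
```

The numbers mean: the acidic medium keeps carboxyls ~99% protonated while
the basic one deprotonates ~99.8% of them; 22% of the constructed ensemble
is dissociated (11/50, and every attainable value at N = 50 is a multiple
of 2%); the Einstein estimator recovers the generating diffusion
coefficient within sampling error on a single seed (averaging seeds
tightens it to a few percent); the percolation analysis recovers a
phantom's exact bottleneck within a grid spacing; and the release exponent
n = 0.256 < 0.5 classifies transport as Fickian diffusion.

An end-to-end demonstration (build → pores → metrics → kinetics →
correlate, with per-stage CSV/JSON outputs and a manifest) runs via

```r
run_pipeline(run_config("out-demo", seed = 1))
```

and a thin command-line front end over the same functions lives at
`inst/cli/gelmesh.R`.

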