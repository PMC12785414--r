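# chromodyn

Post-processing toolkit for molecular-dynamics trajectories and
pH-titration spectra of β-barrel fluorescent proteins, built around the
questions raised by chromophore-modified red FPs such as the
mCherry M66C (thiol-chromophore) variant: how mobile is the chromophore,
which interstrand gates do chromophore-associated waters leave through,
how long do they reside, and which ionization states explain the
pH-dependent spectra.

## What it computes

**Trajectory statistics** (all internal units nm/ns; Å only at PDB
boundaries):

- Kabsch least-squares superposition; per-frame RMSD of a measured
  selection after fitting on another (e.g. chromophore heavy atoms after
  Cα fitting); per-atom or per-residue RMSF about the time-averaged
  structure, and RMSF difference profiles between variants.
- Geometric hydrogen bonds (donor–acceptor ≤ 0.35 nm,
  H–donor–acceptor ≤ 30° by default), counted per frame and partitioned
  by partner class (protein vs water).
- **Water residency**: the residency time of a water is the earliest
  time *t\** from which its oxygen's distance to the chromophore's
  β-methylene bridge atom stays above 2 nm for at least 0.1 ns
  continuously. Departed waters are assigned an exit region — one of
  four interstrand gates (bulge-split strand 7 vs strands 10/8, strand 3
  vs 11) — by the nearest gate centroid at the first frame of the
  persistent excursion. Per-water mean ± sample sd across runs, with
  censored (never-exiting) waters reported as `> duration`.
- Interstrand distance series (e.g. the A145–K198 and T43–Y214 Cα
  pairs) and 0.1 nm-binned distance distributions with their modes.
- Two-state segmentation of chromophore RMSD series (deterministic 1-D
  two-means) and the acylimine carbonyl flip angle, with persistent
  ~180° flip events.

**Titration analysis**: a sequential ionization model for the
chromophore. For the thiol variant, three species — SH/OH (band at
420 nm), SH/O⁻ (566 nm), S⁻/O⁻ (543 nm) — with fractions

    p(SH/OH) = h²/D,  p(SH/O⁻) = h·K1/D,  p(S⁻/O⁻) = K1·K2/D,
    D = h² + h·K1 + K1·K2,   h = 10^-pH, Ki = 10^-pKai

Dual-wavelength absorbance ratio curves (A566/A425 over pH 4.5–8 for the
low-range phenol pKa; A544/A566 over pH 6–11 for the high-range thiol
pKa) are fitted with the Henderson–Hasselbalch sigmoid

    R(pH) = R_lo + (R_hi − R_lo) / (1 + 10^(pKa − pH))

**Synthetic data**: `gen_trajectory()` builds a stylized 11-strand
barrel with a chromophore, and plants water escapes through named gates,
carbonyl flips, scripted H-bond counts and gap breathing — recording the
schedule as ground truth — so every analysis stage is testable without
any real (unpublished) trajectory. `gen_titration()` does the same for
spectra.

## Worked example

```r
library(chromodyn)

# a 10 ns synthetic run: two waters planted to leave at 2.5 ns (gate
# "Reg 1") and 6 ns ("Reg 4"), carbonyl flips at 3 and 7 ns
w <- data.frame(water_id = c("W1", "W2"), exit_time = c(2.5, 6.0),
                region = c("Reg 1", "Reg 4"))
spec <- trajectory_spec(duration = 10, frame_interval = 0.01,
                        noise_sd = 0.01, waters = w, flips = c(3, 7),
                        seed = 42)
run <- gen_trajectory(spec)
run$trajectory
#> <chromo_traj> 117 atoms, 1001 frame(s), 0-10 ns
#>   residues: 98  chains: A,W

residency_table(run$trajectory, c(1001, 1002), load_regions(),
                water_ids = c("W1", "W2"))
#>   water_id residency_ns censored exit_region decision_margin_nm
#> 1       W1          2.5    FALSE       Reg 1          0.3628116
#> 2       W2          6.0    FALSE       Reg 4          0.9740328

# noiseless titration planted with pKa 5.7/8.8; low-range ratio fit
tit <- gen_titration(titration_spec(ionization_model(5.7, 8.8)))
fit <- fit_pka(ratio_curve(tit$series, 566, 425, window = c(4.5, 8)))
sprintf("low-range pKa: %.3f", fit$pka)
#> [1] "low-range pKa: 5.700"
```

Both planted waters are recovered at exactly their planted times and
gates (the decision margin is the distance gap to the second-nearest
gate), and the ratio fit returns the planted pKa to three decimals.

`run_pipeline(config, out_dir)` chains generator (or PDB input) →
analyses → report tables (TSV/JSON plus a manifest with file hashes)
for multi-run studies; see the methods vignette.

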