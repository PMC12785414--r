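---
title: "chromodyn: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromodyn: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromodyn post-processes molecular-dynamics trajectories and
pH-titration spectra of β-barrel fluorescent proteins. This vignette is
the package's own account of the models it implements, the parameters
that matter, and the places where the design was genuinely open and a
choice had to be made.

## Units, containers, conventions

Coordinates are nm and times ns everywhere inside the package;
Ångströms appear only when reading/writing PDB files and when reporting
crystal-to-crystal RMSDs, where Å is the field's convention. A
trajectory couples a topology (author residue numbering is preserved —
F65, C66/M66, Q42, A145, K198, T43, Y214 keep their familiar numbers)
with an `n_atoms × 3 × n_frames` coordinate array and strictly
increasing, uniformly spaced frame times. Multi-model PDB is the
portable trajectory dialect; the file format carries no time axis, so
the frame interval is declared at read time. The default interval of
0.01 ns makes a 1000 ns production run exactly 100,001 frames inclusive
of both endpoints, the cadence of the simulations this package's
analyses are shaped around; it is config-overridable because that
cadence is a convention, not a constant of nature.

## Superposition and fluctuation statistics

Rigid superposition is the closed-form Kabsch solution (SVD of the
3 × 3 covariance with a determinant correction guaranteeing a proper
rotation). Degenerate inputs — fewer than three points, coincident or
collinear sets — are errors, not warnings, because a silently
ill-conditioned fit poisons every downstream series.

Per-frame RMSD series fit on one selection and measure on another:
the standard arrangement fits on protein Cα and measures over
chromophore heavy atoms, so the series reports internal chromophore
motion rather than global tumbling. The chromophore selection includes
the acylimine atoms contributed by the preceding residue (F65), since
the conjugated system extends through that carbonyl.

RMSF uses a two-pass reference: frames are aligned to frame 1, the
time-average structure is formed, frames are re-aligned to that
average, and fluctuations are taken about the re-averaged structure.
This is the standard stable choice; a single-pass reference biases
fluctuations toward whatever frame was chosen. No mass weighting is
applied anywhere — the Cα/heavy-atom analyses here are geometric, and
introducing masses would add a parameter without changing any
conclusion these profiles support. For isotropic Gaussian jitter of
per-coordinate sd σ the per-atom RMSF converges to σ√3, which the test
suite uses as a closed-form oracle.

## Hydrogen bonds

A donor–hydrogen⋯acceptor triple counts as a hydrogen bond when the
donor–acceptor distance is ≤ 0.35 nm and the hydrogen–donor–acceptor
angle is ≤ 30°. These are the documented defaults of the common MD
analysis tools and are exposed in `hbond_criteria()`. Donor/acceptor
typing is a deliberately small rule table — N and O acceptors, N and O
donors when they carry a declared hydrogen — and is overridable,
because no published enumeration exists for chromophore chemistries
like the acylimine. Topologies without declared hydrogens (crystal
structures) are an explicit unsupported error: inferring hydrogen
positions silently would manufacture bonds the data cannot support.
Partitioned counting is direction-agnostic (the group atom may donate
or accept) and requires partner classes to be disjoint, making
`total = Σ class counts` an invariant rather than a hope.

## Water residency and exit classification

The residency statistic is the package's central definition: the
residency time of a water is the earliest `t*` such that its
oxygen-to-bridge-atom distance exceeds 2 nm at **every** sampled frame
in `[t*, t* + 0.1 ns]`, window inclusive of its start frame — a
literal reading of "consistently above". Both the 2 nm cutoff and the
0.1 ns persistence are parameters of `residency_criteria()`; the
reference atom defaults to the chromophore β-methylene bridge carbon
(atom name `CB2` in the standard chromophore component naming) but is
selection-overridable because the atom *role*, not a PDB name, defines
the statistic. The detector is run-length based and is tested for
exact agreement against a brute-force scan over all windows.

A water that never satisfies the criterion is *censored*: reported as
`> duration`, excluded from mean/sd aggregation, and counted
separately. One published residency of ">10,000 ns" inside a 1000 ns
run is treated as exactly this — "never exited" — rather than as a
number.

Exit classification is this package's own operationalization (no
published geometric rule exists for these assignments): at the first frame
of the persistent excursion, the water is assigned to the interstrand
gate whose centroid — the mean Cα position of the gate's two residue
segments at that frame — is nearest. At that moment the water sits
≈2 nm from the barrel core, just beyond the surface, where the nearest
gate is still unambiguous; the margin to the second-nearest gate is
recorded with every decision so that borderline assignments are
auditable. Ties break to the earlier region label, for determinism.
The four shipped gates follow the barrel taxonomy: Reg 1 =
S7A-bulge (139–145) × S10, Reg 2 = S7B (146–153) × S10, Reg 3 =
S7A-bulge × S8, Reg 4 = S3 × S11. Residue ranges for S3/S8/S10/S11 are
not published; they ship as an editable text config, not constants in
code.

Aggregation uses the arithmetic mean and the sample (n−1) sd across
runs. One rounding discrepancy is knowingly not reproduced: the
published per-run values 7.1/4.07/7.6 ns average to 6.26 ns, which
rounds to 6.3 rather than the printed 6.2; the sd (1.9) and the other
printed summaries follow exactly from the printed per-run values.

## Chromophore states and the carbonyl flip

Two-state segmentation of an RMSD series is deterministic 1-D
two-means: centres initialise at the series min/max, assignment is by
the midpoint threshold, and the loop runs to a fixed point. This is an
*operationalization* of the by-eye identification of "low/high RMSD
forms" common in trajectory analysis — stated as this package's
definition, not anyone else's. It is label-invariant under affine
rescaling of the series, and a numerically constant series returns one
state with zero switches rather than an arbitrary split.

The acylimine carbonyl flip is monitored as the signed dihedral of
imidazolinone-N, acylimine-Cα, carbonyl-C and carbonyl-O (default atom
quadruple `N2–CA1–C1–O1`, overridable: the moiety, not the atom names,
is what is named in the literature). A flip event is a departure of
≥ 120° (wrapped) from the first-frame reference persisting ≥ 0.05 ns.
The 120° threshold separates the ~180° flip from the ≤ 50° in-plane
rotations also seen in these systems, and whether a ~50° rotation
constitutes a distinct state is deliberately left to threshold
configuration. The 0.05 ns persistence sits above the frame interval
(suppressing single-frame noise) and below the residency persistence
scale.

## Ionization model and ratiometric pKa fitting

The titration model is strictly sequential: phenol deprotonates first,
thiol second, so the species are SH/OH → SH/O⁻ → S⁻/O⁻ and the mixed
S⁻/OH state is excluded. That follows from assigning the neutral-pH
spectrum to the thiol–phenolate form; including a fourth state would
add a parameter the dual-wavelength data cannot identify. Fractions
are the exact sequential-scheme expressions (see README); they sum to
1 at machine precision and are monotone in pH, both of which are
tested as invariants.

Ratio fitting uses the Henderson–Hasselbalch sigmoid with the Hill
coefficient fixed at 1 (a free-n variant exists behind a flag). The
functional form actually used for the published ratio plots is not
stated anywhere; the sigmoid is this package's definition. Fit windows
default to pH 4.5–8 (low range, A566/A425) and pH 6–11 (high range,
A544/A566), the windows of the published plots.

**Why the default basis spectra look the way they do.** A
two-wavelength ratio `A(λnum)/A(λden)` of a two-species mixture is an
exact sigmoid in pH, but its midpoint is the true pKa **only if the
denominator wavelength is an isosbestic point** of the transition —
otherwise the apparent midpoint shifts by `log10` of the two species'
absorbance ratio at λden. This is the textbook validity condition for
ratiometric assays, and single Gaussian bands at 420/566/543 nm cannot
satisfy it (the anionic species would absorb essentially nothing at
425 nm and the low-range ratio would grow exponentially instead of
saturating — un-fittable). Real chromophore spectra do retain weak
blue absorbance in their anionic forms. The default basis therefore
gives each anionic species a weak secondary blue band with the same
shape as the neutral species' main band (so 425 nm is exactly
isosbestic for the low transition) and sets the S⁻/O⁻ main amplitude
to `1/g(566; 543, w)` (so 566 nm is isosbestic for the high
transition). These amplitudes were fixed from this principle when the
generator was designed; they are not tuned quantities. Widths default
to 30 nm — band positions are the only published shape information, so
the width is plumbing for synthetic data. One visible consequence: at
pH 10 about 6% of the 566 nm species remains, so the predicted
spectrum's argmax on a 1 nm grid can land at 544 nm rather than 543;
the pure-species limit peaks at exactly 543.

## The synthetic generator: what it emulates, what it does not

`gen_trajectory()` emulates the *output cadence and event structure* of
1000 ns production runs: default duration 1000 ns, interval 0.01 ns,
so 100,001 frames. The barrel is a stylized 11-slot cylinder (radius
1.2 nm, strands of Cα atoms, ~0.5–1.2 nm interstrand gaps) arranged so
the four configured gates are spatially real; it is *not* a protein,
and nothing downstream assumes it is — the analyses consume labelled
geometry only.

Planted events and their margins:

- **Water escapes** follow the gate direction: dwell at 0.3–1.0 nm
  (default 0.6) from the bridge atom, then a step to 2.2 nm at the
  planted exit time followed by a 0.1 nm/ns outward drift. The 0.2 nm
  step margin over the 2 nm cutoff is ≈14 per-frame noise sd at the
  default noise, so the persistence detector recovers the planted time
  to the frame and the planted gate with 100% success over seeded
  configurations (a tested invariant). The piecewise path makes the
  persistence rule's edge cases — brief excursions, late crossings —
  directly constructible.
- **Carbonyl flips** rotate the O1 atom 180° about the CA1–C1 axis,
  toggling at each planted time, which makes the dihedral series and
  the two-state RMSD segmentation recover the planted schedule.
- **Scripted H-bond counts** are realised geometrically: plant waters
  sit at 0.28 nm / ≈0° from a static chromophore acceptor when bonded
  and at 0.6 nm when not, so the *detector* is exercised rather than
  bypassed. The bonded-angle margin is the narrowest in the generator
  (≈30° at ≈4 sd of angular noise at the default 0.01 nm jitter), so
  scripted-count recovery tests run at 0.005 nm noise where the margin
  is ≈8 sd.
- **Gap breathing** displaces the A145 Cα sinusoidally along the
  A145–K198 axis and records the scripted distance series as truth.

Noise is isotropic Gaussian jitter added to **all** atoms, scripted
ones included — the detectors should cope with noise on the atoms they
measure, and the plant margins above are set so they do. Same seed ⇒
identical output; different seeds change the noise but never the
plants; the generator restores the caller's RNG stream.

What the generator does *not* emulate: force-field physics, water
re-entry kinetics, realistic H-bond networks, correlated strand
motions, or the specific dynamics of any real protein. Passing the
recovery tests therefore demonstrates that the *estimators* are
correct and deterministic on data whose truth is known — it does not
validate any claim about real trajectories, whose raw data are not
published.

## Numerical choices and degenerate inputs

- Histogram bins are left-closed right-open, anchored at 0; the mode
  is the centre of the most populated bin and ties break to the lower
  bin (determinism).
- The persistence window spans `floor(persistence/dt) + 1` frames,
  inclusive of the start frame.
- Frame-spacing uniformity is enforced within a relative tolerance of
  1e-6; non-uniform traces are errors because the persistence rule is
  defined on a uniform grid.
- Two-means on a series whose range is below 1e-12 of its magnitude is
  declared single-state.
- `fit_pka` starts from data-derived values (asymptotes from extremes,
  midpoint from the half-range crossing) and uses
  Levenberg–Marquardt; a flat curve is a "no transition" error, not a
  fit.
- Empty selections are errors at use sites; resolution itself is total
  and order-preserving.

## Problem sizes

The shipped tests run synthetic trajectories of 0.02–10 ns (3 to 1001
frames, ~110–180 atoms) for the per-module checks, one full-cadence
100,001-frame generation and one 100,001-frame residency trace for the
end-to-end checks, 20-configuration recovery sweeps, and 100-replicate
pKa noise studies — sizes chosen so the whole suite exercises every
code path at full event density in well under a minute of compute,
which is what the planted-truth design makes possible.

## Known limitations

- Atom matching between structures is by chain/residue-id/atom-name
  only; no sequence alignment, so comparisons across proteins with
  different numbering need pre-renumbered inputs.
- The exit classifier is a nearest-centroid rule, not a tunnel/pathway
  computation; waters taking grazing trajectories between two gates
  are assigned to the nearer centroid and flagged only via the logged
  margin.
- Water-bridge (two-step) hydrogen bonding, energy-based H-bond
  scoring and Markov-state analyses are out of scope.
- The crystal-structure RMSD check needs the two deposited PDB files,
  which the package cannot ship.
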