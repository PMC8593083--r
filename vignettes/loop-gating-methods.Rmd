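---
title: "Quantifying autoinhibitory-loop gating and its catalytic consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autoinhibitory-loop gating and its catalytic consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopgate)
library(dplyr)
```

## The system and the question

The catalytic SET domain of the histone methyltransferase NSD2 (construct
residues 973–1226) carries an autoinhibitory loop that, in the absence of a
histone H3 substrate, folds over the substrate-binding cleft: the side chains
of L1181, C1183 and L1184 occupy the hydrophobic patches that otherwise
accommodate H3V35 and H3P38. Recurrent oncogenic mutations — E1099K and
T1150A — hyperactivate the enzyme without improving nucleosome binding. The
mechanistic hypothesis this package operationalises is that those mutations
loosen the loop's "locks", letting the loop vacate the cleft ("open") more
often, and that the catalytic consequence is an increase in the apparent
turnover number rather than in substrate affinity.

`loopgate` implements the two measurement arms of that hypothesis:

1. **Trajectory arm** — from molecular-dynamics ensembles of the SET domain,
   classify each frame open/closed via four residue-pair distance locks,
   quantify occupancies, per-lock engagement frequencies and lock-state
   entropy, map residue-fluctuation cross-correlations, and condition loop
   state on the surrounding salt-bridge network.
2. **Kinetics arm** — from coupled luminescence assay plates, convert
   signal to product via an SAH standard curve, estimate initial rates by
   linear regression, and fit the Michaelis–Menten model to obtain
   apparent kcat and KM per enzyme variant.

Raw production trajectories for this system are not publicly deposited, so
the package ships ground-truth-labelled synthetic generators that emulate
the statistical structure each analysis assumes. Every stage is therefore
testable end to end without any download; what that does and does not
establish about real data is discussed at the end.

## The lock model

The four locks are minimum side-chain heavy-atom distances between loop and
patch residues:

| lock | residue pair   |
|------|----------------|
| D1   | L1184 – C1102  |
| D2   | C1183 – C1102  |
| D3   | C1183 – T1121  |
| D4   | L1181 – T1121  |

A lock is **engaged** when its distance is at or below the engagement
cutoff, and the loop is **open** in a frame if and only if all four locks
are simultaneously released. An optional fifth series (L1181–T1150) can be
tracked alongside but does not enter the open/closed call.

Two choices here are conventions rather than published parameters, and both
are exposed in the API and in pipeline configs:

* **Engagement cutoff, default 5.0 Å.** No distance criterion for a lock
  being "operational" is published; 5.0 Å on minimum side-chain heavy-atom
  distance is a standard hydrophobic-contact convention. Because published
  open-state percentages depend on this choice, `cutoff_sweep()` reports
  the open fraction over a 4.0–6.0 Å grid and reports should carry that
  sweep. The boundary is inclusive (distance = cutoff counts as engaged).
* **Atom scope, default side-chain heavy atoms.** The locks encode
  side-chain hydrophobic interactions, so backbone atoms are excluded by
  default; `atom_scope = "heavy"` is available.

Occupancies are pooled over the retained frames of all runs (runs have
equal frame counts under the default window), with per-run values retained
for spread. Lock-state entropy is the Shannon entropy of the 16-state joint
histogram, in bits, so the uniform maximum is exactly 4; zero-count states
contribute zero. Entropy in bits was chosen because no base is standard
here and it makes the maximum a round number.

The one structural invariant every output must satisfy is
P(open) ≤ min over locks of P(lock released): openness requires all locks
released, so on raw counts the open count can never exceed any single
lock's released count. `check_gating_invariant()` asserts this and the
pipeline applies it to every ensemble it analyses.

## Windowing and superposition

Production runs carry an equilibration transient; the analysis window
drops frames with time below `discard_initial_ns` (default 100 ns,
matching the convention of analysing the last 400 ns of 500-ns runs) and
then keeps every `stride`-th frame. PDB inputs carry no time axis, so frame
times are assigned uniformly (`dt_ns`, first frame at 0 ns).

Fluctuation analyses require removing rigid-body motion first.
`superpose()` least-squares fits every frame (Kabsch rotation plus
translation) onto the ensemble-mean structure of the fit atoms — by default
the Cα atoms of all residues, the field convention when no fit selection is
published. The mean reference is iterated to convergence starting from the
raw ensemble mean (falling back to the first frame only if that mean is
geometrically degenerate, e.g. collapsed or collinear). This design makes
superposition *exactly idempotent* — refitting an already-fitted ensemble
moves no atom by more than numerical noise — which would not hold for a
first-frame-anchored two-pass fit, and idempotence is the property
downstream code relies on. Rigid fitting preserves all intra-frame
distances, so lock and salt-bridge analyses are unaffected by whether an
ensemble was superposed.

## Cross-correlation of residue fluctuations

The dynamic cross-correlation map uses the isotropic scalar-product
definition

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}},$$

with \(\Delta r_i\) the displacement of residue *i*'s Cα from its mean
position. Whether multi-run maps should pool frames or average per-run
matrices is not standardised; `compute_dccm()` removes the mean **per run**
(so slow inter-run drift cannot masquerade as correlation) and pools the
scalar products across runs, while also retaining the per-run matrices so
both conventions can be reported. Residues with zero fluctuation have no
defined correlation; their rows are set to `NA` and reported, never
silently zeroed — in gated synthetic topologies the fixed anchor atoms
trigger exactly this path, deliberately.

For display, coefficients with \(|c| \le 0.3\) are conventionally shown as
zero; `threshold_dccm()` applies that band boundary-inclusively ("between
−0.3 and 0.3" is read as closed) and keeps the raw matrix alongside.
Region coupling summarises cross-blocks between R1 (1095–1130), R2
(1140–1150) and R3 (1177–1203, the post-SET loop): the mean coefficient and
the fractions of entries at or beyond ±threshold, with an "anti-correlated"
call when the negative fraction exceeds 10% (configurable). Contact maps
use minimum heavy-atom distance with a 4.5 Å cutoff, again a convention
exposed as a parameter.

## Salt-bridge conditioning

The charged cluster around the loop (D1098, E1099/K1099, D1123, K1124,
D1125, R1126, K1152, D1158, D1182) forms a bridge network; the key
observation is that the loop tends to open when the D1123–K1152 bridge is
broken. A bridge is present when any carboxylate oxygen (ASP OD1/OD2,
GLU OE1/OE2) sits within 4.0 Å of any charged nitrogen (LYS NZ,
ARG NE/NH1/NH2) — 4.0 Å being the common salt-bridge convention, again
config-exposed. Histidine is accepted only on explicit request because its
protonation is not modelled. `conditional_open_probability()` reports
P(open | present), P(open | broken) and the odds ratio
odds(open | broken) / odds(open | present), with the Haldane–Anscombe 0.5
correction when a 2×2 cell is empty, and a `estimable = FALSE` marker
(never a silent NaN) when a conditioning set is empty. The law of total
probability holds exactly on the counts and is asserted in the tests.

## Enzyme kinetics

The assay couples SAH production to luminescence. The analysis chain is:

1. `fit_standard_curve()` — OLS line signal = a·amount + b (≥3 points,
   positive slope enforced), inverted by `convert_signal()`.
2. `initial_rates()` — per replicate, the OLS slope of product versus time
   over the sampled timepoints (2/4/6/8 min in the reference design);
   replicate slopes are averaged with their SD. The intercept is free by
   default since a constant assay background cannot be excluded; a
   zero-intercept variant and a pooled-replicates variant are flags.
3. `fit_michaelis_menten()` — nonlinear least squares of
   \(v = V_{max} S / (K_M + S)\) (Levenberg–Marquardt), initialised at
   Vmax₀ = max rate and KM₀ = the substrate grid point nearest half-max;
   kcat = Vmax/[E]. A fitted KM outside the sampled substrate range by more
   than 10× raises an extrapolation warning — this fires, intentionally,
   when all rates are saturated and KM is unidentifiable.
4. `compare_conditions()` — mutant/reference fold changes for kcat, KM and
   kcat/KM with delta-method standard errors; the efficiency fold equals
   the kcat fold over the KM fold exactly on point estimates.

**A caveat the synthetic data makes measurable:** progress curves follow
the integrated rate law, so the secant/OLS slope over 2–8 min
underestimates the true instantaneous v(0) whenever substrate depletion is
appreciable within the window. At the reference plate design the lowest
substrate well reaches ~17% depletion, which biases noiseless kcat
estimates by roughly 1% and KM upward by roughly 10–15%; the generator
flags any dataset exceeding 20% depletion. Exact-recovery identities are
therefore checked in a light-load regime (enzyme diluted 200-fold, <0.1%
depletion) where the initial-rate assumption holds; fold-change recovery is
checked at the full reference design, where the bias largely cancels
between numerator and denominator.

## The synthetic generators

`simulate_gated_trajectory()` emits a minimal topology using real NSD2
residue numbers and side-chain atom names (C1102, T1121, L1181, C1183,
L1184, plus D1123/K1152 when a bridge is modelled) so that every analysis
default applies unchanged. Each lock lives in its own spatial zone and its
distance is realised exactly by one mobile pseudo-side-chain atom moving
along a fixed axis — geometric realism is explicitly a non-goal; label
fidelity is the goal. Lock distances are drawn from state-conditioned
Gaussians (engaged 3.8 ± 0.3 Å, released 9.0 ± 0.5 Å against the 5.0 Å
cutoff); construction refuses regimes separated by less than 4 SD, which
keeps label/classification agreement above 99.9%.

Two gating modes cover the two statistical structures the analyses meet:

* `lock_mode = "state"` — a hidden two-state Markov chain with per-frame
  transition probabilities; open frames release all locks, closed frames
  engage all. Stationary open probability \(\pi = p_{co}/(p_{co}+p_{oc})\)
  in closed form, and the autocorrelation-corrected standard error
  \(\sqrt{\pi(1-\pi)/n \cdot (1+\lambda)/(1-\lambda)}\) with
  \(\lambda = 1 - p_{co} - p_{oc}\) is what recovery tests use.
* `lock_mode = "independent"` — per-frame Bernoulli engagement per lock,
  for testing per-lock frequency estimation and the all-released
  coincidence structure of openness.

With an attached `bridge_model()`, frames are drawn independently (bridge
state first, then loop state from the stated conditionals), because the
purpose of that mode is exact-by-construction conditional probabilities;
temporal persistence is deliberately absent there.

`simulate_correlated_fluctuations()` draws one Cα per residue from a
multivariate Gaussian that is isotropic across x/y/z with a user correlation
matrix (PSD-checked at construction); mean positions lie on a gentle helix
so the superposition problem stays well-posed. No rigid-body drift is
injected, so the expected sample DCCM equals the generating matrix, and the
DCCM fidelity tests run on the generator output directly — rigid-body
refitting of strongly block-correlated motion absorbs part of the coherent
component (a real property of superposition, measurable here: a 0.8
within-block correlation drops to ~0.44 after fitting a 20-residue
two-block system), which is why superposition is a documented precondition
handled by the caller rather than something the DCCM recomputes.

`simulate_kinetics()` mirrors the reference plate design: twofold
nucleosome dilutions 31.25 nM–4 µM, timepoints 2/4/6/8 min, triplicates,
SAM in excess, an invertible linear standard curve, multiplicative Gaussian
noise (5% default). The default truth panel is a wild-type-like reference
plus three activated variants with kcat folds 16, 9 and 3 and equal KM
(KM differences among variants are small in this system). Absolute values
(reference kcat 0.05 min⁻¹, KM 600 nM, enzyme loads 256/16/32/64 nM) were
chosen once as plausible for a slow nucleosomal methyltransferase assayed
at these loads, with the constraint that every well stays below the 20%
depletion flag; they are inputs to the generator, not fitted quantities.

## Pipeline, determinism and problem sizes

`run_pipeline()` validates its config (unknown keys are rejected at every
level), materialises every threshold into the config so that nothing in a
report comes from a hidden default, caches each stage as JSON in the output
directory, skips completed stages unless forced, and writes a deterministic
`report.json` whose centrepiece is the per-condition table of open
percentage, per-lock engaged percentages and entropy. All generator
randomness flows through explicit integer seeds, so identical configs give
byte-identical reports.

Test and acceptance problem sizes are package choices balancing
Monte-Carlo error against convenience: 20,000 frames for occupancy and
conditional-probability recovery (3-SE bounds), 50,000 frames for DCCM
fidelity (±0.05 band) and per-lock frequencies (±0.01), 200 replicate
plates for estimator calibration (median relative error of kcat below 5%,
of KM below 15%).

## What passing tests do and do not show

The generators reproduce the *statistical contracts* the analyses assume:
two-regime lock distances with unambiguous labels, block-structured
Gaussian fluctuations without drift, Bernoulli bridge coupling, integrated
rate-law progress curves. They do not reproduce force-field physics,
solvent, correlated multi-lock kinetics, conformational intermediates at
the cutoff boundary, nucleosome geometry, or assay artefacts such as signal
drift and pipetting structure. Passing therefore certifies the estimators
and the pipeline plumbing — classification, occupancy, entropy,
correlation, conditioning and kinetic fitting are correct on data with
known truth — but says nothing about whether a particular cutoff choice
reproduces any published percentage on real trajectories. That is exactly
why the cutoff sweep exists, and why quantitative comparison with published
open-state numbers requires regenerating production-scale trajectories
(three 500-ns runs per condition) with the original simulation protocol:
at that scale the expectation is qualitative agreement — mutant open
fractions far above wild type, wild type holding the D4 lock most often —
not digit-level reproduction, since the published percentages themselves
depend on an unstated lock criterion.

## Known limitations

* Lock and bridge criteria are single-distance cutoffs; no angular
  (hydrogen-bond geometry) or water-mediated criteria.
* No kinetic modelling of open↔closed transitions (dwell times, MSMs) and
  no free-energy estimates; openness is a per-frame label.
* The kinetics module fits initial rates only; global progress-curve
  (integrated) fitting and substrate-depletion correction are out of scope,
  which is precisely why the depletion flag exists.
* Multi-chain topologies are supported only insofar as residue numbers stay
  unique per chain; the analyses here address a single-domain construct.
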