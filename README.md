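# loopgate

Analysis of autoinhibitory-loop gating in SET-domain methyltransferase
(NSD2) molecular-dynamics trajectories, and of the enzyme kinetics that the
gating hypothesis predicts.

## The problem

The NSD2 SET domain (residues 973–1226) dimethylates histone H3 Lys36 on
nucleosomes. In the substrate-free enzyme an autoinhibitory loop occupies
the substrate-binding cleft: L1181, C1183 and L1184 plug the hydrophobic
patches that otherwise bind H3V35 and H3P38. Oncogenic mutations (E1099K,
T1150A) hyperactivate NSD2 without improving nucleosome affinity. The
mechanistic question is whether those mutations loosen the loop — letting
it vacate the cleft more often — and whether the catalytic gain appears as
turnover (kcat^app) rather than affinity (KM^app).

`loopgate` is for computational structural biologists and enzymologists who
want to quantify that mechanism:

* **Lock gating** — four residue-pair distance locks (D1 L1184–C1102, D2
  C1183–C1102, D3 C1183–T1121, D4 L1181–T1121; minimum side-chain
  heavy-atom distance, engaged at ≤ 5.0 Å). A frame is **open** iff all
  four locks are released. Outputs: open percentage per condition, per-lock
  engaged frequencies, Shannon entropy of the 16 joint lock states
  (H = −Σ p_s log₂ p_s, max 4 bits), cutoff-sensitivity sweeps.
* **Fluctuation correlation** — the dynamic cross-correlation map
  C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩) on Cα displacements after
  Kabsch superposition, with the conventional |c| ≤ 0.3 display-zeroing
  rule and region-coupling summaries over R1 (1095–1130), R2 (1140–1150)
  and R3 (1177–1203); residue contact maps.
* **Salt-bridge conditioning** — occupancy of bridges in the charged
  cluster around the loop (notably D1123–K1152) and
  P(open | bridge present) vs P(open | bridge broken) with odds ratio.
* **Michaelis–Menten kinetics** — SAH standard curve, per-replicate
  initial-rate regression, nonlinear v = Vmax·S/(KM+S) fits,
  kcat = Vmax/[E], and mutant/wild-type fold changes with propagated
  errors.
* **Synthetic generators** — hidden-Markov gated lock trajectories,
  block-correlated Gaussian fluctuations and integrated-rate-law assay
  plates, all with ground-truth labels, so the whole pipeline is testable
  without any trajectory download.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()` on
fitted objects, `autoplot()` on every result type, and a `run_pipeline()`
orchestrator with cached stages and a deterministic JSON report.

## Worked example

Simulate a mutant-like gated trajectory (stationary open probability 0.10,
three runs), discard the equilibration window, and quantify gating:

```r
library(loopgate)

model <- gating_model(p_co = 0.0111, p_oc = 0.1)   # stationary open ~ 0.10
sim   <- simulate_gated_trajectory(model, n_frames = 20000, n_runs = 3,
                                   seed = 42)
traj  <- apply_window(sim$trajectory, discard_initial_ns = 100)
locks <- evaluate_locks(traj, condition = "E1099K-like")

open_fraction(locks)
#> # A tibble: 4 × 4
#>   scope  n_frames n_open open_fraction
#>   <chr>     <int>  <int>         <dbl>
#> 1 pooled    59700   6087        0.102
#> 2 run_1     19900   2072        0.104
#> 3 run_2     19900   1937        0.0973
#> 4 run_3     19900   2078        0.104

lock_state_entropy(locks)
#> <lock_entropy> H = 0.4763 bits (normalized 0.1191), condition E1099K-like
```

The pooled open fraction (10.2%) recovers the generator truth (10%) within
Monte-Carlo error, the per-run spread quantifies between-run variability,
and the low entropy says the four locks move as one two-state system here
(by construction of this generator mode). On the kinetics side:

```r
sim_k <- simulate_kinetics(seed = 11)              # 4-condition plate, 5% noise
sc    <- fit_standard_curve(sim_k$calibration)
rates <- initial_rates(sim_k$data, standard_curve = sc)
fits  <- fit_mm_panel(rates, setNames(sim_k$truth$enzyme_nM,
                                      sim_k$truth$condition))
compare_conditions(fits, "WT")[, c("condition", "kcat", "km", "kcat_fold")]
#> # A tibble: 4 × 4
#>   condition   kcat    km kcat_fold
#>   <chr>      <dbl> <dbl>     <dbl>
#> 1 E1099K    0.820   687.     16.4
#> 2 T1121A    0.158   710.      3.15
#> 3 T1150A    0.481   784.      9.61
#> 4 WT        0.0501  643.      1
```

The fitted turnover folds (16.4 / 9.6 / 3.2) recover the generator's
16 / 9 / 3 panel; `autoplot(fits[["E1099K"]])` draws the saturation curve.

## Documentation

The methods vignette (`vignettes/loop-gating-methods.Rmd`) documents the
lock model and its conventions (cutoffs, atom scopes, pooling), the DCCM
definition and thresholding, the salt-bridge conditioning, the kinetics
chain and its depletion caveat, what the synthetic generators do and do not
emulate, and the package's numerical design choices.
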