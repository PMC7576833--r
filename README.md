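# paratopeMSM

Kinetic characterization of antibody paratope states from
conformational-ensemble trajectories, in R.

The antigen-binding site of an antibody — the paratope, formed by the six
CDR loops — interconverts between several backbone conformations on the
micro-to-millisecond timescale. Which states exist, how probable they are,
how fast they exchange, and how they couple to the relative V<sub>H</sub>–V<sub>L</sub>
domain orientation and the Fab elbow angle are central questions for
antibody engineering. `paratopeMSM` implements the full analysis chain for
answering them from an ensemble of trajectory frames:

- **Featurization** — backbone φ/ψ torsions of the CDR residues mapped to
  (sin, cos) pairs; the ψ-only weighted combination is exposed as the
  enhanced-sampling collective variable.
- **tICA** — slow linear coordinates from the generalized eigenproblem
  *C<sub>τ</sub> v = λ C₀ v* (symmetrized, ridge-regularized).
- **Markov-state model** — k-means microstates (k-means++, deterministic
  under a seed), sliding-window counts, reversible maximum-likelihood
  transition matrix on the largest connected set, implied timescales
  *t<sub>i</sub> = −τ / ln λ<sub>i</sub>*, Chapman–Kolmogorov validation.
- **PCCA+** — metastable macrostates (fuzzy memberships, crisp labels,
  equilibrium probabilities, mean first-passage times).
- **Geometry** — the V<sub>H</sub>–V<sub>L</sub> interface angle as a signed torsion
  over four centers of mass (light-chain CDRs, V<sub>L</sub>, V<sub>H</sub>,
  heavy-chain CDRs) and the elbow angle as the analogous torsion over the
  variable COM, the two switch-region COMs, and the constant COM; Kabsch
  superposition and region RMSD.
- **Conformational clustering** — average-linkage clustering with a
  distance cutoff (1.2 Å default), canonical-cluster assignment against
  user-supplied median torsions, per-macrostate angle distributions, and
  CDR loop co-occurrence matrices with Cramér's V.
- **Synthetic ground truth** — hidden-Markov torsion generators, rigid-body
  mock antibodies with exactly prescribed angle series, and a double-well
  sampler with analytic barrier, so every stage has a parameter-recovery
  test without MD data.

## Worked example

```r
library(paratopeMSM)

spec <- default_hmm_fixture(n_frames = 50000, seed = 42)  # 4 hidden states
sim  <- simulate_hmm_torsions(spec)

coupled <- names(which(vapply(spec$loops, function(l) isTRUE(l$coupled),
                              logical(1))))
feats <- do.call(cbind, lapply(sim$torsions[coupled], sincos_features))
tm    <- fit_tica(feats, lag = 10)
Y     <- project_tica(tm, feats, n_components = tica_dimension(tm))
micro <- kmeans_microstates(Y, k = 150, seed = 7)
msm   <- estimate_msm(count_matrix(micro$dtrajs, 5), lag = 5)
macro <- pcca_plus(msm, 4)

sort(macro$probabilities)
#> [1] 0.2069 0.2275 0.2680 0.2977     # hidden truth: 0.217 0.225 0.255 0.303
implied_timescales(msm, n = 1)$frames
#> [1] 87.2                            # hidden truth: 102.4 frames
```

The four macrostate probabilities land within a few hundredths of the
hidden chain's stationary distribution and the slowest implied timescale
within ~15 % — with `ck_test()` confirming Markovianity at lag multiples
1–5 (max deviation < 0.01). Geometry is exact by construction:

```r
sim2 <- simulate_rigid_antibody(
  rigid_antibody_spec(seq(-150, 150, length.out = 200),
                      elbow_series = seq(110, 170, length.out = 200)))
max(abs(interface_angle(sim2$traj, sim2$regions) - seq(-150, 150, length.out = 200)))
#> [1] 4.3e-14
```

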