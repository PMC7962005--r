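# trpmicro

Tryptophan is the workhorse intrinsic fluorophore of proteins, but in a
multi-tryptophan enzyme its emission is a blend of residues sitting in
very different microenvironments.  `trpmicro` is an R toolkit for
pulling that blend apart and connecting each spectral component to the
structural and electrostatic surroundings of individual tryptophans.
It was built around the analysis of mouse thymidylate synthase (mTS, a
homodimer with five tryptophans per subunit) and its active-site
mutants, but every step is generic.

The package combines four layers:

1. **Steady-state spectra** — blank subtraction, the inner-filter
   factor `G = 10^((ΔA_ex + ΔA_em)/2)`, unit-maximum normalisation
   `I_norm(λ) = I(λ)/I_max`, difference spectra, and band/shoulder
   location from smoothed derivatives.
2. **Multi-dimensional fluorescence** — total synchronous fluorescence
   (TSFS) cubes `(sample × λ_exc × Δλ)` re-laid onto a trilinear
   excitation–emission grid (`λ_em = λ_exc + Δλ`, the "t-EEM" layout)
   and decomposed by PARAFAC,
   `X[s,e,m] ≈ Σ_k A[s,k] B[e,k] C[m,k]`, fitted by weighted
   alternating least squares (missing wedge cells carry zero weight)
   with nonnegativity and the CONCORDIA core-consistency diagnostic for
   choosing the number of components.
3. **Time-resolved decays** — multi-channel TCSPC histograms fitted
   with 1–3 exponentials reconvolved with the IRF, Neyman-weighted
   (`1/max(counts,1)`), with model selection by reduced χ², intensity
   fractions `a_n = α_n τ_n / Σ α_m τ_m` and the intensity-weighted
   mean lifetime `τ_av = Σ (a_n/100) τ_n`.
4. **Per-tryptophan descriptors** — indole ring geometry (benzene and
   pyrrole centroids, the benzene→pyrrole long axis), the packing
   density Den2 (heavy atoms within 7.5 Å of the ring), a GETAREA-style
   solvent accessibility Acc (rolling-probe ratio divided by 1.5),
   spectral (Burstein-style) classes, and the electrostatic descriptor
   `Δ = φ(pyrrole) − φ(benzene)` read from an OpenDX potential grid.
   A screened-Coulomb (Debye–Hückel) generator provides desk-scale
   synthetic grids; real APBS `.dx` files are first-class inputs.

A synthetic-data module generates every input the pipeline consumes —
fluorophore banks, TSFS cubes, Poisson-sampled decay histograms, toy
structures with geometrically correct indole rings, potential grids —
with known ground truth and explicit seeds, so the whole chain is
testable end to end.  The photophysical link between descriptors and
lifetimes is the electron-transfer distance law
`k_ET = k_0 exp(−β(R − R_0))` with `1/τ = k_r + k_nr`.

## Worked example

Recomputing a published-style table row — two decay components of
1.32 ns and 5.5 ns carrying 86 % and 14.5 % of the intensity:

```r
library(trpmicro)
weighted_lifetimes(c(1.32, 5.5), fractions = c(86, 14.5))
#> $fractions
#> [1] 86.0 14.5
#> $tau_av
#> [1] 1.9327
```

i.e. τ_av ≈ 1.93 ns, the blue-channel mean lifetime of mTS.  Class
labels from the calibrated thresholds:

```r
burstein_class(12.1, "acc")   # "II"  (moderately exposed)
burstein_class(121, "den2")   # "I/II" (intermediate packing)
```

An end-to-end synthetic run (20-sample TSFS cube with components at
330/362 nm, three TCSPC channels at 20k peak counts, a two-tryptophan
toy structure):

```r
cfg <- run_config(seed = 42,
  params = list(mdf = list(n_samples = 20, K = 2, noise_sd = 1, n_starts = 2),
                tcspc = list(n_channels = 3, peak_counts = 20000, n_starts = 3),
                descriptors = list(n_trp = 2, n_decoys = 100)))
rep <- run_pipeline(cfg)

rep$mdf$summary
#>   component exc_max_nm em_max_nm score_share
#> 1         1        282       330   0.4882716
#> 2         2        284       362   0.5117284

rep$tcspc$table[, c("channel", "tau_av", "tau_1", "tau_2", "chi2_red")]
#>   channel   tau_av    tau_1    tau_2 chi2_red
#> 1       1 1.722127 1.309260 5.196787 1.068453
#> 2       2 2.775133 1.316725 5.449328 1.056393
#> 3       3 3.820395 1.315299 5.471104 1.076106

rep$descriptors$table[, c("trp_id", "acc", "den2", "delta", "acc_class")]
#>   trp_id      acc den2     delta acc_class
#> 1    A:1 40.85434   15 1.1875988       III
#> 2    A:2 31.15764   16 0.2558857       III
```

The PARAFAC layer recovers the generator's emission maxima exactly
on-grid (330/362 nm) with nearly coincident excitation maxima
(282/284 nm); the decay fits land within a few percent of the true
lifetimes with reduced χ² near 1; the toy tryptophans are solvent
exposed (class III) as expected for isolated indole rings.
`write_report(rep, "out/")` emits a per-tryptophan table that prints
the ring potentials as `benzene -> pyrrole` with a signed Δ, plus a
per-channel lifetime table and a JSON manifest of all seeds.

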