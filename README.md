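# idmc: informed dictionary-guided Monte Carlo inversion for multidimensional diffusion-relaxation MRI

`idmc` estimates voxel-wise joint distributions of frequency-dependent
diffusion tensors and relaxation rates from sparse multidimensional
diffusion-relaxation MRI. It is written for MRI methods researchers who
work with tensor-valued ("b-tensor") diffusion encoding combined with
R1/R2 relaxation weighting, and who need distribution estimates that are
stable across repeated scans and cheap enough for whole-brain use.

## The model and the inversions

A voxel signal is a nonnegative mixture over diffusion-relaxation
components, `s = K w`, with kernel entries

    k(m, n) = exp(-B_m : D_n(w_cent,m)) * (1 - exp(-TR_m R1_n)) * exp(-TE_m R2_n)

Each component carries an axisymmetric frequency-dependent diffusion tensor
whose axial/radial eigenvalues follow a Lorentzian dispersion

    lambda_i(w) = D_i + (D0 - D_i) * w^2 / (w^2 + Gamma_i^2),  i in {par, perp}

from the zero-frequency diffusivities to a high-frequency isotropic plateau
`D0`, plus longitudinal and transverse relaxation rates R1 and R2. The
inverse problem (recovering the weighted component set from ~139
measurements) is ill-posed; three bootstrap-based inversions are provided:

* **MC** — per-bootstrap stochastic *proliferation* (random candidate
  components, NNLS weighting, pruning) followed by *mutation* (local
  Gaussian refinement). The classical Monte Carlo inversion baseline.
* **DM** — pure dictionary matching: each bootstrap signal is matched by
  cosine similarity to a precomputed dictionary of (signal, kernel set,
  parameter set) entries built from training data, then NNLS-projected onto
  the matched kernels.
* **ID-MC** — dictionary matching plus a small number of mutation rounds
  (default 1) over the matched parameter set. Its per-bootstrap fit
  residual can never exceed DM's, by construction of the expanded kernel
  set, and it needs a fraction of MC's kernel evaluations (201 vs 800
  candidate proposals per bootstrap at the defaults).

Bootstrap solutions aggregate to per-voxel distributions, projected onto
scalar maps: E/V/C statistics of `Diso(w)` and `Ddelta^2(w)` and of R1/R2,
white-matter / gray-matter / CSF bin fractions in the `Diso`-`Ddelta^2`
plane, and finite-difference frequency dependence rates over 6.6-21 Hz.
A synthetic evaluation harness (four-component ground-truth phantom, Rician
noise, bias-controlled training dictionaries, exact Earth Mover's Distance
scoring, ICC/CVws reliability statistics) reproduces the in-silico study
design at desk scale.

## Worked example

Noise-free recovery of the ground-truth phantom with the MC baseline:

```r
library(idmc)

ph   <- default_phantom()                      # soma + crossing fibers + CSF
p    <- make_protocol(139, seed = 1)           # synthetic 139-measurement protocol
s    <- synthesize_signal(p, ph$components, ph$weights)
plan <- draw_bootstrap_plan(139, nb = 20, seed = 1)

sols <- mc_invert_voxel(s, p, plan, mc_config(nb = 20, seed = 1))
dist <- aggregate_solutions(sols)

assign_bins(dist)[c("fbin1", "fbin2", "fbin3")]
#> $fbin1
#> [1] 0.521273
#> $fbin2
#> [1] 0.3719528
#> $fbin3
#> [1] 0.1067742
```

The bin fractions estimate the white-matter-like / gray-matter-like /
CSF-like signal fractions; the phantom's true values are 0.50 / 0.35 / 0.15,
so the noise-free MC ensemble lands within a few percent of each. The same
signal inverted through a dictionary (`build_dictionary()`,
`idmc_invert_voxel()`) gives the ID-MC estimate; `run_simulation_study()`
compares all three methods across SNR and dictionary-bias levels and scores
each voxel by EMD against the ground truth:

```r
res <- run_simulation_study(sim_config(snr_list = c(130, 30),
                                       sigma_bias_list = 0.2, seed = 1))
res[, c("method", "snr", "median_emd", "mean_similarity")]
#>   method snr median_emd mean_similarity
#> 1     mc 130  0.7038962       0.9992633
#> 2     dm 130  0.6648176       0.9982587
#> 3   idmc 130  0.6605169       0.9989458
#> 4     mc  30  0.8262864       0.9889947
#> 5     dm  30  0.7976033       0.9844248
#> 6   idmc  30  0.7985666       0.9871741
```

Lower median EMD means distributions closer to the truth: dictionary
guidance (ID-MC) beats the MC baseline at both noise levels, adding one
mutation round recovers the fit quality DM loses to training-set bias, and
every method degrades as SNR falls.

A thin command-line wrapper over these functions lives at
`inst/cli/idmc-tool.R` (subcommands `make-protocol`, `simulate`,
`build-dict`, `invert`, `study`).

## Package layout

* `R/signal_model.R`, `R/components.R`, `R/protocol.R` — forward model
* `R/nnls.R`, `src/nnls.cpp` — nonnegative least squares
* `R/mc.R`, `R/dictionary.R`, `R/idmc.R` — the three inversions
* `R/descriptors.R` — distributions, scalar summaries, maps
* `R/emd.R`, `src/emd.cpp` — exact optimal transport scoring
* `R/simulation.R`, `R/study.R` — synthetic data and the study driver
* `R/io.R` — NIfTI/CSV/JSON I/O and provenance
* `vignettes/idmc-methods.Rmd` — models, assumptions, design choices
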