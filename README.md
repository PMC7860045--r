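# burstloop

Transcription in mammalian cells happens in bursts: mRNAs are produced in
clustered episodes separated by silent periods, so isogenic cells carry
wildly different copy numbers of the same transcript. One under-explored
contributor to this noise is 3′–5′ crosstalk — the recycling of RNA
polymerase II from a gene's terminator back to its promoter (a "gene
loop"), plausibly through a phase-separated PolII compartment. `burstloop`
provides the full computational toolkit for studying that question, aimed
at systems biologists working with flow-FISH readouts of inducible
transgenes, PolII ChIA-PET contact matrices, and single-cell UMI counts.

## What the package implements

**Stationary models.** The telegraph model (switch rates
k<sub>on</sub>/k<sub>off</sub>, transcription rate α, all in units of the
mRNA degradation rate d̃) with its Poisson-beta stationary law

> X | P ~ Poi(αP),  P ~ Beta(k<sub>on</sub>, k<sub>off</sub>),
> μ<sub>X</sub> = α k<sub>on</sub>/(k<sub>on</sub>+k<sub>off</sub>)

its bursting limit — the negative binomial with burst size b = α/k<sub>off</sub>
and noise CV²<sub>X</sub> = 1/μ<sub>X</sub> + 1/k<sub>on</sub> — and the
Poisson model of unregulated expression. Exact pmfs (Gauss–Jacobi
quadrature), moments, and samplers.

**Bayesian inference from flow-FISH.** The measurement equation
Y = ε + κX with a skew-normal background ε fitted on control cells, a
gamma-GLM calibration prior on the scale κ, and an adaptive
Metropolis–Hastings sampler (Haario-type covariance adaptation, frozen
after burn-in) that marginalises the latent counts. Posterior medians with
90% HPD intervals, consensus fits across replicates (shared kinetics,
replicate-specific κ), WAIC model comparison, cell-cycle/size gating, and
the law-of-total-variance extrinsic/intrinsic noise decomposition.

**Microscopic recycling simulator.** Exact SSA of a PolII-compartment model
(influx γ, removal δ, transcription β per PolII with re-injection
probability *l*, repressor blocking at rate nK<sub>λ</sub>, mRNA decay d),
its no-accumulation variant, closed first-moment ODEs as an analytic
oracle, and noise scans over repressor concentration, recycling probability
and degradation rate.

**Genome-wide arm.** TSS–TES interaction scores from binned contact
matrices (length-normalised against 10⁴ random same-length intervals,
arcsinh√(x+0.5) transform), per-gene negative-binomial noise estimates from
raw UMI counts, the influenza-infection cell split (≥ 0.02% flu UMIs), the
ν distance from the reference curve CV² = 1/μ + 1/k̄<sub>on</sub>, the
low/intermediate/high noise classification (ν₁ = 4.5), and
Mann–Whitney/regression association tests.

**Synthetic data.** Deterministic generators for every input above with
known ground truth — the basis of the whole test suite.

## Worked example

Generate a synthetic flow-FISH experiment (truth: μ<sub>X</sub> = 50,
k<sub>on</sub> = 2, burst size 25, κ = 2, skew-normal background), estimate
the background and calibration priors, and fit the negative-binomial model:

```r
library(burstloop)
spec <- synth_spec(seed = 11)
ff  <- synth_flowfish(spec)
bg  <- fit_background(synth_control(spec)$values)
cal <- calibrate_kappa_prior(synth_calibration(spec))
pr  <- default_priors("negative_binomial", calib = cal, background = bg)
fit <- adaptive_mh(ff$replicates[[1]], "negative_binomial", priors = pr,
                   n_iter = 4000, seed = 5)
posterior_summary(fit)
#>    parameter median hpd_lo hpd_hi rhat
#> 1       mu_X 50.263 48.479 51.786 1.06
#> 2       k_on  1.971  1.901  2.043 1.00
#> 3      kappa  1.976  1.921  2.035 1.03
#> 4 burst_size 25.525 24.039 26.808   NA
#> 5      CV2_X  0.527  0.511  0.547   NA
```

Every planted parameter is recovered within a few percent and sits inside
its 90% HPD interval: the mean expression (50.3 vs 50), burst frequency
(1.97 vs 2), fluorescence scale (1.98 vs 2) and burst size (25.5 vs 25).
`CV2_X` is the derived transcriptional noise, here ≈ 0.53 — far above the
Poisson expectation 1/μ = 0.02, the signature of bursting.

The microscopic simulator at the reference parameter set
(γ, β, d, δ, K<sub>λ</sub>) = (10, 10, 0.01, 1, 0.01), with strong
recycling:

```r
p  <- micro_params(gamma = 10, beta = 10, delta = 1, d = 0.01,
                   K_lambda = 0.01, n = 1, l = 0.95)
en <- stationary_ensemble(p, n_cells = 300, seed = 1)
#> mean = 3440.4  CV2 = 0.313
```

a noise level orders of magnitude above Poisson (1/3440 ≈ 3·10⁻⁴) from a
purely intrinsic mechanism — the noise-floor behaviour the recycling model
is built to explain.

## Command line

`inst/cli/burstloop.R` exposes the pipeline as subcommands:

```sh
Rscript inst/cli/burstloop.R simulate --gamma 10 --beta 10 --delta 1 \
    --d 0.01 --K-lambda 0.01 --n 1 --l 0.95 --cells 500 --seed 1 --out sim.csv
Rscript inst/cli/burstloop.R fit --model nb --cells cells.csv \
    --control control.csv --calib calib.csv --iters 4000 --seed 1 --out post.csv
```

`run_pipeline()` (subcommand `run`) drives synth → fit → simulate → score →
classify end to end from a YAML/JSON config with per-stage checksum
skipping.

## Documentation

The methods vignette (`vignettes/burstloop-methods.Rmd`) describes the
models, priors, numerical choices (quadrature, truncation, histogram
compression of the likelihood, burn-in policy), what the synthetic world
does and does not emulate, and known limitations.
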