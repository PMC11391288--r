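# msfweb

Linear stability analysis of food-web metacommunities: when does
dispersal that responds to *other* species' densities (cross-diffusion)
turn a locally stable community into a self-organized spatial pattern —
and when do adaptive behaviours (prey tracking, predator avoidance)
suppress that transition?

The package is aimed at theoretical ecologists studying metacommunity
dynamics on patch networks, and more generally at anyone analysing
reaction–diffusion systems on graphs through master stability
functions.

## The method

Local food-web dynamics on patch `k` couple to dispersal through the
graph Laplacian `L` of the patch network:

    dx_i^k/dt = f_i(x^k) − Σ_l L_kl D_i(x^l)

Linearizing about a homogeneous coexistence state `x*` and decomposing
perturbations over Laplacian eigenmodes reduces the problem to the
mode Jacobian

    J(κ) = P − κ C,     P_ij = ∂f_i/∂x_j |x*,   C_ij = ∂D_i/∂x_j |x*,

with `κ ≥ 0` the Laplacian eigenvalue (a discrete wavenumber). The
master stability function `λ(κ) = max Re eig J(κ)` classifies each
`(P, C)` pair:

* `λ(0) > 0` — **unstable** (fails even on an isolated patch);
* `λ(0) < 0` but `λ(κ) > 0` somewhere — **pattern-forming**
  (Turing-type instability via cross-diffusion);
* `λ(κ) < 0` everywhere — **stable** on any network.

Monte-Carlo scans over local (trophic) and spatial (dispersal)
parameters estimate the *robustness* `ω` of each outcome — the fraction
of parameter space producing it — locally (`ω(P)`), spatially (`ω(C)`)
and in total (`ω(P,C)`), as the number of active cross-diffusion terms
`n_cross` grows, with and without the adaptive sign constraint
`sgn C_ij = −sgn P_ij`. Local communities are either the four classic
three-species motifs (food chain, apparent competition, resource
competition, intraguild predation) with type-II functional responses,
or niche-model random food webs with folded-normal interaction
strengths for species-rich systems.

## Worked example

```r
library(msfweb)

# a feasible intraguild-predation community and its local Jacobian
sys <- sample_feasible_systems("intraguild_predation", 1, seed = 7)
P <- sys$systems[[1]]$P

# unconstrained cross-diffusion on all six permitted positions
pos <- cross_positions("intraguild_predation")$positions
set.seed(7)
Cm <- sample_connectivity(motif_sign_pattern("intraguild_predation"), pos)
classify(P, Cm)
#> dynamical class: pattern_forming

# robustness of each outcome at increasing cross-diffusion prevalence
sc <- scan_motif("intraguild_predation", constrained = FALSE,
                 n_P = 100, n_C = 100, seed = 7)
round(sc[, c("n_cross", "omega_st", "omega_us", "omega_pf")], 3)
#>   n_cross omega_st omega_us omega_pf
#> 1       0    0.940     0.06    0.000
#> 2       1    0.874     0.06    0.066
#> 3       2    0.772     0.06    0.168
#> 4       3    0.651     0.06    0.289
#> 5       4    0.542     0.06    0.398
#> 6       5    0.494     0.06    0.446
#> 7       6    0.469     0.06    0.471
```

Reading: with no interspecific dispersal responses (`n_cross = 0`)
pattern formation is essentially impossible (`omega_pf ≈ 0`); as
responses accumulate, the pattern-forming fraction rises monotonically
until it is the most robust outcome, while the locally-unstable
fraction (a property of `P` alone) stays fixed. Re-running with
`constrained = TRUE` collapses `omega_pf` by an order of magnitude —
the homogenizing effect of adaptive dispersal.

The same question for species-rich webs:

```r
scan_Nq(N_values = 30, q_values = 1, reps = 200, constrained = FALSE,
        seed = 5)
#>    N q constrained reps_kept reps_total omega_pf   seed
#> 1 30 1       FALSE       198        200        1 249276
```

i.e. at web size `N = 30` with a dispersal response on every trophic
link, every locally stable random web is susceptible to pattern
formation; under constraints the fraction drops but grows back with
`N`.

The patch-network layer verifies the eigenmode decomposition the whole
analysis rests on:

```r
two_patches <- patch_laplacian(rbind(c(0, 1), c(1, 0)))
network_growth_rate(-diag(2), matrix(c(1, 2, 2, 1), 2), two_patches)
#> [1] 1
```

which equals `λ(κ = 2) = −1 + 2` computed mode-wise.

Command-line wrappers around the two scans live in `inst/scripts/`
(`scan-motif.R`, `scan-nq.R`); both write deterministic CSVs given
`--seed`.

## Package layout

* `R/motifs.R`, `R/equilibrium.R` — motif definitions, type-II
  dynamics, analytic Jacobians, multi-start Newton equilibrium search,
  feasibility-conditioned sampling.
* `R/dispersal.R` — cross-position enumeration, connectivity sampling,
  adaptive sign constraint.
* `R/stability.R`, `R/classify-grid.R` — master stability function,
  three-way classification, exact Routh–Hurwitz pairwise classifier
  for the Monte-Carlo grids.
* `R/robustness.R` — robustness grids, distributions, moments, motif
  scans.
* `R/random-webs.R` — niche model, random Jacobian/connectivity pairs,
  `(N, q)` scans.
* `R/network.R` — Laplacians, block-system growth rates, linear
  pattern demonstrations.
* `vignettes/metacommunity-pattern-robustness.Rmd` — model,
  assumptions, numerical choices, limitations.
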