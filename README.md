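# hoxmir

Simulation of Hox–microRNA network dynamics and boundary formation in the
developing spinal cord.

## The problem

Limb-innervating motor neurons in the vertebrate spinal cord segregate into
mutually exclusive rostral (Hoxa5-positive) and caudal (Hoxc8-positive)
identities. The opposing retinoic acid (RA) and FGF gradients that induce
*Hox* transcription fluctuate, and *Hox* mRNAs are expressed noisily in
progenitors — yet the protein boundary is sharp, and impairing microRNA
biogenesis (Dicer loss) makes Hoxa5 protein precocious, noisy and caudally
expanded. `hoxmir` models this system to ask how a microRNA ("mir-x")
wired into coherent feed-forward loops can filter transcription noise,
delay protein accumulation, and confer a robust boundary.

The package is aimed at systems-biology users who want to simulate small
gene-regulatory networks under noisy morphogen inputs, quantify boundary
robustness, and screen network topologies.

## The model

Each of 100 cells along the rostrocaudal axis carries five species
(*Hoxa5* mRNA/protein, *Hoxc8* mRNA/protein, mir-x) obeying
sigmoidal-relaxation ODEs

    dX_i/dt = γ_i (F(u_i) − X_i),
    u_i = b_i + Σ_j ω_{j→i} X_j + ω_{RA→i} RA + ω_{FGF→i} FGF,
    F(u) = 1 / (1 + exp(−σ u)),

driven by steady-state exponential RA/FGF gradients,
M(x) = M⁰ exp(−x√(k/D)), perturbed by multiplicative noise factors drawn
uniformly from (1−η, 1+η) once per 1/ω interval (ω = 10/day, η = 0.3) and
independently per cell. Boundary quality is scored as
Ω_a5 + Ω_c8 + |Δ_{a5−c8}|: the widths of the two transition zones (where
the fraction of replicates expressing the protein at >0.5 units lies
strictly between 15% and 85%) plus the distance between the two boundary
midpoints. The six candidate mir-x interactions (four signed inputs, two
inhibitory outputs onto translation) define 3⁴ × 2² = 324 topologies that
`run_screen()` ranks by this score under noise; the top 2% share three
consensus interactions — RA ⊣ mir-x, mir-x ⊣ Hoxa5 protein,
Hoxc8 → mir-x — forming two coherent feed-forward loops.

## Worked example

```r
library(hoxmir)

wt  <- hox_consensus_network()          # calibrated basal net + consensus mir-x edges
res <- run_development(wt, tissue_config(n_replicates = 10), seed = 1)
boundary_report(res)
#> # A tibble: 1 × 7
#>   omega_a5 omega_c8 boundary_a5 boundary_c8   delta  score  time
#>      <dbl>    <dbl>       <dbl>       <dbl>   <dbl>  <dbl> <dbl>
#> 1   0.0202   0.0404       0.369       0.379 -0.0101 0.0707     5
```

Two cells' worth of transition zone for Hoxa5, boundaries one cell apart:
a sharp, accurate boundary. Knock out miRNA biogenesis and rerun under the
identical noise seeds:

```r
dicer <- apply_mutant(wt, "dicer_null")
boundary_report(run_development(dicer, tissue_config(n_replicates = 10), seed = 1))
#> # A tibble: 1 × 7
#>   omega_a5 omega_c8 boundary_a5 boundary_c8 delta score  time
#>      <dbl>    <dbl>       <dbl>       <dbl> <dbl> <dbl> <dbl>
#> 1   0.0909   0.0404       0.677       0.379 0.298 0.429     5
```

The Hoxa5 transition zone widens 4.5-fold and the Hoxa5 boundary invades
the Hoxc8 domain (Δ ≈ 0.30 of the axis) — the precocious, ragged, caudally
expanded mutant phenotype. The feed-forward delay is visible in the
RA-step protocol:

```r
quiet <- noise_params(amplitude = 0)
half_max_time(run_differentiation(wt, 2, ra_level = 1, noise = quiet,
                                  duration = 6, seed = 1))
#> [1] 1.169315
half_max_time(run_differentiation(apply_mutant(wt, "mirx_null"), 2,
                                  ra_level = 1, noise = quiet,
                                  duration = 6, seed = 1))
#> [1] 0.3372808
```

Wild-type Hoxa5 protein reaches half-maximum after ~1.2 days versus ~0.34
days without mir-x: the indirect RA ⊣ mir-x ⊣ Hoxa5 arm delays activation.

Other entry points: `run_screen()` / `consensus_interactions()` /
`strength_sweep()` for the topology screen, `expression_histogram()` and
`coefficient_of_variation()` for population statistics,
`autoplot()` / `plot_occupancy()` for figures, and `run_experiment()` for
YAML-configured, file-producing experiment recipes. See the vignette
`vignettes/hox-mirna-boundary-model.Rmd` for the model, calibration and
numerical details.

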