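# auxinpattern

Simulation of self-organized auxin patterning on cell networks, and of how
a dorsoventral gene-expression boundary restricts it.

## The problem

Leaves and flowers initiate where the hormone auxin accumulates at the
shoot apical meristem (SAM). Auxin maxima self-organize: the efflux carrier
PIN1 polarizes toward neighboring cells with high auxin, so transport feeds
accumulation ("up-the-gradient" feedback) and periodic maxima emerge
spontaneously. Meristems, however, do not initiate organs everywhere — in
particular, organs arise near the boundary between the central/dorsal
(REVOLUTA-expressing) and peripheral/ventral (KANADI-expressing) tissue
identities. `auxinpattern` is for researchers in plant developmental and
computational biology who want to simulate this mechanism: it implements
the transport-feedback model on polygonal cell networks and adds a radial
KAN/REV prepattern that represses the PIN1-polarizing signal, testing in
silico whether such a prepattern is sufficient to confine organ-initiation
sites to the low-expression boundary annulus.

## The model

Per cell \(i\) (volume \(V_i\), wall contact areas \(a_{ij}\)):

    dA_i/dt      = c_A − d_A A_i + (1/V_i)[ D Σ_j a_ij (A_j − A_i)
                                          + T Σ_j a_ij (P_ji A_j − P_ij A_i) ]
    dP_i^tot/dt  = c_P − d_P P_i^tot
    dX_i/dt      = V_X · Hill⁺(A_i) · Hill⁻(R_i) · Hill⁻(K_i) − d_X X_i

with membrane PIN1 given by the quasi-equilibrium allocation

    P_ij = P_i^tot (1 − k_p + k_p X_j) / (f_p + Σ_k (1 − k_p + k_p X_k)).

The KAN/REV prepattern follows Hill kinetics in the radial coordinate (run
to equilibrium in closed form; half-max radii 30 and 25, steepness 20, KAN
binarized at 0.5) and enters only through the two repressive Hill factors
on X. With KAN = REV = 0 the model reduces exactly to the classic
unrepressed polarization model. See the vignette
(`vignettes/boundary-restricted-patterning.Rmd`) for assumptions,
parameter meanings and numerical choices.

## Worked example

Spontaneous patterning on a 100-cell ring (1% seeded production noise to
break the perfect symmetry):

```r
library(auxinpattern)
ring  <- generate_ring_tissue(100)
traj  <- simulate_tissue(ring, model_params(), t_end = 1500,
                         noise_sd = 0.01, noise_seed = 1)
traj
#> tissue_trajectory: 100 cells, 101 samples on [0, 1500]
#>   final A range [0.2353, 2.472]; solver: rk45ck, 6726 steps
peaks <- detect_peaks(final_state(traj), ring)
peaks
#> peak_set: 17 peaks (threshold 1.236)
#>   cells: 4, 10, 16, 21, 26, 32, 39, 44, 49, 55, 62, 70, 77, 82, 87, 94, 100
peak_to_trough(final_state(traj))   # 10.51
peak_spacing(peaks, ring)$gap_cv    # 0.179
```

Auxin settles into 17 regularly spaced maxima (roughly one per six cells;
gap coefficient of variation 0.18) with a ten-fold peak-to-trough
contrast — spontaneous periodic patterning from zero initial conditions.

The headline paired experiment on a 400-cell disc — same template and
parameters, KAN/REV prepattern off versus on:

```r
res <- figure9_experiment(n_cells = 400, radius = 60, seed = 1)
str(res$report)
#> n_peaks_off         : 27        n_peaks_on          : 8
#> peak_to_trough_off  : 8.67      boundary_score_on   : 1
#> peak_radius_iqr_off : 19.9      peak_radius_iqr_on  : 0.74
```

Without the prepattern, 27 maxima spread over the disc (radial IQR ~20
length units). With KAN and REV repressing the polarizing signal, every
remaining maximum (boundary score 1.0) sits in the one-cell-wide annulus
between the REV and KAN domains and the radial spread collapses to under
one cell diameter.

A thin command-line interface wraps the same functions
(`exec/auxinpattern`, subcommands `template`, `prepattern`, `run`,
`analyze`, `figure9`).

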