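---
title: "Boundary-restricted auxin patterning on cell networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-restricted auxin patterning on cell networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 6)
```

## The model

Organ initiation at the plant shoot apical meristem is positioned by local
maxima of the hormone auxin, and those maxima self-organize: the efflux
carrier PIN1 is polarized toward neighboring cells with high auxin, so
auxin accumulation is self-reinforcing ("up-the-gradient" transport
feedback). `auxinpattern` implements this feedback on a static network of
polygonal cells and adds a dorsoventral gene-expression prepattern — a
peripheral KANADI (KAN) domain and a central REVOLUTA (REV) domain — that
represses the polarizing signal and thereby confines auxin maxima to the
narrow boundary annulus between the two domains.

Each cell $i$ carries auxin $A_i$, total PIN1 $P_i^{tot}$ and a polarizing
signal $X_i$:

$$\frac{dA_i}{dt} = c_A - d_A A_i + \frac{1}{V_i}\Big[D \sum_{j \in N_i}
a_{ij}(A_j - A_i) + T \sum_{j \in N_i} a_{ij}(P_{ji}A_j - P_{ij}A_i)\Big],$$

$$\frac{dP_i^{tot}}{dt} = c_P - d_P P_i^{tot}, \qquad
\frac{dX_i}{dt} = V_X\,
\frac{A_i^{n_{XA}}}{K_{XA}^{n_{XA}} + A_i^{n_{XA}}}\,
\frac{K_{XR}^{n_{XR}}}{K_{XR}^{n_{XR}} + R_i^{n_{XR}}}\,
\frac{K_{XK}^{n_{XK}}}{K_{XK}^{n_{XK}} + K_i^{n_{XK}}} - d_X X_i,$$

where $V_i$ is the cell volume, $a_{ij} = a_{ji}$ the contact area of the
wall between cells $i$ and $j$, and $N_i$ the wall neighbors of $i$. The
membrane PIN1 of cell $i$ facing $j$ is not a dynamical state: PIN1 cycling
between cytosol and membranes is assumed fast (quasi-equilibrium), giving

$$P_{ij} = P_i^{tot}\,\frac{1 - k_p + k_p X_j}
{f_p + \sum_{k \in N_i} (1 - k_p + k_p X_k)},$$

with $f_p$ the endocytosis/exocytosis rate ratio and $k_p \in [0,1]$ the
weight of polarized versus symmetric exocytosis. The remainder
$P_i^{tot} f_p / (f_p + \sum_k w_k)$ stays in the cytosol, so membrane PIN1
never exceeds the total. `pin_allocation()` is this algebraic map;
the test suite checks it against numerical integration of the explicit
exchange ODE $dP_{ij}/dt = k_x[(1-k_p) + k_p X_j]P_i - k_n P_{ij}$.

The signal $X$ is deliberately abstract — it has been interpreted both as a
molecular relay and as mechanical stress in neighboring walls — and the
package keeps it abstract. When $K_i = R_i = 0$ everywhere both repression
factors are exactly 1 and the model reduces to the bare polarization
model; this reduction is exact in floating point because the repression
Hills are evaluated as $1/(1 + (x/K)^n)$ with $x = 0$.

## The KAN/REV prepattern

The prepattern is computed on the template before the dynamics run and is
static afterwards. With $r_i$ the distance of cell $i$ from the
volume-weighted tissue center,

$$\frac{dK_i}{dt} = V_K \frac{r_i^{n_K}}{K_K^{n_K} + r_i^{n_K}} - d_K K_i,$$

run to equilibrium, with defaults $V_K = V_R = d_K = d_R = 1$, $K_K = 30$,
$K_R = 25$, $n_K = n_R = 20$. Because production is constant in time and
decay linear, the equilibrium is closed-form
(`prepattern_equilibrium()`); `integrate_prepattern()` exists to verify it
numerically. KAN is binarized at 0.5 — cells with raw equilibrium level
$\le 0.5$ (which includes the half-max cell at $r = K_K$ exactly) get
$K = 0$, the rest $K = 1$ — while REV stays graded.

One design choice was genuinely open: with both Hill terms written in
increasing form, REV would be *peripheral*, yet the biological picture and
the half-max ordering ($K_R = 25 < K_K = 30$) only produce the intended
"two domains with a low-expression gap" if REV *decreases* with radius.
The package therefore defaults to the decreasing (central) REV orientation
and keeps the increasing form available via
`prepattern_params(rev_orientation = "peripheral")`. Similarly, no
explicit cutoff defines "low REV" at the boundary; `boundary_mask()`
defaults to `rev_threshold = 0.5`, mirroring the KAN threshold, which with
the default parameters makes the annulus $25 < r \le 30$.

## Tissue templates

The dynamics only consume $(V_i, a_{ij}, N_i)$ plus centroids, so any
irregular polygonal tiling is a valid template. `generate_disc_tissue()`
places seeded random points in a disc, applies centroidal (Lloyd)
relaxation, and clips the Voronoi tessellation to the disc; volumes are
polygon areas and wall areas are shared-edge lengths. The default template
(400 cells, radius 60, 30 relaxation steps) puts the prepattern thresholds
(25, 30) comfortably inside the tissue with a boundary annulus roughly one
cell wide (~30 cells). `generate_ring_tissue()` provides the periodic
1-D geometry used for oracle and conservation tests.

What the generator does *not* emulate: real meristem templates grow, divide
and curve in 3-D, and their KAN/REV domains are set by gene regulation
rather than a radial rule. Passing tests on these synthetic templates show
that the transport-feedback mechanism behaves as designed on an idealized
geometry, not that parameter values are calibrated to any real meristem.

Boundary handling: walls exist only between cells, so the tissue edge is a
no-flux boundary.

## Numerical choices

* **Solver.** The coupled system is integrated with the embedded
  Cash–Karp Runge–Kutta 4(5) pair (via `deSolve`), adaptive step size,
  defaults `rtol = 1e-6`, `atol = 1e-9`, from concentrations exactly zero
  in all compartments. $P_{ij}$ is recomputed inside every derivative
  evaluation, never integrated.
* **Conservation.** The passive and active flux terms are antisymmetric in
  volume-weighted form, and Runge–Kutta steps preserve linear invariants,
  so with $c_A = d_A = 0$ the total mass $\sum_i V_i A_i$ drifts only at
  rounding level (measured ~1e-15 over $t \in [0, 100]$ by
  `conservation_report()`).
* **Symmetry breaking.** Initial conditions are exactly zero. On irregular
  discs, geometry breaks the symmetry. On perfect rings the homogeneous
  state would persist to machine precision, so `simulate_tissue()` offers
  seeded multiplicative log-normal noise on $c_A$ (default off; the
  package's ring experiments use `noise_sd = 0.01`).
* **Steep Hills.** All Hill terms are evaluated as $t/(1+t)$ with
  $t = (x/K)^n$, stable for $n = 20$ and large $r$; an infinite $t$ maps
  to 1 (or 0 for repression).
* **Peak calling.** A peak is a cell strictly exceeding all wall neighbors
  and `rel_threshold` (default 0.5) of the global maximum; ties disqualify
  both cells, so homogeneous fields yield zero peaks deterministically.
  Peaks are single cells; plateau merging is out of scope because the
  model's steady fields are generically non-degenerate.

## Parameter defaults and calibration

The kinetic scales are fixed at $c_A = d_A = c_P = d_P = 0.1$ and
$d_X = 1$, making the homogeneous state $A = P^{tot} = 1$ and giving the
transport terms an O(1) reference concentration. The transport/polarity
defaults ($T = 10$, $D = 0.3$, $V_X = 1$, $K_{XA} = 1$, $n_{XA} = 4$,
$f_p = 1$, $k_p = 0.9$) were fixed by the coarse scan in
`scripts/calibrate.R`: the unrepressed model must pattern spontaneously on
a 100-cell ring (steady-state peak-to-trough ratio above 2) and, with the
default prepattern on a 400-cell disc, at least 90% of peaks must fall in
the boundary annulus with a reduced radial spread. The scan shows a broad
acceptable region — patterning fails mainly when the auxin→X response is
both shallow ($n_{XA} = 2$) and weak ($V_X = 0.5$, $k_p = 0.7$) — and the
defaults sit well inside it. The repression constants
$K_{XR} = K_{XK} = 0.2$ with exponent 2 make a fully expressing domain
($K$ or $R \approx 1$) suppress X production to a few percent while
leaving boundary cells essentially unrepressed.

Simulations in the tests and the reproduction script use a 100-cell ring
and a 400-cell disc integrated to $t = 1500$ (about 150 auxin turnover
times), sampled at 51 time points; `steady_state()` checks that the
trailing samples of $A$ have stopped moving.

## The headline experiment

```{r, eval = FALSE}
library(auxinpattern)
res <- figure9_experiment(n_cells = 400, radius = 60, seed = 1)
res$report
```

One disc template, identical parameters, two runs. Without the prepattern,
auxin maxima appear across the whole disc (large radial spread). With the
KAN/REV prepattern repressing X, the polarization feedback — and hence
peak formation — survives only in the boundary annulus:
`boundary_score_on` is the fraction of peaks inside the annulus
(1.0 under the default conditions) and `peak_radius_iqr_on` collapses to
roughly one cell diameter, versus tens of length units without the
prepattern.

## Known limitations

* The tissue is static: no growth, division, or mechanics, so the model
  cannot produce divergence-angle sequences over successive initiations.
* X is phenomenological; no mechanical-stress realization is attempted.
* The 0.5 KAN threshold and the boundary `rev_threshold` are artifact
  definitions of the discrete domains, not measured quantities.
* Peak statistics (threshold 0.5 of the max, strict maxima) are the
  package's operationalization of qualitative claims; other reasonable
  detectors would shift counts slightly, which is why acceptance checks
  are property-based (scores, ratios, orderings) rather than exact counts.
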