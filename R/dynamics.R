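#' Rate constants of the auxin / PIN1 / signal-X dynamics
#'
#' The model couples three per-cell variables on the tissue graph. Auxin
#' \eqn{A_i} is produced and degraded in every cell and moves between
#' neighbors both passively and by PIN1-mediated active transport:
#' \deqn{dA_i/dt = c_A - d_A A_i + \frac{1}{V_i}\Big[D \sum_{j} a_{ij}(A_j - A_i)
#'   + T \sum_{j} a_{ij}(P_{ji} A_j - P_{ij} A_i)\Big].}
#' Total PIN1 per cell follows simple turnover, \eqn{dP_i^{tot}/dt = c_P - d_P P_i^{tot}},
#' and its membrane allocation \eqn{P_{ij}} is a quasi-equilibrium function
#' of the neighbors' polarizing signal (see [pin_allocation()]). The signal
#' \eqn{X_i} is activated by the cell's own auxin and repressed by the KAN
#' and REV prepattern factors:
#' \deqn{dX_i/dt = V_X \frac{A_i^{n_{XA}}}{K_{XA}^{n_{XA}}+A_i^{n_{XA}}}
#'   \frac{K_{XR}^{n_{XR}}}{K_{XR}^{n_{XR}}+R_i^{n_{XR}}}
#'   \frac{K_{XK}^{n_{XK}}}{K_{XK}^{n_{XK}}+K_i^{n_{XK}}} - d_X X_i.}
#' With KAN and REV zero everywhere both repression factors are identically
#' 1 and the system reduces to the classic up-the-gradient polarization
#' model.
#'
#' Default values were fixed by a coarse calibration scan over the
#' transport/polarity parameters at unit-scale kinetics (see
#' `scripts/calibrate.R` in the source repository): they lie well inside the
#' patterning regime on both ring and disc geometries. All rates are in
#' arbitrary model units (concentration per time, or per time).
#'
#' @param c_A,d_A auxin production and degradation rates.
#' @param D passive (diffusion-like) transport coefficient.
#' @param T_active active PIN1-mediated transport coefficient (the model's
#'   symbol T; renamed in code to avoid masking `TRUE`'s shorthand).
#' @param c_P,d_P PIN1 production and degradation rates.
#' @param V_X maximal production rate of the polarizing signal X.
#' @param K_XA,n_XA Hill constants of auxin activation of X.
#' @param K_XR,n_XR Hill constants of REV repression of X.
#' @param K_XK,n_XK Hill constants of KAN repression of X.
#' @param d_X degradation rate of X.
#' @param f_p ratio of endocytosis to exocytosis rates (k_n / k_x, > 0).
#' @param k_p weight of polarized vs symmetric exocytosis, in \[0, 1\].
#' @return object of class `model_params`.
#' @export
model_params <- function(c_A = 0.1, d_A = 0.1, D = 0.3, T_active = 10,
                         c_P = 0.1, d_P = 0.1,
                         V_X = 1, K_XA = 1, n_XA = 4,
                         K_XR = 0.2, n_XR = 2, K_XK = 0.2, n_XK = 2,
                         d_X = 1, f_p = 1, k_p = 0.9) {
  p <- list(c_A = c_A, d_A = d_A, D = D, T_active = T_active,
            c_P = c_P, d_P = d_P, V_X = V_X,
            K_XA = K_XA, n_XA = n_XA, K_XR = K_XR, n_XR = n_XR,
            K_XK = K_XK, n_XK = n_XK, d_X = d_X, f_p = f_p, k_p = k_p)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("all model parameters must be finite and non-negative")
  }
  if (p$f_p <= 0) stop("`f_p` must be positive")
  if (p$k_p < 0 || p$k_p > 1) stop("`k_p` must lie in [0, 1]")
  if (any(c(p$K_XA, p$K_XR, p$K_XK) <= 0)) stop("Hill half-max constants must be positive")
  if (any(c(p$n_XA, p$n_XR, p$n_XK) < 1)) stop("Hill exponents must be >= 1")
  structure(p, class = "model_params")
}

#' Quasi-equilibrium PIN1 membrane allocation
#'
#' PIN1 cycles between the cytosol and the membrane compartments facing each
#' neighbor; exocytosis toward neighbor j is biased by that neighbor's
#' polarizing signal. Assuming cycling is fast relative to auxin dynamics,
#' the membrane amounts take the algebraic form
#' \deqn{P_{ij} = P_i^{tot} \frac{1 - k_p + k_p X_j}{f_p + \sum_{k \in N_i} (1 - k_p + k_p X_k)}.}
#' The remainder \eqn{P_i^{tot} f_p / (f_p + \sum_k w_k)} stays cytosolic,
#' so membrane PIN1 never exceeds the total.
#'
#' @param P_tot total PIN1 of the cell (>= 0).
#' @param X_neighbors signal levels of the neighbors, in a fixed order.
#' @param f_p endocytosis/exocytosis rate ratio (> 0).
#' @param k_p polarized-exocytosis weight in \[0, 1\].
#' @return numeric vector of membrane PIN1 values, one per neighbor, in the
#'   same order as `X_neighbors`.
#' @examples
#' pin_allocation(1, c(1, 3), f_p = 1, k_p = 1)  # 0.2, 0.6; cytosol keeps 0.2
#' @export
pin_allocation <- function(P_tot, X_neighbors, f_p, k_p) {
  if (!is.numeric(f_p) || f_p <= 0) stop("`f_p` must be positive")
  if (!is.numeric(k_p) || k_p < 0 || k_p > 1) stop("`k_p` must lie in [0, 1]")
  if (P_tot < 0 || any(X_neighbors < 0)) stop("`P_tot` and signals must be non-negative")
  w <- 1 - k_p + k_p * X_neighbors
  P_tot * w / (f_p + sum(w))
}

# Directed-edge representation of a tissue for fast RHS evaluation:
# ef/et are from/to cell indices, ea the wall area, opp the index of the
# reverse edge.
edge_structure <- function(tissue) {
  ids <- tissue$cells$id
  i <- match(tissue$walls$i, ids)
  j <- match(tissue$walls$j, ids)
  m <- length(i)
  list(ef = c(i, j), et = c(j, i), ea = rep(tissue$walls$area, 2L),
       opp = c(m + seq_len(m), seq_len(m)),
       V = tissue$cells$volume, n = length(ids), m = m)
}

# sum per-from-cell over directed edges (cells with no edges get 0)
edge_accumulate <- function(v, ef, n) {
  out <- numeric(n)
  s <- rowsum(v, ef)
  out[as.integer(rownames(s))] <- s
  out
}

# membrane PIN for all directed edges at once
pin_alloc_edges <- function(P_tot, X, es, f_p, k_p) {
  w <- 1 - k_p + k_p * pmax(X[es$et], 0)
  denom <- f_p + edge_accumulate(w, es$ef, es$n)
  P_tot[es$ef] * w / denom[es$ef]
}

#' Per-wall membrane PIN1 of a system state
#'
#' Evaluates [pin_allocation()] for every directed wall of the tissue.
#'
#' @param state a `system_state` or a list with numeric `P_tot` and `X`.
#' @param tissue a `tissue_graph`.
#' @param params a [model_params()] object.
#' @return data.frame with columns `i`, `j` (cell ids; PIN1 sits in the
#'   membrane of `i` facing `j`) and `P_ij`.
#' @export
pin_membrane <- function(state, tissue, params) {
  es <- edge_structure(tissue)
  P <- pin_alloc_edges(state$P_tot, state$X, es, params$f_p, params$k_p)
  ids <- tissue$cells$id
  data.frame(i = ids[es$ef], j = ids[es$et], P_ij = P)
}

#' Right-hand sides of the model equations
#'
#' Evaluate the instantaneous rates of change of each state variable on a
#' tissue. These are the building blocks [simulate_tissue()] integrates;
#' they are exposed for testing and for composing custom experiments.
#'
#' `rhs_auxin` uses the membrane PIN1 implied by the state's `X` via the
#' quasi-equilibrium allocation; a `P_mem` component on `state` (data.frame
#' as returned by [pin_membrane()]) overrides it, which makes the transport
#' term testable in isolation.
#'
#' @param state list with numeric per-cell `A`, `P_tot`, `X` (and optional
#'   `P_mem`).
#' @param tissue a `tissue_graph`.
#' @param params a [model_params()] object.
#' @param prepattern a `prepattern_field`, or `NULL` for the unrepressed
#'   model (KAN = REV = 0 everywhere).
#' @return numeric vector of per-cell time derivatives.
#' @export
rhs_auxin <- function(state, tissue, params) {
  es <- edge_structure(tissue)
  if (length(state$A) != es$n) stop("state/tissue size mismatch")
  A <- state$A
  Pe <- if (!is.null(state$P_mem)) {
    ids <- tissue$cells$id
    key_state <- paste(match(state$P_mem$i, ids), match(state$P_mem$j, ids))
    key_edge <- paste(es$ef, es$et)
    idx <- match(key_edge, key_state)
    if (anyNA(idx)) stop("`P_mem` must cover every directed wall")
    state$P_mem$P_ij[idx]
  } else {
    pin_alloc_edges(state$P_tot, state$X, es, params$f_p, params$k_p)
  }
  passive <- params$D * es$ea * (A[es$et] - A[es$ef])
  active <- params$T_active * es$ea * (Pe[es$opp] * A[es$et] - Pe * A[es$ef])
  params$c_A - params$d_A * A + edge_accumulate(passive + active, es$ef, es$n) / es$V
}

#' @rdname rhs_auxin
#' @export
rhs_pin_total <- function(state, params) {
  params$c_P - params$d_P * state$P_tot
}

#' @rdname rhs_auxin
#' @export
rhs_signal_x <- function(state, prepattern, params) {
  n <- length(state$A)
  K <- if (is.null(prepattern)) rep(0, n) else prepattern$K
  R <- if (is.null(prepattern)) rep(0, n) else prepattern$R
  act <- hill_up(pmax(state$A, 0), params$K_XA, params$n_XA)
  rep_R <- hill_down(R, params$K_XR, params$n_XR)
  rep_K <- hill_down(K, params$K_XK, params$n_XK)
  params$V_X * act * rep_R * rep_K - params$d_X * state$X
}

#' Simulate the auxin / PIN1 / X dynamics on a tissue
#'
#' Integrates the coupled system with an embedded adaptive Runge-Kutta pair
#' (Cash-Karp 4(5) by default), starting from zero concentrations in all
#' compartments unless `init` is given. Membrane PIN1 is recomputed from
#' the quasi-equilibrium allocation inside every derivative evaluation; it
#' is never an ODE state. The KAN/REV prepattern, when supplied, is static
#' during the run.
#'
#' On perfectly regular templates (rings) the homogeneous state is an exact
#' fixed point and zero initial conditions preserve the symmetry to machine
#' precision; `noise_sd > 0` applies a seeded multiplicative log-normal
#' perturbation to the per-cell auxin production rate `c_A` to break it.
#' Irregular disc templates break symmetry geometrically and need no noise.
#'
#' @param tissue a `tissue_graph`.
#' @param params a [model_params()] object.
#' @param prepattern optional `prepattern_field` (KAN/REV repression of X);
#'   `NULL` runs the unrepressed model.
#' @param t_end end time (> 0).
#' @param output_times times at which states are recorded; default 101
#'   evenly spaced samples on \[0, t_end\].
#' @param init optional initial state: list with per-cell `A`, `P_tot`, `X`
#'   (each recycled if scalar). Default all-zero.
#' @param noise_sd standard deviation of the log-normal factor on `c_A`
#'   (0 = off).
#' @param noise_seed RNG seed for the noise draw (required reproducibility
#'   handle when `noise_sd > 0`).
#' @param rtol,atol relative and absolute local error tolerances.
#' @param min_step step-size underflow threshold: integration aborts with an
#'   error of class `integration_failure` below it.
#' @param max_step optional cap on the step size.
#' @param method a `deSolve` integrator name or `rkMethod` spec; default the
#'   Cash-Karp embedded 4(5) pair.
#' @return object of class `tissue_trajectory`: sampled `times`, state
#'   matrices `A`, `P_tot`, `X` (time by cell, columns named by cell id),
#'   the inputs, and `solver_stats` (steps, derivative evaluations).
#' @examples
#' ring <- generate_ring_tissue(10)
#' traj <- simulate_tissue(ring, model_params(T_active = 0), t_end = 100)
#' tail(final_state(traj)$A, 3)  # relaxing toward c_A / d_A = 1
#' @export
simulate_tissue <- function(tissue, params = model_params(), prepattern = NULL,
                            t_end = 500, output_times = NULL, init = NULL,
                            noise_sd = 0, noise_seed = 1L,
                            rtol = 1e-6, atol = 1e-9,
                            min_step = 1e-12, max_step = NULL,
                            method = "rk45ck") {
  stopifnot(inherits(tissue, "tissue_graph"), inherits(params, "model_params"))
  if (t_end <= 0) stop("`t_end` must be positive")
  if (!is.null(prepattern) && nrow(prepattern) != n_cells(tissue)) {
    stop("prepattern/tissue size mismatch")
  }
  es <- edge_structure(tissue)
  n <- es$n
  idx_A <- seq_len(n)
  idx_P <- n + idx_A
  idx_X <- 2L * n + idx_A

  cA <- rep(params$c_A, n)
  if (noise_sd > 0) {
    cA <- cA * with_seed(noise_seed, exp(noise_sd * rnorm(n)))
  }
  K <- if (is.null(prepattern)) rep(0, n) else prepattern$K
  R <- if (is.null(prepattern)) rep(0, n) else prepattern$R
  rep_static <- hill_down(R, params$K_XR, params$n_XR) *
    hill_down(K, params$K_XK, params$n_XK)

  D <- params$D; Tr <- params$T_active
  d_A <- params$d_A; c_P <- params$c_P; d_P <- params$d_P
  V_X <- params$V_X; K_XA <- params$K_XA; n_XA <- params$n_XA
  d_X <- params$d_X; f_p <- params$f_p; k_p <- params$k_p
  ef <- es$ef; et <- es$et; ea <- es$ea; opp <- es$opp; V <- es$V

  rhs <- function(t, y, p) {
    A <- y[idx_A]; P <- y[idx_P]; X <- y[idx_X]
    Pe <- pin_alloc_edges(P, X, es, f_p, k_p)
    flux <- D * ea * (A[et] - A[ef]) +
      Tr * ea * (Pe[opp] * A[et] - Pe * A[ef])
    dA <- cA - d_A * A + edge_accumulate(flux, ef, n) / V
    dX <- V_X * hill_up(pmax(A, 0), K_XA, n_XA) * rep_static - d_X * X
    list(c(dA, c_P - d_P * P, dX))
  }

  y0 <- numeric(3L * n)
  if (!is.null(init)) {
    y0[idx_A] <- rep_len(init$A %||% 0, n)
    y0[idx_P] <- rep_len(init$P_tot %||% 0, n)
    y0[idx_X] <- rep_len(init$X %||% 0, n)
    if (any(y0 < 0)) stop("initial concentrations must be non-negative")
  }
  times <- if (is.null(output_times)) seq(0, t_end, length.out = 101L) else sort(unique(c(0, output_times)))

  meth <- if (is.character(method) && method %in% c("rk45ck", "rk45dp7", "rk45f")) {
    deSolve::rkMethod(method)
  } else {
    method
  }
  out <- withCallingHandlers(
    deSolve::ode(y0, times, rhs, NULL, method = meth,
                 rtol = rtol, atol = atol, hmin = min_step,
                 hmax = if (is.null(max_step)) t_end else max_step,
                 maxsteps = 1e6),
    warning = function(w) {
      # deSolve signals premature stops as warnings; escalate below via nrow
      invokeRestart("muffleWarning")
    }
  )
  if (anyNA(out) || nrow(out) < length(times)) {
    t_fail <- out[nrow(out), 1L]
    stop(structure(class = c("integration_failure", "error", "condition"),
                   list(message = sprintf("integration failed near t = %g", t_fail),
                        call = sys.call(-1))))
  }
  if (any(!is.finite(out))) {
    stop(structure(class = c("numeric_failure", "error", "condition"),
                   list(message = "non-finite values in solution", call = sys.call(-1))))
  }
  istate <- attr(out, "istate")
  stats <- list(n_steps = unname(istate[2]), n_rhs_evals = unname(istate[3]))
  ids <- as.character(tissue$cells$id)
  A <- out[, 1L + idx_A, drop = FALSE]; colnames(A) <- ids
  P <- out[, 1L + idx_P, drop = FALSE]; colnames(P) <- ids
  X <- out[, 1L + idx_X, drop = FALSE]; colnames(X) <- ids
  structure(
    list(times = out[, 1L], A = A, P_tot = P, X = X,
         tissue = tissue, params = params, prepattern = prepattern,
         noise_sd = noise_sd, noise_seed = noise_seed,
         rtol = rtol, atol = atol, method = if (is.character(method)) method else "custom",
         solver_stats = stats),
    class = "tissue_trajectory"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tissue_trajectory <- function(x, ...) {
  fs <- final_state(x)
  cat(sprintf("tissue_trajectory: %d cells, %d samples on [0, %g]\n",
              ncol(x$A), length(x$times), max(x$times)))
  cat(sprintf("  final A range [%.4g, %.4g]; solver: %s, %s steps\n",
              min(fs$A), max(fs$A), x$method,
              format(x$solver_stats$n_steps)))
  invisible(x)
}

#' Extract a system state from a trajectory
#'
#' @param trajectory a `tissue_trajectory`.
#' @param t time point; defaults to the final sample. The nearest recorded
#'   sample is returned.
#' @return object of class `system_state`: list with `t`, per-cell `A`,
#'   `P_tot`, `X`.
#' @export
state_at <- function(trajectory, t = NULL) {
  k <- if (is.null(t)) length(trajectory$times) else which.min(abs(trajectory$times - t))
  structure(
    list(t = trajectory$times[k],
         A = trajectory$A[k, ], P_tot = trajectory$P_tot[k, ], X = trajectory$X[k, ]),
    class = "system_state"
  )
}

#' @rdname state_at
#' @export
final_state <- function(trajectory) state_at(trajectory)

#' Steady-state check on a trajectory
#'
#' Declares convergence when the auxin field stops moving: over the trailing
#' `window` recorded samples, the maximum relative change of any cell's A
#' (relative to the final field's maximum magnitude) must stay below `tol`.
#'
#' @param trajectory a `tissue_trajectory`.
#' @param window number of trailing samples to examine (>= 2).
#' @param tol relative-change tolerance.
#' @return the final `system_state` if converged; otherwise an object of
#'   class `not_converged` carrying the measured maximum relative change.
#' @export
steady_state <- function(trajectory, window = 10L, tol = 1e-4) {
  nt <- length(trajectory$times)
  if (window < 2L || nt < window) stop("trajectory shorter than `window`")
  tail_idx <- (nt - window + 1L):nt
  Aw <- trajectory$A[tail_idx, , drop = FALSE]
  scale <- max(abs(Aw[window, ]), 1e-300)
  rel <- max(abs(sweep(Aw, 2L, Aw[window, ]))) / scale
  if (rel < tol) {
    state_at(trajectory)
  } else {
    structure(list(max_rel_change = rel, tol = tol), class = "not_converged")
  }
}
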