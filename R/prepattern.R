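#' Parameters of the radial KAN/REV prepattern
#'
#' The dorsoventral prepattern places KANADI (KAN) expression in the tissue
#' periphery and REVOLUTA (REV) expression in the center, with a
#' low-expression boundary annulus in between. Each factor follows first
#' order kinetics with a Hill-shaped production term in the cell's radial
#' coordinate `r`:
#' \deqn{dK_i/dt = V_K r_i^{n_K} / (K_K^{n_K} + r_i^{n_K}) - d_K K_i}
#' and the analogous equation for REV. With `rev_orientation = "central"`
#' (the default) the REV production term is the complementary, decreasing
#' Hill form \eqn{K_R^{n_R}/(K_R^{n_R}+r^{n_R})}, so REV is high in the
#' center; `"peripheral"` uses the increasing form for both factors.
#'
#' Defaults: unit production and degradation, half-max radii `K_K = 30` and
#' `K_R = 25` (model length units) and steepness `n_K = n_R = 20`, which
#' carve two sharply separated domains with a narrow annulus of low KAN and
#' low REV between radii ~25 and ~30.
#'
#' @param V_K,V_R maximal production rates (> 0).
#' @param d_K,d_R degradation rates (> 0).
#' @param K_K,K_R Hill half-max radii (> 0).
#' @param n_K,n_R Hill exponents (>= 1).
#' @param rev_orientation `"central"` (REV decreasing with r) or
#'   `"peripheral"` (REV increasing with r).
#' @return object of class `prepattern_params`.
#' @export
prepattern_params <- function(V_K = 1, V_R = 1, d_K = 1, d_R = 1,
                              K_K = 30, K_R = 25, n_K = 20, n_R = 20,
                              rev_orientation = c("central", "peripheral")) {
  rev_orientation <- match.arg(rev_orientation)
  p <- list(V_K = V_K, V_R = V_R, d_K = d_K, d_R = d_R,
            K_K = K_K, K_R = K_R, n_K = n_K, n_R = n_R,
            rev_orientation = rev_orientation)
  num <- unlist(p[1:8])
  if (any(!is.finite(num)) || any(num[1:6] <= 0)) {
    stop("all prepattern rates and half-max radii must be positive and finite")
  }
  if (p$n_K < 1 || p$n_R < 1) stop("Hill exponents must be >= 1")
  structure(p, class = "prepattern_params")
}

# x^n / (K^n + x^n), computed as t/(1+t) with t = (x/K)^n for stability at
# large x and steep n; x must be >= 0.
hill_up <- function(x, K, n) {
  t <- (x / K)^n
  out <- t / (1 + t)
  out[is.infinite(t)] <- 1
  out
}

# K^n / (K^n + x^n) = 1 - hill_up
hill_down <- function(x, K, n) {
  t <- (x / K)^n
  out <- 1 / (1 + t)
  out[is.infinite(t)] <- 0
  out
}

#' Radial coordinate of every cell
#'
#' Distance of each cell centroid from the tissue center, defined as the
#' volume-weighted centroid of the cell centroids. Translation of the whole
#' tissue leaves the result unchanged.
#'
#' @param tissue a `tissue_graph`.
#' @param warn warn when no cell lies inside the default central REV domain
#'   (all `r >= 25`), which would make the prepattern degenerate.
#' @return numeric vector of distances, aligned with `tissue$cells`.
#' @export
radial_coordinate <- function(tissue, warn = TRUE) {
  w <- tissue$cells$volume
  cx <- sum(w * tissue$cells$x) / sum(w)
  cy <- sum(w * tissue$cells$y) / sum(w)
  r <- sqrt((tissue$cells$x - cx)^2 + (tissue$cells$y - cy)^2)
  if (warn && !any(r < 25)) {
    warning("no cell has r < 25: the default prepattern would have no central REV domain")
  }
  r
}

#' Equilibrium KAN/REV prepattern (closed form)
#'
#' The prepattern kinetics are linear in K and R (constant, r-dependent
#' production; first-order decay), so running them to equilibrium from zero
#' initial conditions has the closed form production/degradation. KAN is
#' then binarized: cells with raw equilibrium level above 0.5 get `K = 1`,
#' all others (including exactly 0.5, reached at `r = K_K`) get `K = 0`.
#' REV stays graded.
#'
#' @param r per-cell radial coordinates (>= 0), from [radial_coordinate()].
#' @param params a [prepattern_params()] object.
#' @return object of class `prepattern_field`: a data.frame with columns
#'   `r`, `K_raw` (pre-threshold equilibrium KAN), `K` (0/1 after the 0.5
#'   threshold) and `R` (graded REV).
#' @examples
#' fld <- prepattern_equilibrium(c(0, 27.5, 60), prepattern_params())
#' fld
#' @export
prepattern_equilibrium <- function(r, params = prepattern_params()) {
  if (any(!is.finite(r)) || any(r < 0)) stop("radial coordinates must be finite and >= 0")
  K_raw <- (params$V_K / params$d_K) * hill_up(r, params$K_K, params$n_K)
  R <- (params$V_R / params$d_R) * switch(params$rev_orientation,
    central = hill_down(r, params$K_R, params$n_R),
    peripheral = hill_up(r, params$K_R, params$n_R)
  )
  structure(
    data.frame(r = r, K_raw = K_raw, K = as.numeric(K_raw > 0.5), R = R),
    class = c("prepattern_field", "data.frame")
  )
}

#' Equilibrium KAN/REV prepattern (numerical integration)
#'
#' Integrates the prepattern ODEs from zero initial conditions on a tissue
#' and applies the same 0.5 KAN threshold as [prepattern_equilibrium()].
#' Exists as a fidelity check on the closed form: for
#' `t_end >> 1/min(d_K, d_R)` the two agree to within the residual
#' exponential transient.
#'
#' @param tissue a `tissue_graph`.
#' @param params a [prepattern_params()] object.
#' @param t_end integration horizon; the default leaves a relative transient
#'   of about `exp(-20)`.
#' @param tol convergence tolerance: warns (class
#'   `prepattern_not_converged`) if `max |dK/dt| > tol * d_K` at `t_end`.
#' @return a `prepattern_field` as in [prepattern_equilibrium()], with
#'   attribute `converged`.
#' @export
integrate_prepattern <- function(tissue, params = prepattern_params(),
                                 t_end = 20 / min(params$d_K, params$d_R),
                                 tol = 1e-6) {
  r <- radial_coordinate(tissue, warn = FALSE)
  n <- length(r)
  prodK <- params$V_K * hill_up(r, params$K_K, params$n_K)
  prodR <- params$V_R * switch(params$rev_orientation,
    central = hill_down(r, params$K_R, params$n_R),
    peripheral = hill_up(r, params$K_R, params$n_R)
  )
  rhs <- function(t, y, p) {
    K <- y[seq_len(n)]
    R <- y[n + seq_len(n)]
    list(c(prodK - params$d_K * K, prodR - params$d_R * R))
  }
  yT <- if (t_end <= 0) {
    rep(0, 2 * n)
  } else {
    out <- deSolve::ode(rep(0, 2 * n), c(0, t_end), rhs, NULL,
                        method = deSolve::rkMethod("rk45ck"),
                        rtol = 1e-10, atol = 1e-12)
    out[nrow(out), -1L]
  }
  K_num <- yT[seq_len(n)]
  R_num <- yT[n + seq_len(n)]
  dK <- prodK - params$d_K * K_num
  converged <- t_end > 0 && max(abs(dK)) <= tol * params$d_K
  if (!converged) {
    warning(structure(
      class = c("prepattern_not_converged", "warning", "condition"),
      list(message = sprintf("prepattern not at equilibrium at t = %g (max |dK/dt| = %.3g)",
                             t_end, if (t_end > 0) max(abs(dK)) else max(abs(prodK))),
           call = sys.call(-1))))
  }
  fld <- structure(
    data.frame(r = r, K_raw = unname(K_num), K = as.numeric(K_num > 0.5),
               R = unname(R_num)),
    class = c("prepattern_field", "data.frame")
  )
  attr(fld, "converged") <- converged
  fld
}

#' Boundary annulus mask
#'
#' Identifies the dorsoventral boundary domain: cells where thresholded KAN
#' is absent (`K = 0`) and REV is low (`R < rev_threshold`). With the
#' default prepattern parameters and central REV this is an annulus between
#' the REV half-max radius (25) and the KAN half-max radius (30).
#'
#' @param field a `prepattern_field`.
#' @param rev_threshold REV cutoff defining "low" expression, strictly
#'   between 0 and the REV plateau level; default 0.5 mirrors the KAN
#'   threshold.
#' @return logical vector, `TRUE` for boundary cells.
#' @export
boundary_mask <- function(field, rev_threshold = 0.5) {
  stopifnot(inherits(field, "prepattern_field"))
  if (!is.numeric(rev_threshold) || rev_threshold <= 0) {
    stop("`rev_threshold` must be positive")
  }
  field$K == 0 & field$R < rev_threshold
}

#' @export
print.prepattern_field <- function(x, ...) {
  cat(sprintf("prepattern_field: %d cells; KAN-on %d, boundary (K=0, R<0.5) %d\n",
              nrow(x), sum(x$K == 1), sum(boundary_mask(x))))
  NextMethod()
}
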