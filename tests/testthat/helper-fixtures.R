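# Shared fixtures, built in code. The generators are deterministic, so these
# are identical in every session.

ring4 <- generate_ring_tissue(4)
ring10 <- generate_ring_tissue(10)

# small irregular disc used by several suites; built once
fixture_disc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_disc_tissue(60, radius = 15, seed = 3, relaxation_steps = 15)
    }
    cache
  }
})

# two identical cells joined by one wall: the minimal transport geometry
two_cell_tissue <- function(V = 1, a = 1) {
  tissue_graph(
    cells = data.frame(id = 1:2, volume = V, x = c(0, 1), y = 0,
                       boundary = TRUE),
    walls = data.frame(i = 1L, j = 2L, area = a),
    meta = list(generator = "pair")
  )
}

# steady state of the explicit PIN1 endo/exocytosis exchange ODE
# dP_ij/dt = k_x [(1 - k_p) + k_p X_j] P_i - k_n P_ij, P_i = P_tot - sum(P_ij),
# integrated from all-membrane-empty; independent oracle for pin_allocation
pin_exchange_oracle <- function(P_tot, X, f_p, k_p, k_x = 1) {
  k_n <- f_p * k_x
  w <- (1 - k_p) + k_p * X
  rhs <- function(t, y, p) {
    list(k_x * w * (P_tot - sum(y)) - k_n * y)
  }
  t_end <- 400 / min(1, k_n)
  out <- deSolve::ode(rep(0, length(X)), c(0, t_end), rhs, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-14)
  unname(out[nrow(out), -1L])
}
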