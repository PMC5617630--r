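test_that("pin_allocation implements the quasi-equilibrium formula", {
  # equal signals split membrane PIN1 equally
  p <- pin_allocation(1, rep(2, 4), f_p = 1, k_p = 0.9)
  expect_equal(p, rep(p[1], 4))

  # k_p = 0: allocation independent of the signals
  expect_equal(pin_allocation(3, c(0, 5, 100), f_p = 2, k_p = 0),
               rep(3 / (2 + 3), 3))

  # worked example: P_tot = 1, f_p = 1, k_p = 1, X = (1, 3)
  p <- pin_allocation(1, c(1, 3), f_p = 1, k_p = 1)
  expect_equal(p, c(0.2, 0.6))
  expect_equal(1 - sum(p), 0.2)  # cytosolic remainder

  # membrane total never exceeds P_tot, even with all-zero signals at k_p = 1
  expect_equal(pin_allocation(1, c(0, 0), f_p = 1, k_p = 1), c(0, 0))
  expect_error(pin_allocation(1, c(1, 2), f_p = 0, k_p = 0.5), "f_p")
  expect_error(pin_allocation(1, c(1, 2), f_p = 1, k_p = 1.5), "k_p")
})

test_that("pin_allocation equals the steady state of the explicit exchange ODE", {
  set.seed(7)
  for (rep in 1:60) {
    m <- sample(1:8, 1)
    P_tot <- runif(1, 0, 2)
    X <- runif(m, 0, 3)
    f_p <- runif(1, 0.2, 5)
    k_p <- runif(1)
    closed <- pin_allocation(P_tot, X, f_p, k_p)
    oracle <- pin_exchange_oracle(P_tot, X, f_p, k_p)
    expect_lt(max(abs(closed - oracle)), 1e-8)
    expect_true(all(closed >= 0))
    expect_lte(sum(closed), P_tot)
  }
})

test_that("auxin right-hand side matches hand evaluation and symmetry limits", {
  # homogeneous state with uniform X: transport sums vanish
  p <- model_params()
  st <- list(A = rep(p$c_A / p$d_A, 10), P_tot = rep(1, 10), X = rep(0.5, 10))
  expect_equal(rhs_auxin(st, ring10, p), rep(0, 10), tolerance = 1e-14)

  # two cells, V = a = 1, c_A = d_A = 0, D = 1, T = 2, prescribed membrane PIN
  pair <- two_cell_tissue()
  p2 <- model_params(c_A = 0, d_A = 0, D = 1, T_active = 2)
  st2 <- list(A = c(1, 0), P_tot = c(1, 1), X = c(0, 0),
              P_mem = data.frame(i = c(1, 2), j = c(2, 1), P_ij = c(0.5, 0.25)))
  dA <- rhs_auxin(st2, pair, p2)
  expect_equal(dA, c(-2, 2))
  expect_equal(sum(dA * pair$cells$volume), 0)  # V-weighted conservation

  # no transport: pure kinetics
  p0 <- model_params(D = 0, T_active = 0)
  stA <- list(A = c(0.3, 2, 5, 1, 0, 0.7, 1.1, 0.2, 3, 4),
              P_tot = rep(1, 10), X = rep(1, 10))
  expect_equal(rhs_auxin(stA, ring10, p0), p0$c_A - p0$d_A * stA$A)
})

test_that("PIN1-total and signal-X right-hand sides follow their kinetics", {
  p <- model_params(c_P = 0.1, d_P = 0.05)
  expect_equal(rhs_pin_total(list(P_tot = p$c_P / p$d_P), p), 0)
  expect_equal(rhs_pin_total(list(P_tot = 0), p), p$c_P)
  expect_equal(rhs_pin_total(list(P_tot = 1), p), 0.05)

  # A = 0 leaves only decay; A at half-max with no repression gives V_X / 2
  st <- list(A = c(0, p$K_XA), X = c(2, 0))
  dX <- rhs_signal_x(st, NULL, p)
  expect_equal(dX[1], -p$d_X * 2)
  expect_equal(dX[2], p$V_X / 2)
})

test_that("with KAN = REV = 0 the X production reduces exactly to the bare model", {
  p <- model_params()
  set.seed(3)
  A <- runif(20, 0, 3)
  st <- list(A = A, X = rep(0, 20))
  null_prep <- structure(
    data.frame(r = 0, K_raw = 0, K = rep(0, 20), R = rep(0, 20)),
    class = c("prepattern_field", "data.frame"))
  bare <- p$V_X * A^p$n_XA / (p$K_XA^p$n_XA + A^p$n_XA)
  expect_identical(rhs_signal_x(st, null_prep, p), bare)
  expect_identical(rhs_signal_x(st, NULL, p), bare)
})

test_that("without active transport the system relaxes to the homogeneous point", {
  p <- model_params(T_active = 0)
  t_end <- 50 / min(p$d_A, p$d_P, p$d_X)
  tr <- simulate_tissue(ring10, p, t_end = t_end)
  fs <- final_state(tr)
  expect_lt(max(abs(fs$A - p$c_A / p$d_A)), 1e-6)
  expect_lt(max(abs(fs$P_tot - p$c_P / p$d_P)), 1e-6)
  expect_lt(max(abs(fs$X - fs$X[1])), 1e-6)
  ss <- steady_state(tr)
  expect_s3_class(ss, "system_state")
})

test_that("total auxin mass is conserved when production and degradation are off", {
  p <- model_params(c_A = 0, d_A = 0)
  set.seed(9)
  init <- list(A = runif(10, 0.5, 2), P_tot = 0, X = 0)
  tr <- simulate_tissue(ring10, p, t_end = 100, init = init)
  rep <- conservation_report(tr, ring10, p)
  expect_false(rep$informational)
  expect_lt(rep$drift, 1e-9)
})

test_that("states stay non-negative along patterning trajectories", {
  tr <- simulate_tissue(ring10, model_params(), t_end = 300,
                        noise_sd = 0.05, noise_seed = 2)
  expect_true(all(tr$A >= -1e-9))
  expect_true(all(tr$P_tot >= -1e-9))
  expect_true(all(tr$X >= -1e-9))
})

test_that("halving rtol changes the final state by less than the coarser rtol", {
  p <- model_params()
  run <- function(rtol) {
    simulate_tissue(ring10, p, t_end = 20, noise_sd = 0.05, noise_seed = 4,
                    rtol = rtol, atol = 1e-12)
  }
  coarse <- final_state(run(1e-6))
  fine <- final_state(run(5e-7))
  expect_lt(max(abs(coarse$A - fine$A)) / max(abs(fine$A)), 1e-6)
})

test_that("noise on c_A is seeded and reproducible", {
  a <- simulate_tissue(ring10, model_params(), t_end = 20, noise_sd = 0.05, noise_seed = 5)
  b <- simulate_tissue(ring10, model_params(), t_end = 20, noise_sd = 0.05, noise_seed = 5)
  c <- simulate_tissue(ring10, model_params(), t_end = 20, noise_sd = 0.05, noise_seed = 6)
  expect_identical(a$A, b$A)
  expect_false(identical(a$A, c$A))
})

test_that("steady_state distinguishes settled from drifting trajectories", {
  p <- model_params(T_active = 0)
  tr <- simulate_tissue(ring10, p, t_end = 500)
  expect_s3_class(steady_state(tr), "system_state")

  drifting <- tr
  drifting$A <- matrix(seq_len(length(tr$times)), ncol = 1)[, rep(1, 10)] * 1.0
  expect_s3_class(steady_state(drifting), "not_converged")

  expect_error(steady_state(tr, window = 1000), "window")
})

test_that("membrane PIN never exceeds the cell total along a trajectory", {
  tr <- simulate_tissue(ring10, model_params(), t_end = 200,
                        noise_sd = 0.05, noise_seed = 8)
  st <- final_state(tr)
  pm <- pin_membrane(st, ring10, model_params())
  expect_true(all(pm$P_ij >= 0))
  tot <- tapply(pm$P_ij, pm$i, sum)
  expect_true(all(tot <= st$P_tot[as.integer(names(tot))] + 1e-12))
})
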