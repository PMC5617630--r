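# brute-force restatement of the peak definition, used as oracle
brute_force_peaks <- function(A, tissue, rel_threshold) {
  ids <- tissue$cells$id
  thr <- rel_threshold * max(A)
  keep <- vapply(seq_along(ids), function(k) {
    nb <- c(match(tissue$walls$j[tissue$walls$i == ids[k]], ids),
            match(tissue$walls$i[tissue$walls$j == ids[k]], ids))
    all(A[k] > A[nb]) && A[k] > thr
  }, logical(1))
  which(keep)
}

test_that("detect_peaks implements the strict local-maximum definition", {
  # homogeneous field: every cell ties with its neighbors, no peaks
  pk <- detect_peaks(rep(1, 10), ring10, 0.5)
  expect_length(pk$peak_cells, 0)

  # one spike
  A <- rep(1, 10); A[4] <- 10
  pk <- detect_peaks(A, ring10, 0.5)
  expect_equal(pk$peak_cells, 4L)
  expect_equal(pk$peak_values, 10)

  expect_error(detect_peaks(A, ring10, 0), "rel_threshold")
  expect_error(detect_peaks(A[1:3], ring10), "mismatch")
})

test_that("detect_peaks agrees with the brute-force oracle on random fields", {
  ring50 <- generate_ring_tissue(50)
  d <- fixture_disc()
  set.seed(21)
  for (rep in 1:20) {
    A <- runif(50)
    expect_equal(detect_peaks(A, ring50, 0.5)$peak_idx,
                 brute_force_peaks(A, ring50, 0.5))
    Ad <- runif(n_cells(d))
    expect_equal(detect_peaks(Ad, d, 0.3)$peak_idx,
                 brute_force_peaks(Ad, d, 0.3))
  }
  # tie between two adjacent cells disqualifies both
  A <- runif(50); A[10] <- A[11] <- 5
  expect_false(any(c(10, 11) %in% detect_peaks(A, ring50, 0.1)$peak_idx))
})

test_that("boundary_restriction_score is the masked fraction and id-invariant", {
  A <- rep(1, 10); A[c(2, 5, 8)] <- c(5, 6, 7)
  pk <- detect_peaks(A, ring10, 0.5)
  expect_equal(length(pk$peak_cells), 3L)
  mask_all <- rep(TRUE, 10)
  expect_equal(boundary_restriction_score(pk, mask_all), 1)
  mask_none <- rep(FALSE, 10)
  expect_equal(boundary_restriction_score(pk, mask_none), 0)
  mask_half <- rep(FALSE, 10); mask_half[c(2, 5)] <- TRUE
  expect_equal(boundary_restriction_score(pk, mask_half), 2 / 3)

  # relabeling cell ids (same order) leaves the score unchanged
  relabeled <- ring10
  relabeled$cells$id <- relabeled$cells$id + 100L
  relabeled$walls$i <- relabeled$walls$i + 100L
  relabeled$walls$j <- relabeled$walls$j + 100L
  pk2 <- detect_peaks(A, relabeled, 0.5)
  expect_equal(boundary_restriction_score(pk2, mask_half),
               boundary_restriction_score(pk, mask_half))

  empty <- detect_peaks(rep(1, 10), ring10, 0.5)
  expect_error(boundary_restriction_score(empty, mask_all), class = "undefined_score")
})

test_that("peak_spacing returns sorted circular gaps summing to 360 degrees", {
  ring36 <- generate_ring_tissue(36)
  A <- rep(1, 36); A[c(1, 10, 19, 28)] <- 5  # cells at 0, 90, 180, 270 degrees
  pk <- detect_peaks(A, ring36, 0.5)
  sp <- peak_spacing(pk, ring36)
  expect_equal(sp$gaps_deg, rep(90, 4))
  expect_equal(sp$gap_cv, 0)

  A2 <- rep(1, 36); A2[c(1, 13)] <- 5  # 0 and 120 degrees
  sp2 <- peak_spacing(detect_peaks(A2, ring36, 0.5), ring36)
  expect_equal(sort(sp2$gaps_deg), c(120, 240))
  expect_equal(sum(sp2$gaps_deg), 360)

  # randomized placements against brute-force angle sorting
  set.seed(31)
  for (rep in 1:10) {
    idx <- sort(sample(seq(1, 34, by = 3), 5))  # pairwise non-adjacent cells
    A3 <- rep(1, 36); A3[idx] <- 5
    pk3 <- detect_peaks(A3, ring36, 0.5)
    sp3 <- peak_spacing(pk3, ring36)
    ang <- sort((360 * (idx - 1) / 36) %% 360)
    expect_equal(sp3$angles_deg, ang, tolerance = 1e-10)
    expect_equal(sp3$gaps_deg, diff(c(ang, ang[1] + 360)), tolerance = 1e-10)
  }

  one <- detect_peaks(c(5, rep(1, 9)), ring10, 0.5)
  expect_error(peak_spacing(one, ring10), class = "undefined_spacing")
})

test_that("conservation_report measures drift of the V-weighted auxin mass", {
  pair <- two_cell_tissue()
  p <- model_params(c_A = 0, d_A = 0, D = 0.5, T_active = 1)
  tr <- simulate_tissue(pair, p, t_end = 50, init = list(A = c(2, 0), P_tot = 1, X = 0))
  rep <- conservation_report(tr, pair, p)
  expect_false(rep$informational)
  expect_lt(rep$drift, 1e-6)
  # the exchange redistributes but preserves total mass
  fs <- final_state(tr)
  expect_equal(sum(fs$A * pair$cells$volume), 2, tolerance = 1e-6)

  # zero transport: mass exactly constant up to floating error
  p0 <- model_params(c_A = 0, d_A = 0, D = 0, T_active = 0)
  tr0 <- simulate_tissue(pair, p0, t_end = 50, init = list(A = c(2, 1), P_tot = 0, X = 0))
  expect_lt(conservation_report(tr0, pair, p0)$drift, 1e-14)

  # with production on, the report is informational
  p1 <- model_params()
  tr1 <- simulate_tissue(pair, p1, t_end = 10, init = list(A = 1, P_tot = 0, X = 0))
  expect_true(conservation_report(tr1, pair, p1)$informational)

  trz <- simulate_tissue(pair, p1, t_end = 10)  # zero initial mass
  expect_error(conservation_report(trz, pair, p1), class = "undefined_conservation")
})

test_that("peak_to_trough and peak_radii summarize the field", {
  expect_equal(peak_to_trough(c(4, 1, 2)), 4)
  d <- fixture_disc()
  r <- radial_coordinate(d, warn = FALSE)
  A <- rep(1, n_cells(d))
  far <- order(r, decreasing = TRUE)[1:2]
  A[far] <- 5
  pk <- detect_peaks(A, d, 0.5)
  pr <- peak_radii(pk, d)
  expect_equal(sort(pr$r), sort(r[far]))
  expect_equal(pr$iqr, unname(stats::IQR(r[far])))
})
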