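test_that("ring tissues are cycles with uniform geometry", {
  expect_equal(n_cells(ring4), 4L)
  expect_equal(n_walls(ring4), 4L)
  expect_true(all(cell_degrees(ring4) == 2L))

  r3 <- generate_ring_tissue(3, cell_volume = 2, wall_area = 0.5)
  expect_equal(sum(r3$cells$volume), 6)
  expect_true(all(r3$walls$area == 0.5))

  r100 <- generate_ring_tissue(100)
  expect_true(all(cell_degrees(r100) == 2L))
  expect_silent(validate_tissue(r100))

  expect_error(generate_ring_tissue(2), "n_cells")
  expect_error(generate_ring_tissue(5, cell_volume = 0), "positive")
})

test_that("disc generator produces a connected polygonal tiling of the disc", {
  d <- generate_disc_tissue(7, radius = 1, seed = 1, relaxation_steps = 50)
  expect_gte(n_cells(d), 7L)
  expect_true(all(d$walls$area > 0))
  expect_true(all(d$cells$volume > 0))
  expect_silent(validate_tissue(d))

  d200 <- generate_disc_tissue(200, radius = 60, seed = 7)
  expect_lt(abs(sum(d200$cells$volume) - pi * 60^2) / (pi * 60^2), 0.05)
  deg <- cell_degrees(d200)
  interior_mean <- mean(deg[!d200$cells$boundary])
  expect_gte(interior_mean, 5)
  expect_lte(interior_mean, 7)

  expect_error(generate_disc_tissue(5, 10), ">= 7")
  expect_error(generate_disc_tissue(20, -1), "positive")
})

test_that("disc generation is deterministic for fixed arguments", {
  a <- generate_disc_tissue(40, 10, seed = 11, relaxation_steps = 5)
  b <- generate_disc_tissue(40, 10, seed = 11, relaxation_steps = 5)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  write_tissue(a, fa); write_tissue(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)), readBin(fb, "raw", file.size(fb)))
  # a different seed gives a different tiling
  expect_false(identical(a, generate_disc_tissue(40, 10, seed = 12, relaxation_steps = 5)))
})

test_that("wall adjacency is planar-consistent with the polygons", {
  d <- fixture_disc()
  set.seed(1)
  # every wall's two cells' polygons contain a shared edge of matching length
  for (k in sample(nrow(d$walls), 10)) {
    i <- d$walls$i[k]; j <- d$walls$j[k]
    pi_ <- d$polygons[[i]]; pj <- d$polygons[[j]]
    # closest approach between vertex sets of the two polygons must be ~0
    dmin <- min(outer(seq_len(nrow(pi_)), seq_len(nrow(pj)), function(a, b) {
      sqrt((pi_[a, 1] - pj[b, 1])^2 + (pi_[a, 2] - pj[b, 2])^2)
    }))
    expect_lt(dmin, 1e-6)
  }
})

test_that("tissue JSON round-trip is the identity", {
  for (t in list(ring4, fixture_disc())) {
    tf <- tempfile(fileext = ".json")
    write_tissue(t, tf)
    expect_identical(read_tissue(tf), t)
  }
})

test_that("malformed tissue files are rejected with the offending record", {
  tf <- tempfile(fileext = ".json")

  write_tissue(ring4, tf)
  bad <- jsonlite::read_json(tf)
  bad$walls[[1]]$j <- 99
  jsonlite::write_json(bad, tf, auto_unbox = TRUE, digits = NA)
  expect_error(read_tissue(tf), "absent cell id 99", class = "tissue_format_error")

  write_tissue(ring4, tf)
  bad <- jsonlite::read_json(tf)
  bad$cells[[2]]$volume <- 0
  jsonlite::write_json(bad, tf, auto_unbox = TRUE, digits = NA)
  expect_error(read_tissue(tf), "non-positive volume", class = "tissue_format_error")

  write_tissue(ring4, tf)
  bad <- jsonlite::read_json(tf)
  bad$walls[[5]] <- list(i = 2, j = 1, area = 1)  # duplicate of wall {1,2}
  jsonlite::write_json(bad, tf, auto_unbox = TRUE, digits = NA)
  expect_error(read_tissue(tf), "duplicate wall", class = "tissue_format_error")

  write_tissue(ring4, tf)
  bad <- jsonlite::read_json(tf)
  bad$walls[[1]]$area <- NULL
  jsonlite::write_json(bad, tf, auto_unbox = TRUE, digits = NA)
  expect_error(read_tissue(tf), "missing field", class = "tissue_format_error")

  # disconnected graph
  write_tissue(ring4, tf)
  bad <- jsonlite::read_json(tf)
  bad$walls <- bad$walls[1:2]
  jsonlite::write_json(bad, tf, auto_unbox = TRUE, digits = NA)
  expect_error(read_tissue(tf), "not connected", class = "tissue_format_error")
})
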