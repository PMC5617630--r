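#' Cell-network tissue graphs
#'
#' A `tissue_graph` is the static geometry the dynamics run on: a set of
#' polygonal cells with volumes (areas), centroids, and a wall-adjacency
#' graph whose edges carry contact areas (shared-edge lengths). Walls are
#' stored once per unordered cell pair, so contact areas are symmetric by
#' construction.
#'
#' @param cells data.frame with columns `id` (integer), `volume` (> 0),
#'   `x`, `y` (centroid coordinates) and `boundary` (logical tissue-edge flag).
#' @param walls data.frame with columns `i`, `j` (cell ids, `i < j`) and
#'   `area` (> 0), one row per unordered neighbor pair.
#' @param polygons optional list of per-cell vertex matrices (two columns),
#'   used for plotting only; `NULL` for abstract geometries such as rings.
#' @param meta named list of provenance (generator, seed, ...).
#' @return An object of class `tissue_graph`.
#' @seealso [generate_disc_tissue()], [generate_ring_tissue()], [read_tissue()]
#' @export
tissue_graph <- function(cells, walls, polygons = NULL, meta = list()) {
  cells <- as.data.frame(cells)
  walls <- as.data.frame(walls)
  need_c <- c("id", "volume", "x", "y", "boundary")
  if (!all(need_c %in% names(cells))) {
    stop("`cells` must have columns: ", paste(need_c, collapse = ", "))
  }
  need_w <- c("i", "j", "area")
  if (!all(need_w %in% names(walls))) {
    stop("`walls` must have columns: ", paste(need_w, collapse = ", "))
  }
  cells$id <- as.integer(cells$id)
  cells <- cells[need_c]
  walls <- walls[need_w]
  rownames(cells) <- NULL
  rownames(walls) <- NULL
  obj <- structure(
    list(cells = cells, walls = walls,
         polygons = polygons, meta = meta),
    class = "tissue_graph"
  )
  validate_tissue(obj)
}

#' Validate a tissue graph
#'
#' Checks the structural invariants every tissue must satisfy: unique cell
#' ids, positive volumes and wall areas, walls joining two distinct existing
#' cells, no duplicated unordered wall pair, and a connected neighbor graph.
#'
#' @param tissue a `tissue_graph`.
#' @return `tissue`, invisibly usable, after passing all checks; otherwise an
#'   error of class `tissue_format_error` naming the offending record.
#' @export
validate_tissue <- function(tissue) {
  cells <- tissue$cells
  walls <- tissue$walls
  fail <- function(msg) {
    stop(structure(class = c("tissue_format_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (nrow(cells) < 1L) fail("tissue has no cells")
  if (anyDuplicated(cells$id)) {
    fail(sprintf("duplicated cell id: %d", cells$id[duplicated(cells$id)][1L]))
  }
  if (any(!is.finite(cells$volume)) || any(cells$volume <= 0)) {
    bad <- cells$id[which(!is.finite(cells$volume) | cells$volume <= 0)[1L]]
    fail(sprintf("cell %d has non-positive volume", bad))
  }
  if (nrow(walls) > 0L) {
    if (any(!is.finite(walls$area)) || any(walls$area <= 0)) {
      k <- which(!is.finite(walls$area) | walls$area <= 0)[1L]
      fail(sprintf("wall (%d,%d) has non-positive area", walls$i[k], walls$j[k]))
    }
    if (any(walls$i == walls$j)) {
      k <- which(walls$i == walls$j)[1L]
      fail(sprintf("wall (%d,%d) joins a cell to itself", walls$i[k], walls$j[k]))
    }
    known <- c(walls$i, walls$j) %in% cells$id
    if (!all(known)) {
      bad <- c(walls$i, walls$j)[!known][1L]
      fail(sprintf("wall references absent cell id %d", bad))
    }
    key <- paste(pmin(walls$i, walls$j), pmax(walls$i, walls$j))
    if (anyDuplicated(key)) {
      k <- which(duplicated(key))[1L]
      fail(sprintf("duplicate wall entry for pair (%d,%d)", walls$i[k], walls$j[k]))
    }
  }
  if (nrow(cells) > 1L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(walls$i), to = as.character(walls$j)),
      directed = FALSE,
      vertices = data.frame(name = as.character(cells$id))
    )
    if (igraph::components(g)$no != 1L) fail("neighbor graph is not connected")
  }
  tissue
}

#' Number of cells and walls
#' @param tissue a `tissue_graph`.
#' @return integer count.
#' @export
n_cells <- function(tissue) nrow(tissue$cells)

#' @rdname n_cells
#' @export
n_walls <- function(tissue) nrow(tissue$walls)

#' Per-cell wall degree
#' @param tissue a `tissue_graph`.
#' @return integer vector aligned with `tissue$cells`, named by cell id.
#' @export
cell_degrees <- function(tissue) {
  ids <- tissue$cells$id
  deg <- tabulate(match(c(tissue$walls$i, tissue$walls$j), ids), nbins = length(ids))
  stats::setNames(deg, ids)
}

#' @export
print.tissue_graph <- function(x, ...) {
  deg <- cell_degrees(x)
  cat(sprintf("tissue_graph: %d cells, %d walls (generator: %s)\n",
              n_cells(x), n_walls(x),
              if (is.null(x$meta$generator)) "unknown" else x$meta$generator))
  cat(sprintf("  total volume %.4g, mean degree %.2f, %d boundary cells\n",
              sum(x$cells$volume), mean(deg), sum(x$cells$boundary)))
  invisible(x)
}

#' Generate a periodic ring tissue
#'
#' A cycle of identical cells: the simplest geometry on which the transport
#' dynamics are well defined. Every cell has exactly two neighbors, uniform
#' volume and uniform wall area. Centroids are placed on a circle with unit
#' arc spacing so radial coordinates are defined (and equal for all cells).
#' There is no tissue edge, so no cell is flagged as boundary.
#'
#' @param n_cells number of cells (>= 3).
#' @param cell_volume volume of every cell (> 0).
#' @param wall_area contact area of every wall (> 0).
#' @return a `tissue_graph`.
#' @examples
#' ring <- generate_ring_tissue(12)
#' cell_degrees(ring)
#' @export
generate_ring_tissue <- function(n_cells, cell_volume = 1, wall_area = 1) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 3L) {
    stop("`n_cells` must be a single integer >= 3")
  }
  if (cell_volume <= 0 || wall_area <= 0) {
    stop("`cell_volume` and `wall_area` must be positive")
  }
  n <- as.integer(n_cells)
  rad <- n / (2 * pi)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cells <- data.frame(id = seq_len(n), volume = cell_volume,
                      x = rad * cos(th), y = rad * sin(th), boundary = FALSE)
  walls <- data.frame(i = seq_len(n), j = c(seq_len(n)[-1L], 1L), area = wall_area)
  swap <- walls$i > walls$j
  tmp <- walls$i[swap]; walls$i[swap] <- walls$j[swap]; walls$j[swap] <- tmp
  tissue_graph(cells, walls, polygons = NULL,
               meta = list(generator = "ring", n_cells = n,
                           cell_volume = cell_volume, wall_area = wall_area))
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an irregular polygonal disc tissue
#'
#' Builds a roughly disc-shaped sheet of polygonal cells by seeded random
#' point placement, optional centroidal (Lloyd) relaxation, and Voronoi
#' tessellation clipped to the disc. Cell volumes are polygon areas, wall
#' areas are shared-edge lengths, and cells touching the disc rim are flagged
#' as boundary cells. The construction is deterministic for fixed arguments.
#'
#' The mild geometric irregularity of the tiling is what breaks symmetry in
#' the transport dynamics, letting patterns emerge from exactly-zero initial
#' conditions without injected noise.
#'
#' @param n_cells number of cells (>= 7).
#' @param radius disc radius, in the model's length units (> 0).
#' @param seed integer RNG seed for point placement.
#' @param relaxation_steps number of Lloyd iterations (0 = raw Voronoi of the
#'   random points; ~30 gives a visually regular but still irregular tiling).
#' @param ngon number of segments approximating the disc rim.
#' @return a `tissue_graph` with polygons attached.
#' @examples
#' disc <- generate_disc_tissue(40, radius = 10, seed = 1, relaxation_steps = 10)
#' disc
#' @export
generate_disc_tissue <- function(n_cells, radius, seed = 1L,
                                 relaxation_steps = 30L, ngon = 64L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 7L) {
    stop("`n_cells` must be a single integer >= 7")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("`radius` must be a single positive number")
  }
  if (relaxation_steps < 0) stop("`relaxation_steps` must be non-negative")
  n <- as.integer(n_cells)

  pts <- with_seed(seed, {
    th <- runif(n, 0, 2 * pi)
    rr <- radius * sqrt(runif(n))
    cbind(rr * cos(th), rr * sin(th))
  })
  disc <- regular_polygon(radius, as.integer(ngon))
  dlabs <- rep(0L, nrow(disc))

  for (it in seq_len(relaxation_steps)) {
    for (i in seq_len(n)) {
      cell <- voronoi_cell(i, pts, disc, dlabs)
      if (nrow(cell$verts) >= 3L) pts[i, ] <- poly_centroid(cell$verts)
    }
  }

  polys <- vector("list", n)
  labs <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- voronoi_cell(i, pts, disc, dlabs)
    polys[[i]] <- cell$verts
    labs[[i]] <- cell$labs
  }

  vol <- vapply(polys, poly_area, numeric(1))
  cent <- t(vapply(polys, poly_centroid, numeric(2)))
  eps <- 1e-9 * radius

  # collect directed wall lengths, then symmetrize over the two measurements
  wl <- new.env(parent = emptyenv())
  boundary <- logical(n)
  for (i in seq_len(n)) {
    v <- polys[[i]]
    m <- nrow(v)
    if (m < 3L) next
    v2 <- v[c(2:m, 1L), , drop = FALSE]
    len <- sqrt(rowSums((v2 - v)^2))
    lb <- labs[[i]]
    boundary[i] <- any(lb == 0L & len > eps)
    for (j in unique(lb[lb > 0L])) {
      lij <- sum(len[lb == j])
      if (lij <= eps) next
      key <- paste(min(i, j), max(i, j))
      prev <- if (!is.null(wl[[key]])) wl[[key]] else c(0, 0)
      wl[[key]] <- prev + c(lij, 1)
    }
  }
  keys <- ls(wl)
  pair <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  vals <- vapply(keys, function(k) {
    v <- wl[[k]]
    v[1] / v[2]
  }, numeric(1))
  walls <- data.frame(i = as.integer(pair[, 1]), j = as.integer(pair[, 2]),
                      area = unname(vals))
  walls <- walls[order(walls$i, walls$j), , drop = FALSE]
  rownames(walls) <- NULL

  cells <- data.frame(id = seq_len(n), volume = vol,
                      x = cent[, 1], y = cent[, 2], boundary = boundary)
  tissue_graph(cells, walls, polygons = polys,
               meta = list(generator = "disc", n_cells = n, radius = radius,
                           seed = as.integer(seed),
                           relaxation_steps = as.integer(relaxation_steps),
                           ngon = as.integer(ngon)))
}

regular_polygon <- function(radius, ngon) {
  th <- 2 * pi * (seq_len(ngon) - 1L) / ngon
  cbind(radius * cos(th), radius * sin(th))
}

poly_area <- function(v) {
  m <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- x[c(2:m, 1L)]; y2 <- y[c(2:m, 1L)]
  sum(x * y2 - x2 * y) / 2
}

poly_centroid <- function(v) {
  m <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- x[c(2:m, 1L)]; y2 <- y[c(2:m, 1L)]
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Clip a convex polygon (counter-clockwise) by the half-plane of points at
# least as close to p as to q. Each edge carries an integer label (neighbor
# id, or 0 for the disc rim); new edges created along the bisector get
# `lab_new`. Labels are stored per edge leaving each vertex.
clip_halfplane <- function(verts, labs, px, py, qx, qy, lab_new) {
  m <- nrow(verts)
  nx <- qx - px; ny <- qy - py
  s <- (verts[, 1] - (px + qx) / 2) * nx + (verts[, 2] - (py + qy) / 2) * ny
  ox <- numeric(m + 2L); oy <- numeric(m + 2L); ol <- integer(m + 2L)
  cnt <- 0L
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    sk <- s[k]; s2 <- s[k2]
    if (sk <= 0) {
      cnt <- cnt + 1L
      ox[cnt] <- verts[k, 1]; oy[cnt] <- verts[k, 2]; ol[cnt] <- labs[k]
      if (s2 > 0) {
        t <- sk / (sk - s2)
        cnt <- cnt + 1L
        ox[cnt] <- verts[k, 1] + t * (verts[k2, 1] - verts[k, 1])
        oy[cnt] <- verts[k, 2] + t * (verts[k2, 2] - verts[k, 2])
        ol[cnt] <- lab_new
      }
    } else if (s2 <= 0) {
      t <- sk / (sk - s2)
      cnt <- cnt + 1L
      ox[cnt] <- verts[k, 1] + t * (verts[k2, 1] - verts[k, 1])
      oy[cnt] <- verts[k, 2] + t * (verts[k2, 2] - verts[k, 2])
      ol[cnt] <- labs[k]
    }
  }
  list(verts = cbind(ox[seq_len(cnt)], oy[seq_len(cnt)]), labs = ol[seq_len(cnt)])
}

# Voronoi cell of seed i within the clip polygon, by successive half-plane
# clipping against other seeds in order of distance. A seed at distance d can
# only cut the current cell if d/2 is below the farthest vertex distance, so
# the loop terminates exactly once d^2 >= 4 * max vertex distance^2.
voronoi_cell <- function(i, pts, clip_poly, clip_labs) {
  d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  verts <- clip_poly
  labs <- clip_labs
  for (j in ord) {
    r2max <- max((verts[, 1] - pts[i, 1])^2 + (verts[, 2] - pts[i, 2])^2)
    if (d2[j] >= 4 * r2max) break
    res <- clip_halfplane(verts, labs, pts[i, 1], pts[i, 2], pts[j, 1], pts[j, 2], j)
    verts <- res$verts
    labs <- res$labs
    if (nrow(verts) < 3L) break
  }
  list(verts = verts, labs = labs)
}
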