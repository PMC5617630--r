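#' Read and write tissue JSON files
#'
#' Tissues are serialized to a plain JSON schema: `"cells"` is an array of
#' `{"id", "volume", "centroid": [x, y], "boundary"}` records, `"walls"` an
#' array of `{"i", "j", "area"}` records (one per unordered pair), `"meta"`
#' carries generator provenance, and `"polygons"` (optional) holds per-cell
#' vertex rings for plotting. Numbers are written at full precision so that
#' write-then-read is the identity on a `tissue_graph`.
#'
#' @param tissue a `tissue_graph`.
#' @param path file path.
#' @return `read_tissue` returns a validated `tissue_graph`; `write_tissue`
#'   returns `path` invisibly. Malformed files (schema violations, dangling
#'   cell references, duplicate or self walls, non-positive volumes or areas)
#'   raise an error of class `tissue_format_error` naming the offending
#'   record.
#' @examples
#' tf <- tempfile(fileext = ".json")
#' write_tissue(generate_ring_tissue(4), tf)
#' ring <- read_tissue(tf)
#' @export
write_tissue <- function(tissue, path) {
  stopifnot(inherits(tissue, "tissue_graph"))
  cells <- lapply(seq_len(nrow(tissue$cells)), function(k) {
    row <- tissue$cells[k, ]
    list(id = row$id, volume = row$volume,
         centroid = c(row$x, row$y), boundary = row$boundary)
  })
  walls <- lapply(seq_len(nrow(tissue$walls)), function(k) {
    row <- tissue$walls[k, ]
    list(i = row$i, j = row$j, area = row$area)
  })
  obj <- list(cells = cells, walls = walls, meta = tissue$meta)
  if (!is.null(tissue$polygons)) {
    obj$polygons <- lapply(tissue$polygons, function(v) {
      lapply(seq_len(nrow(v)), function(k) c(v[k, 1], v[k, 2]))
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(path) {
  fail <- function(msg) {
    stop(structure(class = c("tissue_format_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (!file.exists(path)) fail(sprintf("tissue file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) fail(sprintf("not valid JSON: %s", conditionMessage(e))))
  if (is.null(obj$cells) || length(obj$cells) == 0L) fail("no \"cells\" array")
  getf <- function(rec, field, recname, k) {
    if (is.null(rec[[field]])) {
      fail(sprintf("%s record %d is missing field \"%s\"", recname, k, field))
    }
    rec[[field]]
  }
  cells <- do.call(rbind, lapply(seq_along(obj$cells), function(k) {
    rec <- obj$cells[[k]]
    ctr <- getf(rec, "centroid", "cell", k)
    if (length(ctr) != 2L) fail(sprintf("cell record %d: centroid must be [x, y]", k))
    data.frame(id = as.integer(getf(rec, "id", "cell", k)),
               volume = as.numeric(getf(rec, "volume", "cell", k)),
               x = as.numeric(ctr[[1]]), y = as.numeric(ctr[[2]]),
               boundary = isTRUE(rec$boundary))
  }))
  walls <- if (length(obj$walls) == 0L) {
    data.frame(i = integer(0), j = integer(0), area = numeric(0))
  } else {
    do.call(rbind, lapply(seq_along(obj$walls), function(k) {
      rec <- obj$walls[[k]]
      data.frame(i = as.integer(getf(rec, "i", "wall", k)),
                 j = as.integer(getf(rec, "j", "wall", k)),
                 area = as.numeric(getf(rec, "area", "wall", k)))
    }))
  }
  polygons <- NULL
  if (!is.null(obj$polygons)) {
    polygons <- lapply(obj$polygons, function(ring) {
      do.call(rbind, lapply(ring, function(v) c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    })
  }
  int_keys <- c("n_cells", "seed", "relaxation_steps", "ngon")
  meta <- obj$meta
  for (nm in names(meta)) {
    v <- if (length(meta[[nm]]) == 1L) meta[[nm]][[1]] else unlist(meta[[nm]])
    if (is.numeric(v)) {
      v <- if (nm %in% int_keys) as.integer(v) else as.numeric(v)
    }
    meta[[nm]] <- v
  }
  out <- tryCatch(
    tissue_graph(cells, walls, polygons = polygons, meta = meta),
    error = function(e) fail(conditionMessage(e))
  )
  out
}
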