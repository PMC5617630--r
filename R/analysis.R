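#' Detect auxin peaks on a tissue
#'
#' A peak is a cell whose auxin level strictly exceeds that of every wall
#' neighbor and also exceeds `rel_threshold` times the global maximum.
#' Exact ties with a neighbor disqualify both cells, so a perfectly
#' homogeneous field has no peaks. Peaks are single cells; two peaks are
#' never wall-adjacent (each would have to beat the other).
#'
#' @param state a `system_state`, or a numeric per-cell auxin vector aligned
#'   with `tissue$cells`.
#' @param tissue a `tissue_graph`.
#' @param rel_threshold fraction of the global maximum a peak must exceed,
#'   in (0, 1]. The default 0.5 separates genuine maxima from ripples in
#'   near-homogeneous fields.
#' @return object of class `peak_set`: list with `peak_cells` (cell ids),
#'   `peak_idx` (positions in `tissue$cells`), `peak_values`, and
#'   `threshold_used` (the absolute threshold applied).
#' @export
detect_peaks <- function(state, tissue, rel_threshold = 0.5) {
  if (!inherits(tissue, "tissue_graph") || n_cells(tissue) == 0L) {
    stop("`tissue` must be a non-empty tissue_graph")
  }
  if (!is.numeric(rel_threshold) || rel_threshold <= 0 || rel_threshold > 1) {
    stop("`rel_threshold` must lie in (0, 1]")
  }
  A <- if (is.numeric(state)) state else state$A
  if (length(A) != n_cells(tissue)) stop("state/tissue size mismatch")
  ids <- tissue$cells$id
  ef <- match(c(tissue$walls$i, tissue$walls$j), ids)
  et <- match(c(tissue$walls$j, tissue$walls$i), ids)
  thr <- rel_threshold * max(A)
  # a cell fails if any neighbor's A is >= its own
  beaten <- rep(FALSE, length(A))
  bad <- A[et] >= A[ef]
  beaten[unique(ef[bad])] <- TRUE
  idx <- which(!beaten & A > thr)
  structure(
    list(peak_cells = ids[idx], peak_idx = idx, peak_values = unname(A[idx]),
         threshold_used = thr),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks (threshold %.4g)\n",
              length(x$peak_cells), x$threshold_used))
  if (length(x$peak_cells)) {
    cat("  cells:", paste(x$peak_cells, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fraction of peaks inside the boundary annulus
#'
#' Scores how strongly organ-initiation sites are confined to the
#' dorsoventral boundary: the fraction of detected auxin peaks that fall in
#' the mask of boundary cells. A score of 1 means every peak lies in the
#' annulus.
#'
#' @param peaks a `peak_set`.
#' @param mask per-cell logical vector (e.g. from [boundary_mask()]),
#'   aligned with the tissue the peaks were detected on.
#' @return a number in \[0, 1\]. An empty peak set raises an error of class
#'   `undefined_score` (no peaks is not the same as no peaks in the
#'   boundary).
#' @export
boundary_restriction_score <- function(peaks, mask) {
  stopifnot(inherits(peaks, "peak_set"), is.logical(mask))
  if (length(peaks$peak_idx) == 0L) {
    stop(structure(class = c("undefined_score", "error", "condition"),
                   list(message = "no peaks: boundary-restriction score is undefined",
                        call = sys.call(-1))))
  }
  mean(mask[peaks$peak_idx])
}

#' Angular positions and spacing of peaks
#'
#' Polar angles of the peak cells about the tissue center (volume-weighted
#' centroid), sorted, with the circular gaps between consecutive peaks and
#' their coefficient of variation. Equally spaced peaks give CV = 0; the CV
#' rises as the arrangement departs from a regular (phyllotaxis-like) ring.
#'
#' @param peaks a `peak_set` with at least 2 peaks.
#' @param tissue the `tissue_graph` the peaks were detected on.
#' @return list with `angles_deg` (sorted, in \[0, 360)), `gaps_deg`
#'   (circular gaps, summing to 360) and `gap_cv`.
#' @export
peak_spacing <- function(peaks, tissue) {
  stopifnot(inherits(peaks, "peak_set"), inherits(tissue, "tissue_graph"))
  if (length(peaks$peak_idx) < 2L) {
    stop(structure(class = c("undefined_spacing", "error", "condition"),
                   list(message = "need at least 2 peaks for spacing",
                        call = sys.call(-1))))
  }
  w <- tissue$cells$volume
  cx <- sum(w * tissue$cells$x) / sum(w)
  cy <- sum(w * tissue$cells$y) / sum(w)
  ang <- atan2(tissue$cells$y[peaks$peak_idx] - cy,
               tissue$cells$x[peaks$peak_idx] - cx) * 180 / pi
  # round before wrapping so a tiny negative angle maps to 0, not ~360
  ang <- sort(round(ang, 9) %% 360)
  gaps <- diff(c(ang, ang[1L] + 360))
  list(angles_deg = ang, gaps_deg = gaps,
       gap_cv = stats::sd(gaps) / mean(gaps))
}

#' Mass-conservation diagnostic for a trajectory
#'
#' The transport terms of the auxin equation are antisymmetric in
#' volume-weighted form, so with production and degradation switched off
#' (`c_A = d_A = 0`) the total auxin mass \eqn{M(t) = \sum_i V_i A_i(t)} is
#' an exact invariant; any drift measures solver error. With production or
#' degradation active the report is still computed but flagged
#' informational.
#'
#' @param trajectory a `tissue_trajectory`.
#' @param tissue the `tissue_graph` it was run on.
#' @param params the [model_params()] used.
#' @return list with `drift` (max over time of |M(t) - M(0)| / M(0)),
#'   `M0`, and `informational` (`TRUE` unless `c_A = d_A = 0`). `M(0) = 0`
#'   raises an error of class `undefined_conservation`.
#' @export
conservation_report <- function(trajectory, tissue, params) {
  V <- tissue$cells$volume
  M <- as.numeric(trajectory$A %*% V)
  if (M[1L] == 0) {
    stop(structure(class = c("undefined_conservation", "error", "condition"),
                   list(message = "initial auxin mass is zero; relative drift undefined",
                        call = sys.call(-1))))
  }
  list(drift = max(abs(M - M[1L])) / abs(M[1L]),
       M0 = M[1L],
       informational = !(params$c_A == 0 && params$d_A == 0))
}

#' Peak-to-trough ratio of the auxin field
#'
#' `max(A) / min(A)` over cells at one state; the package's operational
#' criterion for spontaneous patterning is a ratio above 2 at steady state.
#'
#' @param state a `system_state` or numeric auxin vector.
#' @return a single number (`Inf` if the minimum is 0).
#' @export
peak_to_trough <- function(state) {
  A <- if (is.numeric(state)) state else state$A
  max(A) / min(A)
}

#' Radial statistics of a peak set
#'
#' Radial coordinates of peak cells about the tissue center, and their
#' inter-quartile range — the spread statistic used to contrast boundary
#' restricted and unrestricted patterning.
#'
#' @param peaks a `peak_set`.
#' @param tissue the `tissue_graph` the peaks were detected on.
#' @return list with `r` (per-peak radius) and `iqr`.
#' @export
peak_radii <- function(peaks, tissue) {
  r <- radial_coordinate(tissue, warn = FALSE)[peaks$peak_idx]
  list(r = r, iqr = unname(stats::IQR(r)))
}
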