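# 8-connected component labelling of a logical matrix by iterative minimum-
# label propagation (vectorised over the grid; iterations scale with
# component diameter, which is small for compact vortical regions)
label_components8 <- function(B) {
  B[is.na(B)] <- FALSE
  nx <- nrow(B); ny <- ncol(B)
  lab <- matrix(seq_len(nx * ny), nx, ny)
  lab[!B] <- NA_integer_
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  shift2 <- function(M, s) {
    if (s[1] == 1) M <- rbind(NA, M[-nx, , drop = FALSE])
    if (s[1] == -1) M <- rbind(M[-1, , drop = FALSE], NA)
    if (s[2] == 1) M <- cbind(NA, M[, -ny, drop = FALSE])
    if (s[2] == -1) M <- cbind(M[, -1, drop = FALSE], NA)
    M
  }
  repeat {
    new <- lab
    for (s in shifts) {
      nb <- shift2(lab, s)
      upd <- !is.na(new) & !is.na(nb) & nb < new
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- matrix(0L, nx, ny)
  out[!is.na(lab)] <- match(lab[!is.na(lab)], ids)
  out
}

# dilate a logical matrix by one cell with 8-connectivity
dilate8 <- function(B) {
  nx <- nrow(B); ny <- ncol(B)
  B[is.na(B)] <- FALSE
  out <- B
  out[-1, ] <- out[-1, ] | B[-nx, ]
  out[-nx, ] <- out[-nx, ] | B[-1, ]
  out[, -1] <- out[, -1] | B[, -ny]
  out[, -ny] <- out[, -ny] | B[, -1]
  out[-1, -1] <- out[-1, -1] | B[-nx, -ny]
  out[-1, -ny] <- out[-1, -ny] | B[-nx, -1]
  out[-nx, -1] <- out[-nx, -1] | B[-1, -ny]
  out[-nx, -ny] <- out[-nx, -ny] | B[-1, -1]
  out
}

#' Extract vortex structures from a thresholded Q field
#'
#' Identifies the 8-connected components of \code{Q >= threshold} over
#' unmasked nodes and computes their properties: Q-weighted centroid, peak
#' Q, area (node count x spacing^2), circulation (vorticity integrated over
#' the component's nodes) and rotation sign. Structures are returned sorted
#' by decreasing circulation magnitude. Above-threshold nodes are
#' partitioned: every such node belongs to exactly one structure.
#'
#' @param q a \code{\link{scalar_field}} of Q (1/s^2).
#' @param omega the matching \code{\link{scalar_field}} of spanwise
#'   vorticity (1/s).
#' @param threshold Q threshold in 1/s^2 (> 0); see
#'   \code{\link{default_threshold}}.
#' @param min_nodes drop components smaller than this many nodes.
#' @return A list of \code{vortex_structure} objects (possibly empty), each
#'   with \code{nodes} (2-column matrix of grid indices), \code{centroid}
#'   (x, y in metres), \code{peak_q}, \code{area}, \code{circulation},
#'   \code{sign}, \code{phase}, and placeholders \code{attached},
#'   \code{label}.
#' @export
extract_structures <- function(q, omega, threshold, min_nodes = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  h <- q$x[2] - q$x[1]
  B <- !q$mask & !is.na(q$values) & q$values >= threshold
  if (!any(B)) return(list())
  lab <- label_components8(B)
  out <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_nodes) next
    qv <- q$values[idx]
    ov <- omega$values[idx]
    wsum <- sum(qv)
    cen <- c(x = sum(q$x[idx[, 1]] * qv) / wsum,
             y = sum(q$y[idx[, 2]] * qv) / wsum)
    circ <- sum(ov, na.rm = TRUE) * h^2
    out[[length(out) + 1L]] <- structure(list(
      nodes = idx, node_xy = cbind(x = q$x[idx[, 1]], y = q$y[idx[, 2]]),
      centroid = cen, peak_q = max(qv),
      area = nrow(idx) * h^2, circulation = circ,
      sign = sign(circ), phase = q$phase,
      attached = NA, label = NA_character_),
      class = "vortex_structure")
  }
  out[order(-vapply(out, function(s) abs(s$circulation), numeric(1)))]
}

#' @export
print.vortex_structure <- function(x, ...) {
  cat(sprintf(
    "<vortex_structure t/T=%.3f: centroid (%.4f, %.4f) m, Gamma = %.3e m^2/s, area %.2e m^2, peak Q %.3g>\n",
    x$phase, x$centroid[1], x$centroid[2], x$circulation, x$area, x$peak_q))
  invisible(x)
}

#' Default Q threshold from the global field maximum
#'
#' A fixed fraction (default 1\%) of the maximum Q over the supplied field
#' or list of fields (the whole phase series, not a single frame), floored
#' at a configurable absolute minimum. Thresholding slightly above zero
#' suppresses experimental noise in the identified regions.
#'
#' @param q a \code{\link{scalar_field}} or list of them.
#' @param fraction fraction of the global maximum.
#' @param floor_abs absolute lower bound for the returned threshold.
#' @return Threshold in 1/s^2.
#' @export
default_threshold <- function(q, fraction = 0.01, floor_abs = 0) {
  vals <- if (inherits(q, "scalar_field")) q$values
          else unlist(lapply(q, function(f) f$values))
  m <- suppressWarnings(max(vals, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) stop("field has no positive Q values")
  max(fraction * m, floor_abs)
}

#' Leading-edge-vortex attachment test
#'
#' A structure counts as attached while no gap separates its lowest-contour
#' region from the fin: attached iff the minimum grid (Chebyshev) distance
#' between the structure's nodes and the fin-mask nodes is at most one
#' cell, i.e. the structure touches the mask or its immediate neighbours.
#'
#' @param s a \code{vortex_structure}.
#' @param fin_mask logical matrix congruent with the structure's source
#'   grid; TRUE = fin.
#' @return \code{TRUE} if attached.
#' @export
is_attached <- function(s, fin_mask) {
  if (!any(fin_mask, na.rm = TRUE)) stop("fin mask is empty: no fin present")
  halo <- dilate8(fin_mask)
  any(halo[s$nodes])
}

#' Track vortex structures across phases
#'
#' Greedy nearest-predicted-centroid matching between consecutive phases:
#' each active track predicts its next centroid as the previous centroid
#' advanced by \code{advection_guess * dt}, and structures of the same
#' rotation sign within the gating radius are assigned in order of
#' increasing distance (ties by largest circulation magnitude). Unmatched
#' structures start new tracks; a track that misses a phase ends.
#'
#' @param structs list (one element per phase, in phase order) of structure
#'   lists as returned by \code{\link{extract_structures}}.
#' @param phases the t/T value of each element of \code{structs}.
#' @param advection_guess \code{c(Ux, Uy)} m/s used for prediction
#'   (typically the freestream).
#' @param period cycle period (s).
#' @param gate gating radius in metres; default
#'   \code{4 * |advection_guess| * dt} (at least 5 mm).
#' @return A list of \code{vortex_track} objects, each with \code{phases},
#'   \code{structures}, \code{centroids} (n x 2), \code{sign}.
#' @export
track_structures <- function(structs, phases, advection_guess = c(0, 0),
                             period = 1, gate = NULL) {
  dt <- mean(diff(phases)) * period
  if (is.null(gate))
    gate <- max(4 * sqrt(sum(advection_guess^2)) * dt, 5e-3)
  tracks <- list()
  active <- integer(0)          # indices into tracks matched at previous phase
  for (k in seq_along(structs)) {
    ss <- structs[[k]]
    matched_s <- rep(FALSE, length(ss))
    matched_t <- rep(FALSE, length(active))
    if (length(active) && length(ss)) {
      pred <- t(vapply(tracks[active], function(tr) {
        tr$centroids[nrow(tr$centroids), ] + advection_guess * dt
      }, numeric(2)))
      cand <- expand.grid(ti = seq_along(active), si = seq_along(ss))
      cand$d <- sqrt((pred[cand$ti, 1] -
                        vapply(ss, function(s) s$centroid[1], numeric(1))[cand$si])^2 +
                     (pred[cand$ti, 2] -
                        vapply(ss, function(s) s$centroid[2], numeric(1))[cand$si])^2)
      cand$samesign <- vapply(tracks[active], `[[`, numeric(1), "sign")[cand$ti] ==
        vapply(ss, `[[`, numeric(1), "sign")[cand$si]
      cand$circ <- vapply(ss, function(s) abs(s$circulation), numeric(1))[cand$si]
      cand <- cand[cand$samesign & cand$d <= gate, , drop = FALSE]
      cand <- cand[order(cand$d, -cand$circ), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        ti <- cand$ti[r]; si <- cand$si[r]
        if (matched_t[ti] || matched_s[si]) next
        matched_t[ti] <- TRUE; matched_s[si] <- TRUE
        tr <- tracks[[active[ti]]]
        tr$phases <- c(tr$phases, phases[k])
        tr$structures <- c(tr$structures, list(ss[[si]]))
        tr$centroids <- rbind(tr$centroids, ss[[si]]$centroid)
        tracks[[active[ti]]] <- tr
      }
    }
    for (si in which(!matched_s)) {
      tracks[[length(tracks) + 1L]] <- structure(list(
        phases = phases[k], structures = list(ss[[si]]),
        centroids = matrix(ss[[si]]$centroid, 1, 2,
                           dimnames = list(NULL, c("x", "y"))),
        sign = ss[[si]]$sign), class = "vortex_track")
    }
    active <- which(vapply(tracks, function(tr)
      length(tr$phases) && abs(tr$phases[length(tr$phases)] - phases[k]) < 1e-9,
      logical(1)))
  }
  tracks
}

#' @export
print.vortex_track <- function(x, ...) {
  cat(sprintf("<vortex_track: %d phases [%.2f..%.2f], sign %+d, |Gamma| last %.3e>\n",
              length(x$phases), min(x$phases), max(x$phases), x$sign,
              abs(x$structures[[length(x$structures)]]$circulation)))
  invisible(x)
}

#' Estimate the shedding time of a tracked vortex
#'
#' The vortex is considered fed by the trailing-edge shear layer while its
#' structure lies within \code{gap_cells} of a disk of radius
#' \code{te_radius_cells} around the trailing-edge position. The shedding
#' time is the midpoint of the phase interval between the last connected
#' phase and the first subsequent disconnected phase, reported with a
#' half-bin uncertainty (the temporal resolution of the dataset).
#'
#' @param track a \code{vortex_track}.
#' @param te_pos matrix of TE positions (x, y in metres), one row per track
#'   phase (rows are matched to \code{track$phases} by the caller or via
#'   \code{te_phases}).
#' @param spacing grid spacing (m).
#' @param te_phases optional phases corresponding to the rows of
#'   \code{te_pos}; defaults to \code{track$phases}.
#' @param gap_cells gap tolerance in cells (a gap wider than this breaks
#'   the connection).
#' @param te_radius_cells radius of the TE shear-layer disk, cells.
#' @return A list with \code{shed_phase} (t/T, or \code{NA} if the track
#'   never touches the TE region or never detaches within the track) and
#'   \code{uncertainty} (half the phase bin).
#' @export
shedding_phase <- function(track, te_pos, spacing, te_phases = NULL,
                           gap_cells = 1, te_radius_cells = 3) {
  if (is.null(te_phases)) te_phases <- track$phases
  reach <- (te_radius_cells + gap_cells) * spacing + spacing / 2
  connected <- vapply(seq_along(track$phases), function(i) {
    te <- te_pos[which.min(abs(te_phases - track$phases[i]))[1], ]
    s <- track$structures[[i]]
    d2 <- (s$node_xy[, 1] - te[1])^2 + (s$node_xy[, 2] - te[2])^2
    min(d2) <= reach^2
  }, logical(1))
  if (!any(connected)) return(list(shed_phase = NA_real_,
                                   uncertainty = NA_real_))
  last_conn <- max(which(connected))
  if (last_conn == length(track$phases))
    return(list(shed_phase = NA_real_, uncertainty = NA_real_))
  p_a <- track$phases[last_conn]
  p_b <- track$phases[last_conn + 1]
  list(shed_phase = (p_a + p_b) / 2, uncertainty = (p_b - p_a) / 2)
}

#' Fit a straight trajectory to a track
#'
#' Total-least-squares (principal component) line through the track's
#' centroids; returns its inclination relative to the +x (downstream) axis
#' in (-90, 90] degrees and the fraction of centroid variance explained
#' (r^2 of the orthogonal fit).
#'
#' @param track a \code{vortex_track} with at least 3 centroids.
#' @return A list with \code{angle} (degrees) and \code{r_squared}.
#' @export
trajectory_fit <- function(track) {
  P <- track$centroids
  if (nrow(P) < 3) stop("trajectory_fit needs at least 3 centroids")
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)
  dir <- sv$v[, 1]
  ang <- atan2(dir[2], dir[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  lam <- sv$d^2
  list(angle = ang, r_squared = lam[1] / sum(lam))
}

#' Per-vortex circulation from the vorticity field
#'
#' The Q-defined structure marks a vortex's rotation-dominated core, which
#' for a Gaussian-core vortex holds only about 70\% of its circulation; the
#' physically meaningful per-vortex circulation integrates the spanwise
#' vorticity over the connected region where the sign-matching vorticity
#' magnitude exceeds \code{omega_threshold} (the same 1 1/s floor used for
#' the circulation budget) around the structure.
#'
#' @param s a \code{vortex_structure}.
#' @param omega the \code{\link{scalar_field}} of spanwise vorticity for the
#'   same phase.
#' @param omega_threshold vorticity magnitude threshold, 1/s.
#' @return Signed circulation in m^2/s.
#' @export
vortex_circulation <- function(s, omega, omega_threshold = 1) {
  h <- omega$x[2] - omega$x[1]
  B <- !omega$mask & !is.na(omega$values) &
    s$sign * omega$values >= omega_threshold
  lab <- label_components8(B)
  ids <- unique(lab[s$nodes])
  ids <- ids[ids > 0]
  if (!length(ids)) return(0)
  sum(omega$values[lab %in% ids]) * h^2
}

#' Derived structures for every phase of a series
#'
#' Convenience wrapper: computes vorticity and Q for each phase, picks the
#' global 1\%-of-maximum threshold (unless given), and extracts structures
#' per phase.
#'
#' @param series a \code{\link{phase_series}}.
#' @param threshold Q threshold; \code{NULL} for
#'   \code{\link{default_threshold}} over the whole series.
#' @param fraction threshold fraction when auto-thresholding.
#' @param min_nodes passed to \code{\link{extract_structures}}.
#' @return A list with \code{structures} (per phase), \code{q}, \code{omega}
#'   (per-phase scalar fields), and \code{threshold}.
#' @export
structures_by_phase <- function(series, threshold = NULL, fraction = 0.01,
                                min_nodes = 1) {
  np <- length(series$phases)
  qs <- lapply(seq_len(np), function(k) q_criterion_2d(series, k))
  oms <- lapply(seq_len(np), function(k) vorticity_z(series, k))
  if (is.null(threshold)) threshold <- default_threshold(qs, fraction)
  st <- lapply(seq_len(np), function(k)
    extract_structures(qs[[k]], oms[[k]], threshold, min_nodes = min_nodes))
  list(structures = st, q = qs, omega = oms, threshold = threshold)
}
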