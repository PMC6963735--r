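# one-directional finite-difference gradient of an [nx, ny] matrix holding
# NA at masked nodes: centred differences in the interior, one-sided where a
# neighbour is missing (domain edge or mask edge), NA where both are
shift_pos <- function(M, along) {
  n <- dim(M)[along]
  if (along == 1) rbind(M[-1, , drop = FALSE], NA) else
    cbind(M[, -1, drop = FALSE], NA)
}
shift_neg <- function(M, along) {
  n <- dim(M)[along]
  if (along == 1) rbind(NA, M[-n, , drop = FALSE]) else
    cbind(NA, M[, -n, drop = FALSE])
}

fd_gradient <- function(M, h, along) {
  Mp <- shift_pos(M, along)
  Mm <- shift_neg(M, along)
  g <- (Mp - Mm) / (2 * h)
  fwd <- is.na(Mm) & !is.na(Mp)
  bwd <- is.na(Mp) & !is.na(Mm)
  g[fwd] <- (Mp[fwd] - M[fwd]) / h
  g[bwd] <- (M[bwd] - Mm[bwd]) / h
  g[is.na(M)] <- NA_real_
  g
}

check_field_grid <- function(series) {
  if (length(series$x) < 3 || length(series$y) < 3)
    stop("grid too small for finite differences (need >= 3 nodes per axis)")
}

#' Spanwise vorticity of one phase
#'
#' \code{omega_z = dv/dx - du/dy} by centred finite differences in the
#' interior with one-sided fallback at domain boundaries and mask edges;
#' masked nodes propagate the mask. The centred scheme is exact for linear
#' velocity fields.
#'
#' @param series a \code{\link{phase_series}} with uniform grid spacing.
#' @param phase_index which phase (1-based index into \code{series$phases}).
#' @return A \code{\link{scalar_field}} in 1/s.
#' @export
vorticity_z <- function(series, phase_index) {
  check_field_grid(series)
  h <- series$spacing
  u <- series$u[, , phase_index]
  v <- series$v[, , phase_index]
  om <- fd_gradient(v, h, 1) - fd_gradient(u, h, 2)
  scalar_field(series$x, series$y, om, mask = is.na(om), units = "1/s",
               phase = series$phases[phase_index])
}

#' Two-dimensional Q-criterion of one phase
#'
#' \code{Q = (||Omega||^2 - ||S||^2) / 2} from the in-plane 2x2 velocity
#' gradient tensor, with S and Omega its symmetric and antisymmetric parts
#' and Frobenius norms. Q > 0 marks rotation-dominated (vortical) regions;
#' an ideal shear layer has Q = 0. Only in-plane gradients are used, so any
#' spanwise component is carried but not differentiated. Q is invariant
#' under the addition of any uniform velocity.
#'
#' @inheritParams vorticity_z
#' @return A \code{\link{scalar_field}} in 1/s^2.
#' @export
q_criterion_2d <- function(series, phase_index) {
  check_field_grid(series)
  h <- series$spacing
  u <- series$u[, , phase_index]
  v <- series$v[, , phase_index]
  ux <- fd_gradient(u, h, 1); uy <- fd_gradient(u, h, 2)
  vx <- fd_gradient(v, h, 1); vy <- fd_gradient(v, h, 2)
  # ||Omega||^2 = (uy - vx)^2 / 2 ; ||S||^2 = ux^2 + vy^2 + (uy + vx)^2 / 2
  Q <- 0.5 * ((uy - vx)^2 / 2 - ux^2 - vy^2 - (uy + vx)^2 / 2)
  scalar_field(series$x, series$y, Q, mask = is.na(Q), units = "1/s^2",
               phase = series$phases[phase_index])
}

#' Phase-average a sequence of instantaneous frames
#'
#' Assigns frame k (0-based) of a sequence sampled at \code{frame_rate} to
#' phase bin \code{(k * n_phases * motion_freq / frame_rate) mod n_phases}
#' of the periodic motion and averages within bins. The frame-to-bin stride
#' must be integral (e.g. 12.5 Hz frames of a 1 Hz motion binned into 25
#' phases give stride 2: every other phase is sampled instantaneously and
#' all 25 bins fill over two periods); otherwise an error lists the nearest
#' commensurate values of \code{n_phases}.
#'
#' @param frames list of frames, each a list with matrices \code{u} and
#'   \code{v} (all congruent).
#' @param frame_rate acquisition rate, Hz.
#' @param motion_freq motion frequency, Hz.
#' @param n_phases number of phase bins.
#' @param x,y grid coordinates (default: node indices).
#' @param freestream,freq,spacing,plane_z attributes for the result.
#' @return A \code{\link{phase_series}} with attribute \code{"bin_counts"},
#'   the number of frames averaged into each bin.
#' @export
phase_average <- function(frames, frame_rate, motion_freq, n_phases,
                          x = NULL, y = NULL, freestream = NA_real_,
                          freq = motion_freq, spacing = NULL, plane_z = 0) {
  stride <- n_phases * motion_freq / frame_rate
  if (abs(stride - round(stride)) > 1e-9) {
    cand <- which(vapply(1:400, function(n) {
      s <- n * motion_freq / frame_rate
      abs(s - round(s)) < 1e-9
    }, logical(1)))
    cand <- cand[cand >= 8]
    near <- cand[order(abs(cand - n_phases))][seq_len(min(3, length(cand)))]
    stop(sprintf(
      "frame_rate/motion_freq and n_phases are not commensurate (stride %.6g); nearest valid n_phases: %s",
      stride, paste(near, collapse = ", ")))
  }
  stride <- as.integer(round(stride))
  d <- dim(frames[[1]]$u)
  nx <- d[1]; ny <- d[2]
  if (is.null(x)) x <- seq_len(nx)
  if (is.null(y)) y <- seq_len(ny)
  usum <- array(0, c(nx, ny, n_phases)); vsum <- array(0, c(nx, ny, n_phases))
  counts <- integer(n_phases)
  for (k in seq_along(frames)) {
    b <- ((k - 1L) * stride) %% n_phases + 1L
    usum[, , b] <- usum[, , b] + frames[[k]]$u
    vsum[, , b] <- vsum[, , b] + frames[[k]]$v
    counts[b] <- counts[b] + 1L
  }
  if (any(counts == 0))
    warning(sprintf("%d of %d phase bins received no frames",
                    sum(counts == 0), n_phases))
  for (b in seq_len(n_phases)) {
    if (counts[b] > 0) {
      usum[, , b] <- usum[, , b] / counts[b]
      vsum[, , b] <- vsum[, , b] / counts[b]
    } else {
      usum[, , b] <- NA_real_; vsum[, , b] <- NA_real_
    }
  }
  out <- phase_series(x, y, usum, vsum, phases = (seq_len(n_phases) - 1) / n_phases,
                      freestream = freestream, freq = freq, spacing = spacing,
                      plane_z = plane_z)
  attr(out, "bin_counts") <- counts
  out
}

#' Stitch two phase series into one domain
#'
#' Combines two series measured on the same grid lattice (identical spacing
#' and phase set, extents overlapping or abutting, offsets commensurate with
#' the spacing) into a union-grid series. Nodes covered by both are averaged
#' (\code{overlap = "mean"}) or taken from the first series
#' (\code{overlap = "primary"}); a node masked in one source takes the other
#' source's value.
#'
#' @param a,b \code{\link{phase_series}} objects.
#' @param overlap "mean" or "primary".
#' @return A \code{\link{phase_series}} on the union grid, with a
#'   \code{"stitch_provenance"} attribute recording the source extents and
#'   blending rule.
#' @export
stitch <- function(a, b, overlap = c("mean", "primary")) {
  overlap <- match.arg(overlap)
  h <- a$spacing
  if (abs(b$spacing - h) > 1e-9 * h) stop("grid spacings differ")
  if (length(a$phases) != length(b$phases) ||
      any(abs(a$phases - b$phases) > 1e-9))
    stop("phase sets differ")
  offx <- (b$x[1] - a$x[1]) / h; offy <- (b$y[1] - a$y[1]) / h
  if (abs(offx - round(offx)) > 1e-6 || abs(offy - round(offy)) > 1e-6)
    stop("grids are not on a common lattice")
  x <- seq(min(a$x[1], b$x[1]), max(a$x[length(a$x)], b$x[length(b$x)]), by = h)
  y <- seq(min(a$y[1], b$y[1]), max(a$y[length(a$y)], b$y[length(b$y)]), by = h)
  nx <- length(x); ny <- length(y); np <- length(a$phases)
  idx <- function(g, sub) round((sub - g[1]) / h) + 1L
  ia <- list(x = idx(x, a$x), y = idx(y, a$y))
  ib <- list(x = idx(x, b$x), y = idx(y, b$y))
  u <- array(NA_real_, c(nx, ny, np)); v <- u
  mask <- array(TRUE, c(nx, ny, np))
  for (k in seq_len(np)) {
    ua <- matrix(NA_real_, nx, ny); va <- ua; ub <- ua; vb <- ua
    ua[ia$x, ia$y] <- a$u[, , k]; va[ia$x, ia$y] <- a$v[, , k]
    ub[ib$x, ib$y] <- b$u[, , k]; vb[ib$x, ib$y] <- b$v[, , k]
    if (overlap == "mean") {
      cnt <- (!is.na(ua)) + (!is.na(ub))
      us <- ifelse(is.na(ua), 0, ua) + ifelse(is.na(ub), 0, ub)
      vs <- ifelse(is.na(va), 0, va) + ifelse(is.na(vb), 0, vb)
      u[, , k] <- ifelse(cnt > 0, us / cnt, NA_real_)
      v[, , k] <- ifelse(cnt > 0, vs / cnt, NA_real_)
    } else {
      u[, , k] <- ifelse(is.na(ua), ub, ua)
      v[, , k] <- ifelse(is.na(va), vb, va)
    }
    mask[, , k] <- is.na(u[, , k])
  }
  out <- phase_series(x, y, u, v, mask = mask, phases = a$phases,
                      freestream = a$freestream, freq = a$freq,
                      spacing = h, plane_z = a$plane_z)
  attr(out, "stitch_provenance") <- list(
    a_extent = range(a$x) , a_yextent = range(a$y),
    b_extent = range(b$x), b_yextent = range(b$y), overlap = overlap)
  out
}

#' Time-averaged momentum-surplus map
#'
#' Phase-mean of the streamwise velocity at each node, normalised as
#' \code{U/Uinf - 1}: positive values mark a thrust-type jet where momentum
#' has been added to the wake, negative values a momentum deficit. Phases at
#' which a node is occluded are excluded from that node's mean.
#'
#' @param series a \code{\link{phase_series}} with \code{freestream}
#'   recorded.
#' @return A dimensionless \code{\link{scalar_field}}.
#' @export
momentum_surplus <- function(series) {
  if (is.na(series$freestream) || series$freestream == 0)
    stop("momentum_surplus requires a non-zero recorded freestream")
  um <- apply(series$u, c(1, 2), function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  scalar_field(series$x, series$y, um / series$freestream - 1,
               mask = is.na(um), units = "")
}

#' Total circulation of a field by area integral of vorticity
#'
#' \code{sum(omega_z) * spacing^2} over unmasked nodes, optionally above a
#' signed threshold. Consistency helper used to compare the synthetic
#' ground truth and the circulation budget.
#'
#' @param omega a \code{\link{scalar_field}} of spanwise vorticity (1/s).
#' @param spacing grid spacing (m); taken from the coordinate vector when
#'   missing.
#' @return Circulation in m^2/s.
#' @export
total_circulation <- function(omega, spacing = NULL) {
  if (is.null(spacing)) spacing <- omega$x[2] - omega$x[1]
  sum(omega$values[!omega$mask], na.rm = TRUE) * spacing^2
}
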