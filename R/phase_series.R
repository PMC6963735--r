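#' Phase series of gridded velocity fields
#'
#' A cycle of phase-indexed 2D velocity fields on a regular grid for one
#' spanwise measurement plane. Velocity arrays are dimensioned
#' \code{[nx, ny, n_phases]} with x along the first dimension (streamwise)
#' and y along the second (lateral, the TE motion direction); the optional
#' third velocity component \code{w} (spanwise) is carried but never
#' differentiated. Masked nodes (fin/body occlusion) hold \code{NA}
#' velocities and \code{TRUE} in \code{mask}.
#'
#' @param x,y grid coordinates in metres (strictly increasing, uniform).
#' @param u,v velocity arrays \code{[nx, ny, n_phases]} in m/s.
#' @param mask logical array \code{[nx, ny, n_phases]}; TRUE = occluded.
#' @param phases nondimensional times t/T in [0, 1), strictly increasing.
#' @param freestream freestream speed U in m/s.
#' @param freq motion frequency f in 1/s.
#' @param spacing grid spacing in metres.
#' @param plane_z spanwise plane offset in metres.
#' @param w optional spanwise velocity array.
#' @return An object of class \code{phase_series}.
#' @export
phase_series <- function(x, y, u, v, mask = NULL, phases,
                         freestream = NA_real_, freq = NA_real_,
                         spacing = NULL, plane_z = 0, w = NULL) {
  nx <- length(x); ny <- length(y); np <- length(phases)
  if (!all(dim(u) == c(nx, ny, np)) || !all(dim(v) == c(nx, ny, np)))
    stop("u and v must be [nx, ny, n_phases] arrays congruent with x, y, phases")
  if (any(diff(phases) <= 0)) stop("phases must be strictly increasing")
  if (is.null(mask)) mask <- array(FALSE, c(nx, ny, np))
  if (is.null(spacing)) {
    spacing <- if (nx > 1) x[2] - x[1] else if (ny > 1) y[2] - y[1] else 1
  }
  hx <- diff(x); hy <- diff(y)
  if ((nx > 1 && diff(range(hx)) > 1e-9 * spacing) ||
      (ny > 1 && diff(range(hy)) > 1e-9 * spacing))
    stop("grid must be uniform")
  structure(list(x = x, y = y, u = u, v = v, w = w, mask = mask,
                 phases = phases, freestream = freestream, freq = freq,
                 spacing = spacing, plane_z = plane_z),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d x %d grid (%.3g m), %d phases, U = %g m/s, f = %g 1/s, z = %g m>\n",
              length(x$x), length(x$y), x$spacing, length(x$phases),
              x$freestream, x$freq, x$plane_z))
  invisible(x)
}

#' Scalar field on a phase-series grid
#'
#' @param x,y grid coordinates (metres).
#' @param values matrix \code{[nx, ny]} of node values.
#' @param mask logical matrix; TRUE = occluded/undefined.
#' @param units unit string ("1/s" for vorticity, "1/s^2" for Q, "" for
#'   nondimensional maps).
#' @param phase t/T stamp, if the field belongs to one phase.
#' @return An object of class \code{scalar_field}.
#' @export
scalar_field <- function(x, y, values, mask = NULL, units = "",
                         phase = NA_real_) {
  if (!all(dim(values) == c(length(x), length(y))))
    stop("values must be an [nx, ny] matrix congruent with x, y")
  if (is.null(mask)) mask <- is.na(values)
  structure(list(x = x, y = y, values = values, mask = mask, units = units,
                 phase = phase),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<scalar_field %s: %d x %d, range [%.4g, %.4g]>\n",
              x$units, length(x$x), length(x$y), rng[1], rng[2]))
  invisible(x)
}

#' @param ... passed to \code{graphics::image}.
#' @rdname scalar_field
#' @export
plot.scalar_field <- function(x, ...) {
  graphics::image(x$x, x$y, x$values, asp = 1, xlab = "x (m)",
                  ylab = "y (m)", col = grDevices::hcl.colors(64, "RdBu",
                                                              rev = TRUE),
                  ...)
  invisible(x)
}
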