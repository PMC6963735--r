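#' Angle trace container
#'
#' A measured or generated pitch-angle time series for the tail or the fin.
#'
#' @param time time in seconds, strictly increasing.
#' @param angle angle in degrees, same length as \code{time}.
#' @param which \code{"tail"} or \code{"fin"}.
#' @return An object of class \code{angle_trace}.
#' @export
angle_trace <- function(time, angle, which = c("tail", "fin")) {
  which <- match.arg(which)
  if (length(time) != length(angle)) stop("time and angle lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), angle = as.numeric(angle),
                 which = which), class = "angle_trace")
}

#' Least-squares sinusoid fit at fixed frequency
#'
#' Fits \code{A sin(2 pi f t + phase) + offset} to an angle trace with the
#' frequency held at the commanded value, the standard comparison between a
#' measured pitch trace and its prescribed sinusoid. The model is linear in
#' \code{(A cos(phase), A sin(phase), offset)} so the fit is a plain linear
#' least-squares solve; the recovered constant offset is the angular
#' misalignment of the trace.
#'
#' @param trace an \code{\link{angle_trace}} (or any list with \code{time}
#'   and \code{angle}).
#' @param freq fixed frequency f in 1/s.
#' @return A list of class \code{sinusoid_fit} with \code{amplitude} (>= 0),
#'   \code{phase} (degrees in (-180, 180]), \code{offset} (misalignment, same
#'   unit as the input), and \code{rms_residual}.
#' @export
fit_sinusoid_with_offset <- function(trace, freq) {
  t <- trace$time; y <- trace$angle
  if (length(t) < 5) stop("need at least 5 samples")
  if (diff(range(t)) < 1 / freq - 1e-9)
    stop("samples must span at least one period")
  X <- cbind(s = sin(2 * pi * freq * t), c = cos(2 * pi * freq * t), 1)
  beta <- qr.coef(qr(X), y)
  amp <- sqrt(beta[1]^2 + beta[2]^2)
  phase <- if (amp > 0) rad2deg(atan2(beta[2], beta[1])) else 0
  resid <- y - X %*% beta
  structure(list(amplitude = unname(amp), phase = unname(phase),
                 offset = unname(beta[3]),
                 rms_residual = sqrt(mean(resid^2))),
            class = "sinusoid_fit")
}

#' Trailing-edge trace: excursion, velocity and motion segmentation
#'
#' Samples the trailing-edge excursion over one cycle at \code{n_phases}
#' equispaced phases, differentiates it with centred finite differences under
#' periodic wraparound (phase-averaged data is periodic by construction),
#' locates the amplitude extrema as the zero crossings of the velocity, and
#' partitions the cycle into acceleration/deceleration intervals.
#'
#' @param case a \code{\link{motion_case}} with geometry set; the excursion
#'   is evaluated from the two-DOF angle model.
#' @param n_phases number of phases per cycle (>= 8).
#' @param excursion optional measured excursion series (metres) at the
#'   \code{n_phases} equispaced phases, used instead of the kinematic model.
#' @return An object of class \code{te_trace} with \code{phase} (t/T in
#'   [0,1)), \code{excursion} (m), \code{velocity} (m/s), \code{intervals}
#'   (data frame: start, end, regime), and \code{extrema_phases}.
#' @export
te_trace <- function(case, n_phases = 25, excursion = NULL) {
  if (n_phases < 8) stop("n_phases must be >= 8")
  phase <- (seq_len(n_phases) - 1) / n_phases
  period <- 1 / case$freq
  if (is.null(excursion)) {
    excursion <- trailing_edge_excursion(case, phase * period)
  } else if (length(excursion) != n_phases) {
    stop("excursion series length must equal n_phases")
  }
  te_trace_from_series(phase, excursion, period = period)
}

#' @rdname te_trace
#' @param phase phases t/T in [0, 1), strictly increasing and equispaced.
#' @param period cycle period in seconds.
#' @export
te_trace_from_series <- function(phase, excursion, period = 1) {
  n <- length(phase)
  if (n < 8) stop("need at least 8 phases")
  dp <- diff(phase)
  if (any(dp <= 0) || diff(range(dp)) > 1e-8 * mean(dp))
    stop("phases must be strictly increasing and equispaced over one cycle")
  dt <- mean(dp) * period
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  velocity <- (excursion[ip] - excursion[im]) / (2 * dt)
  extrema <- zero_crossing_phases(phase, velocity)
  tr <- structure(list(phase = phase, excursion = excursion,
                       velocity = velocity, period = period,
                       extrema_phases = extrema),
                  class = "te_trace")
  tr$intervals <- segment_accel_decel(tr)
  tr
}

# phases where a periodic series crosses zero, by linear interpolation
# between consecutive samples (cyclic)
zero_crossing_phases <- function(phase, v) {
  n <- length(v)
  ip <- c(2:n, 1)
  cross <- which(v * v[ip] < 0 | (v == 0 & v[ip] != 0))
  if (!length(cross)) return(numeric(0))
  p1 <- phase[cross]
  p2 <- phase[ip[cross]]
  p2[p2 < p1] <- p2[p2 < p1] + 1
  frac <- ifelse(v[cross] == 0, 0,
                 v[cross] / (v[cross] - v[ip[cross]]))
  sort((p1 + frac * (p2 - p1)) %% 1)
}

#' Segment a cycle into acceleration and deceleration intervals
#'
#' Partitions the cycle into maximal intervals where the trailing-edge speed
#' |velocity| is increasing (accelerating) or decreasing (decelerating);
#' boundaries fall at local extrema of |velocity|. A pure sinusoid yields
#' four alternating quarter-cycle intervals.
#'
#' @param trace a \code{\link{te_trace}} (velocity series required).
#' @return A data frame with columns \code{start}, \code{end} (t/T, the
#'   intervals tile [0,1)) and \code{regime} ("accelerating",
#'   "decelerating", or "constant" for a degenerate all-flat speed, which is
#'   flagged with attribute \code{degenerate = TRUE}).
#' @export
segment_accel_decel <- function(trace) {
  phase <- trace$phase; v <- trace$velocity
  n <- length(v)
  sp <- abs(v)
  ip <- c(2:n, 1)
  ds <- sp[ip] - sp               # forward difference of speed, periodic
  tol <- 1e-12 * max(sp, 1e-300)
  sgn <- sign(ds) * (abs(ds) > tol)
  if (all(sgn == 0)) {
    out <- data.frame(start = 0, end = 1, regime = "constant")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # fill flat runs with the regime of the preceding moving sample (cyclic)
  while (any(sgn == 0)) {
    prev <- c(sgn[n], sgn[-n])
    fill <- sgn == 0 & prev != 0
    if (!any(fill)) break
    sgn[fill] <- prev[fill]
  }
  # run-length boundaries on the cyclic sign sequence
  brk <- which(sgn != c(sgn[n], sgn[-n]))    # sample k starts a new regime
  if (!length(brk)) {
    out <- data.frame(start = 0, end = 1,
                      regime = ifelse(sgn[1] > 0, "accelerating", "decelerating"))
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  starts <- phase[brk]
  ends <- c(starts[-1], starts[1] + 1)
  regime <- ifelse(sgn[brk] > 0, "accelerating", "decelerating")
  out <- data.frame(start = starts, end = ends, regime = regime,
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- FALSE
  out
}

#' @export
print.te_trace <- function(x, ...) {
  cat(sprintf("<te_trace: %d phases, peak |a| = %.4g m, peak |v| = %.4g m/s>\n",
              length(x$phase), max(abs(x$excursion)), max(abs(x$velocity))))
  cat("  extrema at t/T =", paste(sprintf("%.3f", x$extrema_phases), collapse = ", "), "\n")
  invisible(x)
}
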