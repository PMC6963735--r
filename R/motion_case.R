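#' Construct a motion case
#'
#' A motion case holds the kinematic and flow parameters of one experimental
#' configuration of the two degree-of-freedom tail/caudal-fin model: the tail
#' and fin pitching amplitudes and their constant angular misalignments, the
#' tail-fin phase offset, the cycle frequency, the trailing-edge excursion
#' amplitude, and the freestream conditions. Geometry (tail length, midspan
#' chord, body length) and kinematic viscosity are optional and only needed
#' by operations that use them.
#'
#' Angles are stored in degrees (the convention used for pitching-foil
#' kinematics) and converted to radians internally for trigonometry.
#'
#' @param case_id label for the case (integer or character).
#' @param theta_T_amp tail pitching amplitude, degrees (angle between head
#'   and tail centerlines).
#' @param theta_C_amp caudal-fin pitching amplitude, degrees (angle between
#'   tail and fin centerlines).
#' @param phi phase offset in degrees by which the tail motion leads the fin
#'   motion; must lie in [0, 360).
#' @param freq cycle frequency f in 1/s.
#' @param te_excursion_max maximum trailing-edge excursion A in metres.
#' @param freestream freestream speed U in m/s.
#' @param delta_theta_T,delta_theta_C constant angular misalignments of tail
#'   and fin, degrees.
#' @param strouhal_group,kinematic_group optional integer group labels.
#' @param tail_length tail length L_T in metres (pivot to peduncle joint).
#' @param chord midspan chord c of the caudal fin in metres.
#' @param body_length body length L in metres (for the Reynolds number).
#' @param kinematic_viscosity kinematic viscosity in m^2/s.
#' @return An object of class \code{motion_case}.
#' @examples
#' mc <- motion_case(1, theta_T_amp = 0.24, theta_C_amp = 12.90,
#'                   phi = 0, freq = 1, te_excursion_max = 0.0251,
#'                   freestream = 0.0815)
#' strouhal(mc)
#' @export
motion_case <- function(case_id,
                        theta_T_amp, theta_C_amp, phi, freq,
                        te_excursion_max, freestream,
                        delta_theta_T = 0, delta_theta_C = 0,
                        strouhal_group = NA_integer_,
                        kinematic_group = NA_integer_,
                        tail_length = NA_real_, chord = NA_real_,
                        body_length = NA_real_,
                        kinematic_viscosity = NA_real_) {
  stopifnot(is.numeric(theta_T_amp), is.numeric(theta_C_amp),
            is.numeric(phi), is.numeric(freq))
  if (freq <= 0) stop("freq must be > 0")
  if (freestream <= 0) stop("freestream must be > 0")
  if (theta_T_amp < 0 || theta_C_amp < 0) stop("amplitudes must be >= 0")
  if (phi < 0 || phi >= 360) stop("phi must lie in [0, 360)")
  if ((theta_T_amp > 0 || theta_C_amp > 0) &&
      !is.na(te_excursion_max) && te_excursion_max <= 0)
    stop("te_excursion_max must be > 0 when either amplitude is > 0")
  structure(list(
    case_id = case_id,
    strouhal_group = strouhal_group,
    kinematic_group = kinematic_group,
    theta_T_amp = theta_T_amp,
    theta_C_amp = theta_C_amp,
    delta_theta_T = delta_theta_T,
    delta_theta_C = delta_theta_C,
    phi = phi,
    freq = freq,
    tail_length = tail_length,
    chord = chord,
    te_excursion_max = te_excursion_max,
    freestream = freestream,
    kinematic_viscosity = kinematic_viscosity,
    body_length = body_length
  ), class = "motion_case")
}

#' @export
print.motion_case <- function(x, ...) {
  cat(sprintf("<motion_case %s>\n", as.character(x$case_id)))
  cat(sprintf("  theta_T,o = %.2f deg (offset %+.2f), theta_C,o = %.2f deg (offset %+.2f)\n",
              x$theta_T_amp, x$delta_theta_T, x$theta_C_amp, x$delta_theta_C))
  cat(sprintf("  phi = %g deg, f = %g 1/s, A = %g m, U = %g m/s, St = %.3f\n",
              x$phi, x$freq, x$te_excursion_max, x$freestream, strouhal(x)))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Tail and caudal-fin pitch angle time series
#'
#' The tail pitches as \code{theta_T(t) = theta_T_amp * sin(2 pi f t + phi)}
#' and the fin as \code{theta_C(t) = theta_C_amp * sin(2 pi f t)}; the tail
#' leads the fin by \code{phi}. The constant misalignment offsets are added
#' when \code{include_misalignment} is \code{TRUE} (the default), matching
#' how the measured angle traces sit about a non-zero mean.
#'
#' @param case a \code{\link{motion_case}}.
#' @param t time in seconds (vectorised).
#' @param include_misalignment add the constant misalignment offset?
#' @return Angle(s) in degrees.
#' @export
tail_angle <- function(case, t, include_misalignment = TRUE) {
  a <- case$theta_T_amp * sin(2 * pi * case$freq * t + deg2rad(case$phi))
  if (include_misalignment) a <- a + case$delta_theta_T
  a
}

#' @rdname tail_angle
#' @export
fin_angle <- function(case, t, include_misalignment = TRUE) {
  a <- case$theta_C_amp * sin(2 * pi * case$freq * t)
  if (include_misalignment) a <- a + case$delta_theta_C
  a
}

#' Trailing-edge excursion of the two-DOF tail/fin system
#'
#' Lateral trailing-edge displacement
#' \code{a(t) = L_T sin(theta_T(t)) + c sin(theta_T(t) + theta_C(t))}:
#' the tail rotates the peduncle joint about the tail pivot and the fin chord
#' adds its own rotation on top of the tail angle. By default the constant
#' misalignment offsets are excluded (the excursion amplitude A is defined by
#' the oscillatory motion); set \code{include_misalignment = TRUE} to include
#' them.
#'
#' @inheritParams tail_angle
#' @return Excursion in metres.
#' @export
trailing_edge_excursion <- function(case, t, include_misalignment = FALSE) {
  if (is.na(case$tail_length) || is.na(case$chord))
    stop("trailing_edge_excursion requires tail_length and chord to be set")
  thT <- deg2rad(tail_angle(case, t, include_misalignment))
  thC <- deg2rad(fin_angle(case, t, include_misalignment))
  case$tail_length * sin(thT) + case$chord * sin(thT + thC)
}

#' Amplitude and phase of a sum of two synchronous sinusoids
#'
#' For a trailing-edge motion modelled as the sum of a tail contribution
#' \code{amp_T * sin(w t + phi)} and a fin contribution \code{amp_C * sin(w t)},
#' returns the amplitude of the resultant sinusoid and the phase \code{psi}
#' (degrees) by which the resultant leads the fin component. This quantifies
#' how the phase offset between the total trailing-edge motion and the fin
#' motion shifts as the tail/fin amplitude ratio changes.
#'
#' @param amp_T,amp_C non-negative component amplitudes (any common unit).
#' @param phi phase offset in degrees by which the tail leads the fin.
#' @return A list with \code{amplitude} (same unit as inputs), \code{psi}
#'   (degrees), and \code{degenerate} (\code{TRUE} when both amplitudes are
#'   zero and the phase is undefined).
#' @export
resultant_amplitude_phase <- function(amp_T, amp_C, phi) {
  if (amp_T < 0 || amp_C < 0) stop("amplitudes must be >= 0")
  phir <- deg2rad(phi)
  amp <- sqrt(amp_T^2 + amp_C^2 + 2 * amp_T * amp_C * cos(phir))
  if (amp_T == 0 && amp_C == 0) {
    return(list(amplitude = 0, psi = NA_real_, degenerate = TRUE))
  }
  psi <- rad2deg(atan2(amp_T * sin(phir), amp_C + amp_T * cos(phir)))
  list(amplitude = amp, psi = psi, degenerate = FALSE)
}

#' Strouhal number
#'
#' \code{St = f A / U} with A the maximum trailing-edge excursion, the
#' principal nondimensional parameter of oscillatory propulsion.
#'
#' @param case a \code{\link{motion_case}}.
#' @return Dimensionless Strouhal number.
#' @export
strouhal <- function(case) {
  if (case$freestream <= 0) stop("freestream must be > 0")
  case$freq * case$te_excursion_max / case$freestream
}

#' Reynolds number based on body length
#'
#' \code{Re = U L / nu}.
#'
#' @param case a \code{\link{motion_case}} with \code{body_length} and
#'   \code{kinematic_viscosity} set.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(case) {
  if (is.na(case$body_length) || is.na(case$kinematic_viscosity))
    stop("reynolds requires body_length and kinematic_viscosity to be set")
  case$freestream * case$body_length / case$kinematic_viscosity
}
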