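#' Lamb-Oseen vortex velocity
#'
#' Velocity induced at a set of points by a Lamb-Oseen vortex: tangential
#' speed \code{Gamma/(2 pi r) * (1 - exp(-r^2/rc^2))} about the centre,
#' regular at the origin (zero velocity at the centre). Positive circulation
#' is counterclockwise. This desingularised vortex with a Gaussian vorticity
#' core is the ground-truth primitive of the synthetic wake generator.
#'
#' @param gamma signed circulation in m^2/s.
#' @param rc core radius in metres (> 0).
#' @param center vortex centre \code{c(x, y)} in metres.
#' @param x,y point coordinates (equal-length vectors, matrices or arrays).
#' @return A list with components \code{u} and \code{v} shaped like \code{x}.
#' @export
lamb_oseen_velocity <- function(gamma, rc, center, x, y) {
  if (rc <= 0) stop("rc must be > 0")
  dx <- x - center[1]
  dy <- y - center[2]
  r2 <- dx * dx + dy * dy
  # u_theta / r, finite (-> gamma/(2 pi rc^2)... actually -> 0 slope) at r = 0
  f <- gamma / (2 * pi) * ifelse(r2 > 0, (1 - exp(-r2 / rc^2)) / r2, 0)
  list(u = -f * dy, v = f * dx)
}

#' Lamb-Oseen vorticity profile
#'
#' Analytic spanwise vorticity \code{Gamma/(pi rc^2) exp(-r^2/rc^2)}.
#' @inheritParams lamb_oseen_velocity
#' @return Vorticity (1/s), shaped like \code{x}.
#' @export
lamb_oseen_vorticity <- function(gamma, rc, center, x, y) {
  dx <- x - center[1]; dy <- y - center[2]
  gamma / (pi * rc^2) * exp(-(dx * dx + dy * dy) / rc^2)
}

#' Square-like trailing-edge waveform with dwell at the extrema
#'
#' A sinusoid time-warped to hold at each amplitude extreme for
#' \code{dwell_fraction} of its half-cycle, emulating a trailing edge that
#' remains almost stationary at the extremes before reversing (the
#' square-like kinematic discrepancy of a compliant drive). The waveform is
#' periodic and odd-symmetric with peak value \code{amplitude}; with
#' \code{dwell_fraction = 0} it reduces to
#' \code{amplitude * sin(2 pi t/T)} exactly. Extrema sit at t/T = 0.25
#' (maximum) and 0.75 (minimum), as for the plain sinusoid.
#'
#' @param t_over_T nondimensional time t/T (any real values; the waveform is
#'   1-periodic).
#' @param amplitude peak excursion (metres).
#' @param dwell_fraction fraction of each half-cycle spent dwelling at the
#'   extreme, in [0, 0.5).
#' @return Excursion values shaped like \code{t_over_T}.
#' @export
dwell_waveform <- function(t_over_T, amplitude, dwell_fraction = 0) {
  amplitude * sin(2 * pi * dwell_warp(t_over_T, dwell_fraction))
}

#' @rdname dwell_waveform
#' @param period cycle period in seconds (the derivative is with respect to
#'   dimensional time).
#' @return For \code{dwell_waveform_velocity}, the analytic time derivative
#'   of the waveform in m/s.
#' @export
dwell_waveform_velocity <- function(t_over_T, amplitude, dwell_fraction = 0,
                                    period = 1) {
  g <- dwell_warp(t_over_T, dwell_fraction)
  amplitude * cos(2 * pi * g) * 2 * pi *
    dwell_warp_slope(t_over_T, dwell_fraction) / period
}

# piecewise-linear phase warp: flat (slope 0) for a window of width
# W = dwell_fraction/2 (cycle fraction) centred on each extremum, slope
# 0.5/(0.5 - W) elsewhere; identity when dwell_fraction = 0
dwell_warp <- function(t, df) {
  if (df < 0 || df >= 0.5) stop("dwell_fraction must lie in [0, 0.5)")
  W <- df / 2                         # dwell width per extremum, cycle units
  q <- (t - 0.25) %% 1                # extrema now at q = 0 and q = 0.5
  s <- 0.5 / (0.5 - W)
  g <- ifelse(q < W / 2, 0,
       ifelse(q <= 0.5 - W / 2, (q - W / 2) * s,
       ifelse(q < 0.5 + W / 2, 0.5,
       ifelse(q <= 1 - W / 2, 0.5 + (q - 0.5 - W / 2) * s, 1))))
  g + 0.25
}

dwell_warp_slope <- function(t, df) {
  W <- df / 2
  q <- (t - 0.25) %% 1
  s <- 0.5 / (0.5 - W)
  ifelse(q < W / 2 | (q >= 0.5 - W / 2 & q < 0.5 + W / 2) | q >= 1 - W / 2,
         0, s)
}

#' Specify one shed vortex of a synthetic wake scenario
#'
#' Describes the life cycle of a single trailing-edge vortex with known
#' ground truth. During formation (\code{formation_phase <= t/T <
#' shed_phase}) the total circulation ramps up linearly and is distributed
#' between a core held at a fixed standoff downstream of the shedding origin
#' and a chain of small feeder vortices along the feeding shear layer, so
#' the Q-thresholded structure stays connected to the trailing-edge region.
#' At \code{shed_phase} the feeders are entrained into the core (total
#' circulation is conserved) and the core advects with constant velocity.
#'
#' @param circulation signed total circulation Gamma in m^2/s at shedding.
#' @param core_radius Lamb-Oseen core radius in metres.
#' @param shed_phase shedding time t/T.
#' @param origin \code{c(x, y)} trailing-edge position at shedding (metres);
#'   filled in from the scenario kinematics when \code{NULL}.
#' @param advection \code{c(Ux, Uy)} post-shedding advection velocity, m/s.
#' @param formation_phase t/T at which formation begins (may be negative:
#'   vorticity production can start before the nominal half-cycle).
#' @param standoff distance (m) of the core downstream of the origin along
#'   \code{advection} at the moment of shedding.
#' @param standoff0 core standoff at the start of formation; the roll-up
#'   centre migrates linearly from \code{standoff0} to \code{standoff} as
#'   the vortex forms. Defaults to \code{min(standoff, 0.008)}.
#' @param n_feed number of feeder vortices in the forming chain (0 disables
#'   the chain).
#' @param feed_core feeder core radius (m); default spans the chain gap.
#' @param label structure label ("P1", "S1", ...).
#' @return An object of class \code{vortex_spec}.
#' @export
vortex_spec <- function(circulation, core_radius, shed_phase,
                        origin = NULL, advection = c(0, 0),
                        formation_phase = shed_phase - 0.25,
                        standoff = 0.022, standoff0 = NULL,
                        n_feed = 2, feed_core = NULL,
                        label = "P1") {
  if (core_radius <= 0) stop("core_radius must be > 0")
  if (abs(circulation) <= 0) stop("|circulation| must be > 0")
  if (formation_phase >= shed_phase) stop("formation_phase must precede shed_phase")
  if (is.null(standoff0)) standoff0 <- min(standoff, 0.008)
  if (is.null(feed_core)) feed_core <- 0.95 * standoff / (n_feed + 1)
  structure(list(circulation = circulation, core_radius = core_radius,
                 shed_phase = shed_phase, origin = origin,
                 advection = advection, formation_phase = formation_phase,
                 standoff = standoff, standoff0 = standoff0,
                 n_feed = n_feed, feed_core = feed_core,
                 label = label),
            class = "vortex_spec")
}

#' Specify a scripted leading-edge vortex
#'
#' An LEV that rides the fin at a fixed chordwise station and small normal
#' offset while attached, then detaches at \code{detach_phase}: its position
#' jumps clear of the fin by \code{detach_jump} along the fin normal (the
#' pinch that opens the gap between the lowest Q contour and the fin),
#' after which it drifts with \code{post_velocity} while its circulation
#' decays with time constant \code{decay_tau} (dissipation).
#'
#' @param circulation signed circulation (m^2/s) while attached.
#' @param core_radius core radius (m).
#' @param attach_phase,detach_phase t/T bounds of the attached interval.
#' @param chord_frac chordwise station of the LEV centre, fraction of chord
#'   from the pivot.
#' @param side +1 for the +y side of the fin, -1 for the -y side.
#' @param normal_offset distance (m) of the centre from the fin centreline
#'   while attached; default \code{half_thickness + core_radius/2}.
#' @param detach_jump outward normal displacement (m) applied at detachment.
#' @param post_velocity drift velocity after detachment, m/s.
#' @param decay_tau circulation decay time constant after detachment, in
#'   cycles.
#' @param label structure label.
#' @return An object of class \code{lev_spec}.
#' @export
lev_spec <- function(circulation, core_radius, attach_phase, detach_phase,
                     chord_frac = 0.55, side = 1, normal_offset = NULL,
                     detach_jump = 0.014, post_velocity = c(0.04, 0.02),
                     decay_tau = 0.12, label = "LEV") {
  if (detach_phase <= attach_phase) stop("detach_phase must follow attach_phase")
  structure(list(circulation = circulation, core_radius = core_radius,
                 attach_phase = attach_phase, detach_phase = detach_phase,
                 chord_frac = chord_frac, side = side,
                 normal_offset = normal_offset, detach_jump = detach_jump,
                 post_velocity = post_velocity, decay_tau = decay_tau,
                 label = label),
            class = "lev_spec")
}

#' Define a synthetic wake scenario
#'
#' Bundles the kinematic case, grid, trailing-edge waveform, fin geometry,
#' vortex scripts and noise level that together define one synthetic
#' phase-averaged dataset with known ground truth. The grid defaults mirror
#' phase-averaged planar PIV of the tail/fin wake: 25 phases per cycle,
#' 1.78 mm spacing, a 0.34 m x 0.26 m domain, and a masked fin region.
#'
#' The trailing-edge lateral position is
#' \code{te_y(t/T) = dwell_waveform(t/T - 0.25, A, te_dwell_fraction)}, i.e.
#' a (possibly square-like) waveform with the positive amplitude extreme at
#' t/T = 0.5, so the half-cycles are [0, 0.5) and [0.5, 1).
#'
#' @param case a \code{\link{motion_case}}; supplies A, U, f.
#' @param vortices list of \code{\link{vortex_spec}}.
#' @param levs list of \code{\link{lev_spec}}.
#' @param spacing grid spacing in metres.
#' @param extent domain \code{c(x0, x1, y0, y1)} in metres.
#' @param n_phases phases per cycle (>= 8).
#' @param te_dwell_fraction dwell fraction of the TE waveform (0 = sinusoid).
#' @param fin list with \code{pivot = c(x, y)}, \code{chord},
#'   \code{half_thickness} (metres) describing the rotating fin mask.
#' @param noise_sigma iid Gaussian velocity noise per node per phase, m/s
#'   (phase-averaged residual turbulence).
#' @param n_history number of past cycles whose shed vortices populate the
#'   downstream wake (steady-state periodicity).
#' @param seed integer RNG seed; generation is a pure function of
#'   (scenario, seed).
#' @param label scenario label.
#' @return An object of class \code{wake_scenario}.
#' @export
wake_scenario <- function(case, vortices = list(), levs = list(),
                          spacing = 1.78e-3,
                          extent = c(-0.04, 0.30, -0.13, 0.13),
                          n_phases = 25, te_dwell_fraction = 0,
                          fin = list(pivot = c(-0.062, 0), chord = 0.105,
                                     half_thickness = 0.003),
                          noise_sigma = 2e-4, n_history = 2, seed = 1L,
                          label = "scenario") {
  if (spacing <= 0) stop("grid spacing must be > 0")
  if (n_phases < 8) stop("n_phases must be >= 8")
  scn <- structure(list(case = case, vortices = vortices, levs = levs,
                        spacing = spacing, extent = extent,
                        n_phases = n_phases,
                        te_dwell_fraction = te_dwell_fraction, fin = fin,
                        noise_sigma = noise_sigma, n_history = n_history,
                        seed = as.integer(seed), label = label),
                   class = "wake_scenario")
  # resolve vortex origins from the TE position at their shed phase
  scn$vortices <- lapply(scn$vortices, function(vs) {
    if (is.null(vs$origin)) vs$origin <- te_position(scn, vs$shed_phase)
    vs
  })
  scn
}

#' Trailing-edge lateral position of a scenario
#' @param scenario a \code{\link{wake_scenario}}.
#' @param t_over_T nondimensional times.
#' @return For \code{te_lateral}, TE y-positions (m); for
#'   \code{te_position}, an n x 2 matrix of TE (x, y).
#' @export
te_lateral <- function(scenario, t_over_T) {
  dwell_waveform(t_over_T - 0.25, scenario$case$te_excursion_max,
                 scenario$te_dwell_fraction)
}

#' @rdname te_lateral
#' @export
te_position <- function(scenario, t_over_T) {
  yy <- te_lateral(scenario, t_over_T)
  chord <- scenario$fin$chord
  xx <- scenario$fin$pivot[1] + sqrt(pmax(chord^2 - yy^2, 0))
  cbind(x = xx, y = yy)
}

#' Phase-sampled trailing-edge trace of a scenario
#' @param scenario a \code{\link{wake_scenario}}.
#' @return A \code{\link{te_trace}} at the scenario's phase grid.
#' @export
scenario_te_trace <- function(scenario) {
  ph <- (seq_len(scenario$n_phases) - 1) / scenario$n_phases
  te_trace_from_series(ph, te_lateral(scenario, ph),
                       period = 1 / scenario$case$freq)
}

# components (x, y, gamma, rc) of one vortex_spec at unwrapped time t
# (cycles); empty data.frame when absent
vortex_components <- function(vs, t, period) {
  if (t < vs$formation_phase) return(NULL)
  dir <- vs$advection
  nd <- sqrt(sum(dir^2))
  dir <- if (nd > 0) dir / nd else c(1, 0)
  if (t < vs$shed_phase) {
    prog <- (t - vs$formation_phase) / (vs$shed_phase - vs$formation_phase)
    stand <- vs$standoff0 + (vs$standoff - vs$standoff0) * prog
    core_pos <- vs$origin + dir * stand
    ramp <- prog
    g_tot <- ramp * vs$circulation
    if (vs$n_feed > 0) {
      fr <- seq_len(vs$n_feed) / (vs$n_feed + 1)
      feed_x <- vs$origin[1] + dir[1] * stand * fr
      feed_y <- vs$origin[2] + dir[2] * stand * fr
      data.frame(x = c(core_pos[1], feed_x), y = c(core_pos[2], feed_y),
                 gamma = c(0.6, rep(0.4 / vs$n_feed, vs$n_feed)) * g_tot,
                 rc = c(vs$core_radius, rep(vs$feed_core, vs$n_feed)))
    } else {
      data.frame(x = core_pos[1], y = core_pos[2], gamma = g_tot,
                 rc = vs$core_radius)
    }
  } else {
    core_pos <- vs$origin + dir * vs$standoff
    dt <- (t - vs$shed_phase) * period
    data.frame(x = core_pos[1] + vs$advection[1] * dt,
               y = core_pos[2] + vs$advection[2] * dt,
               gamma = vs$circulation, rc = vs$core_radius)
  }
}

# fin centreline direction and normal at time t
fin_geometry <- function(scenario, t) {
  te <- te_position(scenario, t)
  d <- c(te[1], te[2]) - scenario$fin$pivot
  d <- d / sqrt(sum(d^2))
  list(te = c(te), dir = d, normal = c(-d[2], d[1]))
}

# (x, y, gamma, rc) of one lev_spec at unwrapped time t
lev_components <- function(ls, t, scenario, period) {
  if (t < ls$attach_phase) return(NULL)
  off <- if (is.null(ls$normal_offset))
    scenario$fin$half_thickness + ls$core_radius / 2 else ls$normal_offset
  if (t < ls$detach_phase) {
    g <- fin_geometry(scenario, t)
    p <- scenario$fin$pivot + g$dir * ls$chord_frac * scenario$fin$chord +
      ls$side * g$normal * off
    data.frame(x = p[1], y = p[2], gamma = ls$circulation,
               rc = ls$core_radius)
  } else {
    g <- fin_geometry(scenario, ls$detach_phase)
    p0 <- scenario$fin$pivot + g$dir * ls$chord_frac * scenario$fin$chord +
      ls$side * g$normal * (off + ls$detach_jump)
    dt <- (t - ls$detach_phase) * period
    gam <- ls$circulation * exp(-(t - ls$detach_phase) / ls$decay_tau)
    data.frame(x = p0[1] + ls$post_velocity[1] * dt,
               y = p0[2] + ls$side * abs(ls$post_velocity[2]) * dt,
               gamma = gam, rc = ls$core_radius)
  }
}

#' Generate a synthetic phase-resolved wake with ground truth
#'
#' Builds a phase series on the scenario grid: freestream plus the induced
#' velocity of every scripted vortex active at each phase (including copies
#' from the previous \code{n_history} cycles, advected one wake wavelength
#' further downstream per cycle, so the wake is in periodic steady state),
#' plus iid Gaussian noise, with the rotating fin rectangle masked out.
#' Components whose centre leaves the domain are dropped from the field but
#' retained in the ground truth with \code{clipped = TRUE}.
#'
#' The same scenario and seed always produce bit-identical output.
#'
#' @param scenario a \code{\link{wake_scenario}}.
#' @return A list with \code{series} (a \code{\link{phase_series}}) and
#'   \code{truth}, a list holding per-phase component tables
#'   (\code{components}), per-spec summaries (\code{specs}: label, total
#'   circulation, shed/detach phase, trajectory angle), and per-half-cycle
#'   injected circulation (\code{half_cycle_gamma}).
#' @export
generate_wake <- function(scenario) {
  scn <- scenario
  h <- scn$spacing
  nx <- floor((scn$extent[2] - scn$extent[1]) / h + 1e-9) + 1
  ny <- floor((scn$extent[4] - scn$extent[3]) / h + 1e-9) + 1
  x <- scn$extent[1] + (seq_len(nx) - 1) * h
  y <- scn$extent[3] + (seq_len(ny) - 1) * h
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  n <- scn$n_phases
  phases <- (seq_len(n) - 1) / n
  period <- 1 / scn$case$freq
  U <- scn$case$freestream

  # restore the caller's RNG state afterwards: generation is a pure
  # function of (scenario, seed)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(scn$seed)

  u <- array(0, c(nx, ny, n)); v <- array(0, c(nx, ny, n))
  mask <- array(FALSE, c(nx, ny, n))
  comp_rows <- list()
  inside <- function(px, py)
    px >= scn$extent[1] && px <= scn$extent[2] &&
    py >= scn$extent[3] && py <= scn$extent[4]

  for (k in seq_len(n)) {
    uk <- matrix(U, nx, ny); vk <- matrix(0, nx, ny)
    # m = -1 covers the next cycle's pre-onset formation (vorticity
    # production can begin before t/T = 0 of its half-cycle), keeping the
    # periodic steady state consistent near the end of the sampled cycle
    for (m in -1:(scn$n_history - 1)) {
      t <- phases[k] + m
      specs <- c(scn$vortices, scn$levs)
      for (si in seq_along(specs)) {
        sp <- specs[[si]]
        comp <- if (inherits(sp, "vortex_spec"))
          vortex_components(sp, t, period)
        else lev_components(sp, t, scn, period)
        if (is.null(comp)) next
        for (ci in seq_len(nrow(comp))) {
          clip <- !inside(comp$x[ci], comp$y[ci])
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            label = sp$label, phase = phases[k], cycle_back = m,
            x = comp$x[ci], y = comp$y[ci], gamma = comp$gamma[ci],
            rc = comp$rc[ci], core = ci == 1L, clipped = clip)
          if (clip) next
          uv <- lamb_oseen_velocity(comp$gamma[ci], comp$rc[ci],
                                    c(comp$x[ci], comp$y[ci]), X, Y)
          uk <- uk + uv$u; vk <- vk + uv$v
        }
      }
    }
    if (scn$noise_sigma > 0) {
      uk <- uk + matrix(stats::rnorm(nx * ny, 0, scn$noise_sigma), nx, ny)
      vk <- vk + matrix(stats::rnorm(nx * ny, 0, scn$noise_sigma), nx, ny)
    }
    mk <- fin_mask(scn, phases[k], X, Y)
    uk[mk] <- NA_real_; vk[mk] <- NA_real_
    u[, , k] <- uk; v[, , k] <- vk; mask[, , k] <- mk
  }

  series <- phase_series(x = x, y = y, u = u, v = v, mask = mask,
                         phases = phases, freestream = U,
                         freq = scn$case$freq, spacing = h,
                         plane_z = 0)
  specs_df <- do.call(rbind, lapply(c(scn$vortices, scn$levs), function(sp) {
    if (inherits(sp, "vortex_spec")) {
      data.frame(label = sp$label, circulation = sp$circulation,
                 shed_phase = sp$shed_phase,
                 detach_phase = NA_real_,
                 trajectory_angle = atan2(sp$advection[2],
                                          sp$advection[1]) * 180 / pi)
    } else {
      data.frame(label = sp$label, circulation = sp$circulation,
                 shed_phase = NA_real_, detach_phase = sp$detach_phase,
                 trajectory_angle = NA_real_)
    }
  }))
  hc <- half_cycle_gamma_truth(scn)
  truth <- list(components = do.call(rbind, comp_rows), specs = specs_df,
                half_cycle_gamma = hc, scenario_label = scn$label,
                seed = scn$seed)
  list(series = series, truth = truth)
}

# injected trailing-edge circulation per half-cycle and sign (LEVs excluded:
# they live at the fin, not in the TE integration region)
half_cycle_gamma_truth <- function(scn) {
  if (!length(scn$vortices)) return(NULL)
  g <- vapply(scn$vortices, `[[`, numeric(1), "circulation")
  shed <- vapply(scn$vortices, `[[`, numeric(1), "shed_phase")
  half <- ifelse(shed %% 1 >= 0.5, "second", "first")
  out <- aggregate(abs(g), list(half = half, sign = sign(g)), sum)
  names(out)[3] <- "gamma_total"
  out
}

# logical [nx, ny] fin occlusion mask at time t: nodes within half_thickness
# of the pivot->TE segment
fin_mask <- function(scn, t, X, Y) {
  g <- fin_geometry(scn, t)
  p <- scn$fin$pivot
  L <- sqrt(sum((g$te - p)^2))
  sx <- X - p[1]; sy <- Y - p[2]
  proj <- pmin(pmax(sx * g$dir[1] + sy * g$dir[2], 0), L)
  dx <- sx - proj * g$dir[1]; dy <- sy - proj * g$dir[2]
  dx * dx + dy * dy <= scn$fin$half_thickness^2
}

#' Preset wake scenarios
#'
#' Ready-made scenarios emulating the observed wake organisations:
#' \describe{
#' \item{\code{scenario_case4_like}}{near-sinusoidal TE motion; per
#'   half-cycle one strong primary vortex (shed at t/T = 0.70) followed by
#'   two trailing secondary vortices (shed at 0.80 and 0.88), all advecting
#'   streamwise. Used for circulation-budget recovery.}
#' \item{\code{scenario_case1_like}}{square-like TE motion (dwell fraction
#'   0.3); per half-cycle a weak early secondary vortex on an inclined
#'   trajectory (shed at 0.56) followed by a strong late primary (shed at
#'   0.81). Used for tracking and trajectory recovery.}
#' \item{\code{scenario_shedding}}{one primary vortex per half-cycle (shed
#'   at t/T = 0.70) plus a scripted LEV attached to the fin that detaches at
#'   t/T = 0.80. Used for shedding-time and attachment recovery.}
#' }
#'
#' Vortex strengths are chosen so that peak core vorticity is 20-60 times
#' the 1 1/s circulation threshold, as in well-resolved phase-averaged
#' measurements, and cores are resolved (rc = 9 mm, about 5 grid cells).
#'
#' @param freestream freestream speed U in m/s.
#' @param seed integer RNG seed.
#' @param noise_sigma velocity noise, m/s.
#' @param gamma_primary,gamma_secondary,gamma_lev circulation magnitudes
#'   (m^2/s) of the scripted structures.
#' @param core core radius (m) of primary/secondary vortices.
#' @param n_phases phases per cycle.
#' @return A \code{\link{wake_scenario}}.
#' @export
scenario_case4_like <- function(freestream = 0.0815, seed = 1L,
                                noise_sigma = 2e-4,
                                gamma_primary = 16e-3, gamma_secondary = 5e-3,
                                core = 9e-3, n_phases = 25) {
  case <- motion_case("case4-like", theta_T_amp = 3.44, theta_C_amp = 0.18,
                      phi = 0, freq = 1, te_excursion_max = 0.0221,
                      freestream = freestream,
                      tail_length = 0.26, chord = 0.105,
                      body_length = 0.285, kinematic_viscosity = 1e-6)
  # the shed vortices organise into the two rows of a reverse-Karman
  # street, offset +-10 mm about the wake axis (positive row above),
  # as mutual induction reorganises the street just downstream of the TE
  te_x0 <- -0.062 + 0.105          # TE x at zero lateral excursion
  mk <- function(g, shed, form, stand, lab)
    vortex_spec(g, core, shed,
                origin = c(te_x0, sign(g) * 0.010),
                advection = c(freestream, 0),
                formation_phase = form, standoff = stand, label = lab)
  vortices <- list(
    mk(+gamma_primary, 0.70, 0.50, 0.020, "P1"),
    mk(+gamma_secondary, 0.80, 0.70, 0.012, "S1"),
    mk(+gamma_secondary, 0.88, 0.80, 0.008, "S2"),
    mk(-gamma_primary, 0.20, 0.00, 0.020, "P1n"),
    mk(-gamma_secondary, 0.30, 0.20, 0.012, "S1n"),
    mk(-gamma_secondary, 0.38, 0.30, 0.008, "S2n"))
  wake_scenario(case, vortices = vortices, noise_sigma = noise_sigma,
                n_phases = n_phases, te_dwell_fraction = 0, seed = seed,
                label = "case4-like")
}

#' @rdname scenario_case4_like
#' @param incline_vy lateral advection (m/s) of the early secondary vortex
#'   (sets its inclined trajectory).
#' @export
scenario_case1_like <- function(freestream = 0.0815, seed = 1L,
                                noise_sigma = 2e-4,
                                gamma_primary = 14e-3, gamma_secondary = 2.5e-3,
                                core = 9e-3, incline_vy = 0.030,
                                n_phases = 25) {
  case <- motion_case("case1-like", theta_T_amp = 0.24, theta_C_amp = 12.90,
                      phi = 0, freq = 1, te_excursion_max = 0.0251,
                      freestream = freestream,
                      tail_length = 0.26, chord = 0.105,
                      body_length = 0.285, kinematic_viscosity = 1e-6)
  vortices <- list(
    vortex_spec(+gamma_secondary, 7e-3, 0.56,
                advection = c(freestream, incline_vy),
                formation_phase = 0.44, standoff = 0.012, n_feed = 1,
                label = "S1"),
    vortex_spec(+gamma_primary, core, 0.81,
                advection = c(freestream, 0),
                formation_phase = 0.64, standoff = 0.020, label = "P1"),
    vortex_spec(-gamma_secondary, 7e-3, 0.06,
                advection = c(freestream, -incline_vy),
                formation_phase = -0.06, standoff = 0.012, n_feed = 1,
                label = "S1n"),
    vortex_spec(-gamma_primary, core, 0.31,
                advection = c(freestream, 0),
                formation_phase = 0.14, standoff = 0.020, label = "P1n"))
  wake_scenario(case, vortices = vortices, noise_sigma = noise_sigma,
                n_phases = n_phases, te_dwell_fraction = 0.3, seed = seed,
                label = "case1-like")
}

#' @rdname scenario_case4_like
#' @param shed_phase scripted primary shedding time t/T.
#' @param detach_phase scripted LEV detachment time t/T.
#' @export
scenario_shedding <- function(freestream = 0.0815, seed = 1L,
                              noise_sigma = 2e-4,
                              gamma_primary = 8e-3, gamma_lev = 4e-3,
                              core = 9e-3, shed_phase = 0.70,
                              detach_phase = 0.80, n_phases = 25) {
  case <- motion_case("shedding", theta_T_amp = 3.44, theta_C_amp = 0.18,
                      phi = 0, freq = 1, te_excursion_max = 0.0221,
                      freestream = freestream,
                      tail_length = 0.26, chord = 0.105,
                      body_length = 0.285, kinematic_viscosity = 1e-6)
  adv <- c(freestream, 0)
  vortices <- list(
    vortex_spec(+gamma_primary, core, shed_phase, advection = adv,
                formation_phase = shed_phase - 0.24, standoff = 0.022,
                label = "P1"),
    vortex_spec(-gamma_primary, core, shed_phase - 0.5, advection = adv,
                formation_phase = shed_phase - 0.74, standoff = 0.022,
                label = "P1n"))
  levs <- list(
    lev_spec(-gamma_lev, core, attach_phase = detach_phase - 0.26,
             detach_phase = detach_phase, side = +1,
             post_velocity = c(0.4 * freestream, 0.02), label = "LEV"),
    lev_spec(+gamma_lev, core, attach_phase = detach_phase - 0.76,
             detach_phase = detach_phase - 0.5, side = -1,
             post_velocity = c(0.4 * freestream, 0.02), label = "LEVn"))
  wake_scenario(case, vortices = vortices, levs = levs,
                noise_sigma = noise_sigma, n_phases = n_phases,
                te_dwell_fraction = 0, seed = seed, label = "shedding")
}
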