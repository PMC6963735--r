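# fixtures shared across the suite -- everything is built in code

table1_path <- function() {
  p <- system.file("extdata", "table1_cases.csv", package = "finwake")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", "table1_cases.csv")
  p
}

# a small two-DOF case with explicit geometry for kinematic tests
toy_case <- function(theta_T = 3, theta_C = 5, phi = 70, freq = 1,
                     A = 0.022, U = 0.0815, LT = 0.05, c = 0.04,
                     dT = 0, dC = 0) {
  motion_case("toy", theta_T_amp = theta_T, theta_C_amp = theta_C,
              phi = phi, freq = freq, te_excursion_max = A,
              freestream = U, delta_theta_T = dT, delta_theta_C = dC,
              tail_length = LT, chord = c,
              body_length = 0.285, kinematic_viscosity = 1e-6)
}

# phase series built directly from a velocity function u(x, y), v(x, y)
# (same field at every phase unless fun takes a phase argument)
series_from_fun <- function(ufun, vfun, nx = 41, ny = 41, h = 1e-3,
                            n_phases = 1, freestream = NA_real_, freq = 1,
                            x0 = -(nx - 1) / 2 * h, y0 = -(ny - 1) / 2 * h) {
  x <- x0 + (seq_len(nx) - 1) * h
  y <- y0 + (seq_len(ny) - 1) * h
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  u <- array(0, c(nx, ny, n_phases)); v <- array(0, c(nx, ny, n_phases))
  for (k in seq_len(n_phases)) {
    u[, , k] <- ufun(X, Y); v[, , k] <- vfun(X, Y)
  }
  phase_series(x, y, u, v, phases = (seq_len(n_phases) - 1) / n_phases,
               freestream = freestream, freq = freq, spacing = h)
}

# single Lamb-Oseen vortex series (one phase), centred in the grid
lamb_oseen_series <- function(gamma = 2e-3, rc = 9e-3, h = 1.78e-3,
                              half_cells = 45, center = c(0, 0),
                              freestream = NA_real_) {
  n <- 2 * half_cells + 1
  series_from_fun(
    function(X, Y) lamb_oseen_velocity(gamma, rc, center, X, Y)$u,
    function(X, Y) lamb_oseen_velocity(gamma, rc, center, X, Y)$v,
    nx = n, ny = n, h = h, freestream = freestream)
}

# 20x20 reference frame pattern used by the phase-averaging noise check
base_big <- function(b) matrix(sin(b / 3) + outer(1:20, 1:20) / 400, 20, 20)
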