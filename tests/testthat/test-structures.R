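q_omega_of <- function(s) list(q = q_criterion_2d(s, 1),
                               omega = vorticity_z(s, 1))

test_that("structure extraction finds isolated vortices and partitions nodes", {
  # all-subthreshold field
  s0 <- series_from_fun(function(X, Y) X * 0 + 0.01, function(X, Y) X * 0)
  qo0 <- q_omega_of(s0)
  expect_equal(extract_structures(qo0$q, qo0$omega, 1), list())

  s1 <- lamb_oseen_series(gamma = 2e-3, rc = 9e-3, half_cells = 35)
  qo1 <- q_omega_of(s1)
  st1 <- extract_structures(qo1$q, qo1$omega, 1)
  expect_length(st1, 1)
  expect_lt(sqrt(sum(st1[[1]]$centroid^2)), s1$spacing)  # true centre (0,0)
  expect_equal(st1[[1]]$sign, 1)
  expect_equal(st1[[1]]$area, nrow(st1[[1]]$nodes) * s1$spacing^2)

  # two opposite-sign vortices separated by > 6 rc
  rc <- 8e-3; d <- 3.5 * rc
  s2 <- series_from_fun(
    function(X, Y) lamb_oseen_velocity(2e-3, rc, c(-d, 0), X, Y)$u +
      lamb_oseen_velocity(-2e-3, rc, c(d, 0), X, Y)$u,
    function(X, Y) lamb_oseen_velocity(2e-3, rc, c(-d, 0), X, Y)$v +
      lamb_oseen_velocity(-2e-3, rc, c(d, 0), X, Y)$v,
    nx = 81, ny = 51, h = 1.78e-3)
  qo2 <- q_omega_of(s2)
  st2 <- extract_structures(qo2$q, qo2$omega, 1)
  expect_length(st2, 2)
  expect_equal(sort(vapply(st2, `[[`, numeric(1), "sign")), c(-1, 1))

  # partition: every above-threshold node in exactly one structure
  B <- !qo2$q$mask & qo2$q$values >= 1
  expect_equal(sum(vapply(st2, function(s) nrow(s$nodes), integer(1))),
               sum(B, na.rm = TRUE))
  # circulation sum equals the integral over the thresholded set
  expect_equal(sum(vapply(st2, `[[`, numeric(1), "circulation")),
               sum(qo2$omega$values[B]) * s2$spacing^2, tolerance = 1e-12)
})

test_that("default threshold is the configured fraction of the global maximum", {
  s <- lamb_oseen_series(gamma = 2e-3, rc = 9e-3, half_cells = 25)
  q <- q_criterion_2d(s, 1)
  expect_equal(default_threshold(q, 0.01),
               0.01 * max(q$values, na.rm = TRUE))
  # a field whose maximum is 100 gives the 1 s^-2 floor of the 1 % rule
  q100 <- q
  q100$values <- q$values * (100 / max(q$values, na.rm = TRUE))
  expect_equal(default_threshold(q100, 0.01), 1)
  # monotone in the fraction; fraction 1 keeps at most the peak ties
  expect_lt(default_threshold(q, 0.01), default_threshold(q, 0.05))
  om <- vorticity_z(s, 1)
  st <- extract_structures(q, om, default_threshold(q, 1))
  expect_lte(sum(vapply(st, function(x) nrow(x$nodes), integer(1))), 2)
  q0 <- q; q0$values[] <- 0
  expect_error(default_threshold(q0), "no positive")
})

test_that("attachment requires contact within one grid cell of the mask", {
  nx <- 30; ny <- 30
  fin <- matrix(FALSE, nx, ny); fin[1:3, ] <- TRUE
  touching <- structure(list(nodes = cbind(4:6, 10:12)),
                        class = "vortex_structure")
  apart <- structure(list(nodes = cbind(7:9, 10:12)),
                     class = "vortex_structure")
  expect_true(is_attached(touching, fin))
  expect_false(is_attached(apart, fin))
  expect_error(is_attached(touching, matrix(FALSE, nx, ny)), "empty")
})

test_that("raising the Q threshold can only detach, never attach", {
  # vortex core near a straight wall mask
  rc <- 8e-3
  s <- series_from_fun(
    function(X, Y) lamb_oseen_velocity(3e-3, rc, c(0, 1.2 * rc), X, Y)$u,
    function(X, Y) lamb_oseen_velocity(3e-3, rc, c(0, 1.2 * rc), X, Y)$v,
    nx = 61, ny = 61, h = 1.78e-3)
  fin <- matrix(FALSE, 61, 61); fin[, 1:28] <- FALSE; fin[, 1:25] <- TRUE
  s$mask[, , 1] <- fin
  s$u[, , 1][fin] <- NA; s$v[, , 1][fin] <- NA
  qo <- q_omega_of(s)
  prev <- TRUE
  for (thr in c(1, 3, 10, 30)) {
    st <- extract_structures(qo$q, qo$omega, thr)
    att <- if (length(st)) is_attached(st[[1]], fin) else FALSE
    expect_false(att && !prev)   # no re-attachment as the contour shrinks
    prev <- att
  }
})

test_that("tracking follows advecting vortices without identity swaps", {
  # two same-sign vortices far apart, advecting with the freestream
  U <- 0.08; h <- 1.78e-3; rc <- 8e-3
  n_ph <- 10
  x <- (0:120) * h; y <- (0:60) * h
  X <- matrix(x, 121, 61); Y <- matrix(y, 121, 61, byrow = TRUE)
  u <- array(0, c(121, 61, n_ph)); v <- u
  for (k in 1:n_ph) {
    t <- (k - 1) / n_ph
    c1 <- c(0.02 + U * t * 0.5, 0.03)
    c2 <- c(0.02 + U * t * 0.5, 0.08)
    uv1 <- lamb_oseen_velocity(2e-3, rc, c1, X, Y)
    uv2 <- lamb_oseen_velocity(2e-3, rc, c2, X, Y)
    u[, , k] <- uv1$u + uv2$u; v[, , k] <- uv1$v + uv2$v
  }
  s <- phase_series(x, y, u, v, phases = (0:(n_ph - 1)) / n_ph,
                    freestream = U, freq = 1, spacing = h)
  sb <- structures_by_phase(s)
  tr <- track_structures(sb$structures, s$phases,
                         advection_guess = c(U * 0.5, 0))
  long <- Filter(function(t) length(t$phases) == n_ph, tr)
  expect_length(long, 2)
  for (t in long) expect_lt(max(abs(diff(t$centroids[, 2]))), 2 * h)
})

test_that("trajectory fitting recovers straight paths and their angles", {
  mk_track <- function(P) structure(list(centroids = P), class = "vortex_track")
  P1 <- cbind(seq(0, 0.1, length.out = 6), rep(0.02, 6))
  f1 <- trajectory_fit(mk_track(P1))
  expect_equal(f1$angle, 0, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1)

  xx <- seq(0, 0.1, length.out = 5)
  f2 <- trajectory_fit(mk_track(cbind(xx, xx / 2)))
  expect_equal(f2$angle, atan(0.5) * 180 / pi, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1)

  expect_error(trajectory_fit(mk_track(P1[1:2, ])), "at least 3")
})

test_that("shedding-phase estimation returns NA off the TE and scales with bin width", {
  # synthetic track far from the TE
  mk <- function(phases, xy) structure(list(
    phases = phases,
    structures = lapply(seq_along(phases), function(i) {
      structure(list(node_xy = matrix(xy[i, ], 1, 2),
                     centroid = xy[i, ]), class = "vortex_structure")
    }),
    centroids = xy, sign = 1), class = "vortex_track")
  ph25 <- seq(0.4, 0.8, by = 0.04)
  far <- mk(ph25, cbind(0.2 + ph25, 0.05))
  te <- cbind(rep(0.04, length(ph25)), rep(0, length(ph25)))
  expect_true(is.na(shedding_phase(far, te, 1.78e-3,
                                   te_phases = ph25)$shed_phase))

  # attached for three bins then departs: estimate at the bin midpoint,
  # uncertainty = half the bin width at both resolutions
  near_xy <- rbind(matrix(c(0.041, 0), 3, 2, byrow = TRUE),
                   cbind(0.1 + (1:5) * 0.01, 0))
  tr25 <- mk(seq(0.5, by = 0.04, length.out = 8), near_xy)
  e25 <- shedding_phase(tr25, cbind(rep(0.04, 8), rep(0, 8)), 1.78e-3,
                        te_phases = tr25$phases)
  tr12 <- mk(seq(0.5, by = 0.08, length.out = 8), near_xy)
  e12 <- shedding_phase(tr12, cbind(rep(0.04, 8), rep(0, 8)), 1.78e-3,
                        te_phases = tr12$phases)
  expect_equal(e25$shed_phase, 0.5 + 2 * 0.04 + 0.02)
  expect_equal(e12$uncertainty, 2 * e25$uncertainty)
})

test_that("per-vortex circulation is recovered within 10 % once shed and resolved", {
  n_ok <- 0; n_tot <- 0
  for (seed in 1:3) {
    sc <- scenario_shedding(seed = seed)
    g <- generate_wake(sc); s <- g$series
    k <- which.min(abs(s$phases - 0.92))    # P1+ shed at 0.70, well clear
    q <- q_criterion_2d(s, k); om <- vorticity_z(s, k)
    st <- extract_structures(q, om, 1)
    # the P1+ structure: positive, downstream of the TE, upstream of old copies
    cand <- Filter(function(x) x$sign > 0 && x$centroid[1] > 0.05 &&
                     x$centroid[1] < 0.10, st)
    expect_gte(length(cand), 1)
    gam <- vortex_circulation(cand[[1]], om, omega_threshold = 1)
    n_tot <- n_tot + 1
    if (abs(gam - 8e-3) / 8e-3 < 0.10) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, n_tot)
})

test_that("scripted LEV detachment flips the attachment flag at the scripted phase", {
  sc <- scenario_shedding(seed = 21)
  g <- generate_wake(sc); s <- g$series
  sb <- structures_by_phase(s)
  att <- rep(NA, length(s$phases))
  for (k in which(s$phases >= 0.56 - 1e-9)) {
    cand <- Filter(function(st) st$sign < 0 && st$centroid[1] < 0.03,
                   sb$structures[[k]])
    if (length(cand)) {
      lev <- cand[[which.max(vapply(cand, `[[`, numeric(1), "peak_q"))]]
      att[k] <- is_attached(lev, s$mask[, , k])
    }
  }
  first_detached <- s$phases[which(!is.na(att) & !att)[1]]
  expect_lte(abs(first_detached - 0.80), 0.04 + 1e-9)
  expect_true(all(att[s$phases >= 0.56 & s$phases <= 0.76], na.rm = TRUE))
})
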