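#' Moving rectangular integration region for circulation histories
#'
#' The trailing-edge circulation budget is evaluated inside a rectangle
#' whose upstream and transverse boundaries are held stationary while the
#' downstream boundary moves with the approximate vortex advection speed,
#' so that circulation shed earlier (and advecting with the wake) neither
#' leaves nor newly enters the region.
#'
#' @param upstream_x fixed upstream boundary (m).
#' @param y_min,y_max fixed transverse boundaries (m), \code{y_min < y_max};
#'   tall enough to capture the full transverse extent of the wake.
#' @param downstream_x0 initial downstream boundary (m), \code{>=
#'   upstream_x}.
#' @param advection_speed downstream-boundary speed U_adv (m/s), typically
#'   the freestream or a speed fitted from vortex tracks.
#' @param start_phase t/T at which the history starts (may correspond to
#'   the onset of vorticity production slightly before the nominal
#'   half-cycle).
#' @return An object of class \code{integration_region}.
#' @export
integration_region <- function(upstream_x, y_min, y_max, downstream_x0,
                               advection_speed, start_phase = 0) {
  if (y_min >= y_max) stop("y_min must be < y_max")
  if (downstream_x0 < upstream_x)
    stop("downstream_x0 must be >= upstream_x")
  structure(list(upstream_x = upstream_x, y_min = y_min, y_max = y_max,
                 downstream_x0 = downstream_x0,
                 advection_speed = advection_speed,
                 start_phase = start_phase),
            class = "integration_region")
}

#' Rectangle occupied by an integration region at a given phase
#'
#' @param region an \code{\link{integration_region}}.
#' @param phase t/T; values below \code{start_phase} are unwrapped
#'   cyclically (phase + 1), values at or above it are used as-is, so an
#'   unwrapped multi-cycle phase axis is supported.
#' @param period cycle period (s).
#' @param domain optional \code{c(x0, x1, y0, y1)} to clip against; the
#'   result then carries \code{clipped = TRUE} when clipping occurred.
#' @return A list \code{(x0, x1, y0, y1, clipped)}.
#' @export
region_at_phase <- function(region, phase, period = 1, domain = NULL) {
  elapsed <- phase - region$start_phase
  if (elapsed < 0) elapsed <- elapsed + 1
  x1 <- region$downstream_x0 + region$advection_speed * elapsed * period
  r <- list(x0 = region$upstream_x, x1 = x1,
            y0 = region$y_min, y1 = region$y_max, clipped = FALSE)
  if (r$x1 < r$x0) stop("region is inverted (negative advection too fast)")
  if (!is.null(domain)) {
    cl <- c(r$x0 < domain[1], r$x1 > domain[2],
            r$y0 < domain[3], r$y1 > domain[4])
    r$x0 <- max(r$x0, domain[1]); r$x1 <- min(r$x1, domain[2])
    r$y0 <- max(r$y0, domain[3]); r$y1 <- min(r$y1, domain[4])
    r$clipped <- any(cl)
  }
  r
}

#' Circulation production history at the trailing edge
#'
#' Per phase, the positive and negative circulation inside the moving
#' integration region, computed as area integrals of the spanwise vorticity
#' above a magnitude threshold:
#' \code{Gamma+ = sum(omega >= +thr) * dA} and
#' \code{Gamma- = |sum(omega <= -thr)| * dA}, masked nodes excluded. The
#' phase axis is unwrapped from \code{region$start_phase} over
#' \code{n_cycles} cycles (the phase-averaged series is periodic, so phases
#' beyond 1 reuse the corresponding bin while the downstream boundary keeps
#' advecting).
#'
#' @param series a \code{\link{phase_series}}.
#' @param region an \code{\link{integration_region}}.
#' @param threshold vorticity magnitude threshold, 1/s (default 1).
#' @param omega optional precomputed list of per-phase vorticity
#'   \code{\link{scalar_field}}s (else computed here).
#' @param n_cycles number of cycles of history.
#' @return An object of class \code{circulation_history}: \code{phase}
#'   (unwrapped t/T), \code{gamma_pos}, \code{gamma_neg} (m^2/s, both
#'   non-negative), \code{threshold}, \code{region}.
#' @export
circulation_history <- function(series, region, threshold = 1,
                                omega = NULL, n_cycles = 1) {
  n <- length(series$phases)
  if (is.null(omega))
    omega <- lapply(seq_len(n), function(k) vorticity_z(series, k))
  domain <- c(series$x[1], series$x[length(series$x)],
              series$y[1], series$y[length(series$y)])
  if (region$upstream_x > domain[2] || region$y_min > domain[4] ||
      region$y_max < domain[3])
    stop("integration region lies outside the domain")
  period <- 1 / series$freq
  h <- series$spacing
  start_bin <- which.min(abs(series$phases - region$start_phase %% 1))[1]
  ks <- (rep(seq_len(n) , n_cycles))[((start_bin - 1) + seq_len(n * n_cycles) - 1) %% n + 1]
  ph <- region$start_phase + (seq_len(n * n_cycles) - 1) / n
  gp <- numeric(length(ks)); gn <- numeric(length(ks))
  for (i in seq_along(ks)) {
    om <- omega[[ks[i]]]
    r <- region_at_phase(region, ph[i], period, domain = domain)
    ix <- series$x >= r$x0 & series$x <= r$x1
    iy <- series$y >= r$y0 & series$y <= r$y1
    w <- om$values[ix, iy, drop = FALSE]
    w[om$mask[ix, iy]] <- NA
    gp[i] <- sum(w[!is.na(w) & w >= threshold]) * h^2
    gn[i] <- abs(sum(w[!is.na(w) & w <= -threshold]) * h^2)
  }
  structure(list(phase = ph, gamma_pos = gp, gamma_neg = gn,
                 threshold = threshold, region = region),
            class = "circulation_history")
}

#' @export
print.circulation_history <- function(x, ...) {
  cat(sprintf(
    "<circulation_history: t/T %.2f..%.2f, max Gamma+ %.3e, max Gamma- %.3e m^2/s (|omega| >= %g 1/s)>\n",
    min(x$phase), max(x$phase), max(x$gamma_pos), max(x$gamma_neg),
    x$threshold))
  invisible(x)
}

#' Per-half-cycle circulation totals from a history
#'
#' Half-cycles are delimited by the trailing edge reaching an amplitude
#' maximum or minimum (velocity zero crossings of the TE trace). For each
#' half-cycle and each sign, the total circulation produced is the maximum
#' of the corresponding signed history over a window running from the
#' half-cycle start to \code{lag} cycles past its end — the history rises
#' during the half-cycle, reaches its maximum and then plateaus, and the
#' maximum at the beginning of the plateau is the half-cycle total. A
#' history that never rises above its window-start value is flagged.
#'
#' @param history a \code{\link{circulation_history}}.
#' @param te a \code{\link{te_trace}} on the same cycle convention.
#' @param lag window extension past the half-cycle end, cycles.
#' @return A data frame with columns \code{start}, \code{end} (t/T),
#'   \code{sign}, \code{total} (m^2/s), \code{phase_at_max}, and
#'   \code{no_rise}.
#' @export
half_cycle_totals <- function(history, te, lag = 0.25) {
  ext <- sort(te$extrema_phases)
  if (!length(ext)) stop("TE trace has no extrema")
  lo <- min(history$phase); hi <- max(history$phase)
  # unwrap the extremum grid across the cycles spanned by the history
  bounds <- sort(unique(c(outer(ext, floor(lo - 1):ceiling(hi + 1), `+`))))
  rows <- list()
  for (i in seq_len(length(bounds) - 1)) {
    b0 <- bounds[i]; b1 <- bounds[i + 1]
    if (b0 < lo - 1e-9 || b1 + lag > hi + 1e-9) next
    win <- history$phase >= b0 - 1e-9 & history$phase <= b1 + lag + 1e-9
    if (sum(win) < 2) next
    for (sg in c(1, -1)) {
      g <- if (sg > 0) history$gamma_pos[win] else history$gamma_neg[win]
      imax <- which.max(g)
      rows[[length(rows) + 1L]] <- data.frame(
        start = b0, end = b1, sign = sg, total = g[imax],
        phase_at_max = history$phase[win][imax],
        no_rise = g[imax] <= g[1] + 1e-12)
    }
  }
  if (!length(rows)) stop("history does not span one full half-cycle plus lag")
  do.call(rbind, rows)
}

#' Compare trailing-edge excursion amplitudes of two cases
#'
#' Percentage by which the larger maximum TE excursion exceeds the smaller:
#' \code{100 (A_max - A_min) / A_min}, reported to one decimal.
#'
#' @param case_a,case_b \code{\link{motion_case}} objects with positive A.
#' @return Percent difference (one decimal).
#' @export
compare_excursions <- function(case_a, case_b) {
  A <- c(case_a$te_excursion_max, case_b$te_excursion_max)
  if (any(A <= 0)) stop("both cases need A > 0")
  round(100 * (max(A) - min(A)) / min(A), 1)
}

#' Half-cycle circulation totals of a synthetic or measured series
#'
#' Convenience pipeline for the trailing-edge circulation budget: builds
#' the moving integration region just downstream of the trailing edge
#' (upstream boundary fixed near the TE, transverse boundaries spanning the
#' domain, downstream boundary advecting at \code{u_adv}), starting
#' \code{onset_lead} cycles before the half-cycle begins (vorticity
#' production starts slightly before the TE reverses), computes the
#' history, and extracts per-half-cycle totals.
#'
#' @param series a \code{\link{phase_series}}.
#' @param te a \code{\link{te_trace}}.
#' @param te_x x-position of the trailing edge (m).
#' @param u_adv advection speed for the downstream boundary; default the
#'   recorded freestream.
#' @param threshold vorticity threshold (1/s).
#' @param onset_lead cycles before the half-cycle start at which the
#'   history begins.
#' @param margin upstream gap between the TE and the fixed upstream
#'   boundary (m).
#' @param lag plateau window extension, cycles.
#' @param half_start t/T of the half-cycle whose totals are wanted; default
#'   the first TE extremum at or after 0.5.
#' @return A list with \code{totals} (the half-cycle rows) and
#'   \code{history}.
#' @export
half_cycle_circulation <- function(series, te, te_x, u_adv = NULL,
                                   threshold = 1, onset_lead = 0.12,
                                   margin = 2e-3, lag = 0.25,
                                   half_start = NULL) {
  if (is.null(u_adv)) u_adv <- series$freestream
  ext <- sort(te$extrema_phases)
  if (is.null(half_start))
    half_start <- if (any(ext >= 0.5)) min(ext[ext >= 0.5]) else ext[1]
  region <- integration_region(
    upstream_x = te_x + margin,
    y_min = series$y[1], y_max = series$y[length(series$y)],
    downstream_x0 = te_x + margin + 0.02,
    advection_speed = u_adv,
    start_phase = half_start - onset_lead)
  hist <- circulation_history(series, region, threshold = threshold,
                              n_cycles = 2)
  tot <- half_cycle_totals(hist, te, lag = lag)
  half_end <- half_start + 0.5
  tot_half <- tot[abs(tot$start - half_start) < 1e-6 &
                    abs(tot$end - half_end) < 1e-6, , drop = FALSE]
  list(totals = tot_half, all_totals = tot, history = hist,
       region = region)
}
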