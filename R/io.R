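CASE_TABLE_COLUMNS <- c("case", "SG", "KG", "theta_T_amp", "dtheta_T",
                        "theta_C_amp", "dtheta_C", "phi", "A_mm", "U_mm_s",
                        "f_hz", "St")
SERIES_SCHEMA <- "finwake-phase-series v1"

#' Read a kinematic case table
#'
#' Parses a delimited case table (one row per experimental case) with
#' columns \code{case, SG, KG, theta_T_amp, dtheta_T, theta_C_amp,
#' dtheta_C, phi, A_mm, U_mm_s, f_hz, St} and optional geometry columns
#' \code{LT_m, c_m, L_m, nu_m2_s}. Lengths are converted to metres
#' (A, U are tabulated in mm and mm/s); angles stay in degrees. A missing
#' phase offset (\code{"-"}, blank or NA, used when one amplitude is zero)
#' is read as 0. The Strouhal number is recomputed from f, A and U and
#' compared with the stored \code{St} column; mismatches beyond 0.001 are
#' reported with a warning and recorded in the \code{st_mismatch} column.
#'
#' @param path path to the delimited file (comma-separated).
#' @return An object of class \code{case_table}: a list with \code{cases}
#'   (named list of \code{\link{motion_case}}) and \code{table} (the parsed
#'   data frame with recomputed \code{St_recomputed} and logical
#'   \code{st_mismatch}).
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stop("case table not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("schema error: case table is empty")
  missing_cols <- setdiff(CASE_TABLE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$case))
    stop("validation error: duplicated case id(s): ",
         paste(unique(df$case[duplicated(df$case)]), collapse = ", "))
  df$phi[df$phi %in% c("-", "")] <- "0"
  num_cols <- setdiff(CASE_TABLE_COLUMNS, "case")
  for (cc in num_cols) {
    val <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(val) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                   df[[cc]][bad[1]], cc, bad[1]))
    df[[cc]] <- val
  }
  df$St_recomputed <- df$f_hz * (df$A_mm / 1000) / (df$U_mm_s / 1000)
  df$st_mismatch <- abs(df$St_recomputed - df$St) > 0.001
  if (any(df$st_mismatch))
    warning(sprintf("stored St disagrees with f*A/U beyond 0.001 for case(s): %s",
                    paste(df$case[df$st_mismatch], collapse = ", ")))
  opt <- function(col, row, default) if (col %in% names(df))
    as.numeric(df[[col]][row]) else default
  cases <- lapply(seq_len(nrow(df)), function(i) {
    motion_case(df$case[i],
                strouhal_group = df$SG[i], kinematic_group = df$KG[i],
                theta_T_amp = df$theta_T_amp[i],
                theta_C_amp = df$theta_C_amp[i],
                delta_theta_T = df$dtheta_T[i],
                delta_theta_C = df$dtheta_C[i],
                phi = df$phi[i], freq = df$f_hz[i],
                te_excursion_max = df$A_mm[i] / 1000,
                freestream = df$U_mm_s[i] / 1000,
                tail_length = opt("LT_m", i, NA_real_),
                chord = opt("c_m", i, NA_real_),
                body_length = opt("L_m", i, NA_real_),
                kinematic_viscosity = opt("nu_m2_s", i, NA_real_))
  })
  names(cases) <- as.character(df$case)
  structure(list(cases = cases, table = df), class = "case_table")
}

#' @export
print.case_table <- function(x, ...) {
  cat(sprintf("<case_table: %d cases; %d St mismatch(es)>\n",
              length(x$cases), sum(x$table$st_mismatch)))
  print(x$table[, c("case", "SG", "KG", "A_mm", "U_mm_s", "f_hz", "St",
                    "St_recomputed")])
  invisible(x)
}

#' Read or write an angle trace
#'
#' Two-column delimited text (\code{t_s, angle_deg}).
#' @param path file path.
#' @param which "tail" or "fin".
#' @export
read_angle_trace <- function(path, which = "tail") {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "angle_deg") %in% names(df)))
    stop("angle trace needs columns t_s, angle_deg")
  angle_trace(df$t_s, df$angle_deg, which = which)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write / read a phase series as a self-describing text container
#'
#' A single delimited text file carrying a versioned schema line, a JSON
#' attribute header (grid, phases, freestream, frequency, plane offset,
#' spacing) and a long-format node table (phase index, grid indices, u, v,
#' mask). Values are written with 17 significant digits so a
#' write-then-read roundtrip reproduces the arrays bit-for-bit.
#'
#' @param series a \code{\link{phase_series}}.
#' @param path output path.
#' @return \code{write_phase_series} returns \code{path} invisibly;
#'   \code{read_phase_series} returns the \code{\link{phase_series}}.
#' @export
write_phase_series <- function(series, path) {
  nx <- length(series$x); ny <- length(series$y)
  np <- length(series$phases)
  attrs <- list(schema = SERIES_SCHEMA, nx = nx, ny = ny, n_phases = np,
                x0 = series$x[1], y0 = series$y[1],
                spacing = series$spacing,
                phases = series$phases,
                freestream = series$freestream, freq = series$freq,
                plane_z = series$plane_z)
  hdr <- c(paste0("# ", SERIES_SCHEMA),
           paste0("# attrs: ",
                  jsonlite::toJSON(attrs, auto_unbox = TRUE, digits = NA)))
  grid <- expand.grid(i = seq_len(nx), j = seq_len(ny),
                      k = seq_len(np))
  dt <- data.table::data.table(
    k = grid$k, i = grid$i, j = grid$j,
    u = fmt_full(as.vector(series$u)),
    v = fmt_full(as.vector(series$v)),
    mask = as.integer(as.vector(series$mask)))
  writeLines(hdr, path)
  data.table::fwrite(dt, path, append = TRUE, sep = "\t",
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_phase_series
#' @export
read_phase_series <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!grepl(SERIES_SCHEMA, hdr[1], fixed = TRUE))
    stop("read error: not a ", SERIES_SCHEMA, " file: ", path)
  attrs <- jsonlite::fromJSON(sub("^# attrs: ", "", hdr[2]))
  dt <- data.table::fread(path, skip = 2, sep = "\t")
  need <- c("k", "i", "j", "u", "v", "mask")
  if (!all(need %in% names(dt)))
    stop("read error: missing variable(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  nx <- attrs$nx; ny <- attrs$ny; np <- attrs$n_phases
  if (nrow(dt) != nx * ny * np)
    stop("read error: node table size disagrees with header for variable u")
  ord <- order(dt$k, dt$j, dt$i)
  u <- array(as.numeric(dt$u[ord]), c(nx, ny, np))
  v <- array(as.numeric(dt$v[ord]), c(nx, ny, np))
  mask <- array(dt$mask[ord] == 1L, c(nx, ny, np))
  phase_series(x = attrs$x0 + (seq_len(nx) - 1) * attrs$spacing,
               y = attrs$y0 + (seq_len(ny) - 1) * attrs$spacing,
               u = u, v = v, mask = mask, phases = attrs$phases,
               freestream = attrs$freestream, freq = attrs$freq,
               spacing = attrs$spacing, plane_z = attrs$plane_z)
}

#' Export / import per-phase delimited velocity tables
#'
#' Generic planar-PIV ASCII dialect: one file per phase with columns
#' \code{x, y, u, v}, written at \code{digits} significant digits.
#'
#' @param series a \code{\link{phase_series}}.
#' @param dir output directory (created if needed).
#' @param digits significant digits for the text export.
#' @return File paths (write) or a \code{\link{phase_series}} (read).
#' @export
write_piv_ascii <- function(series, dir, digits = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nx <- length(series$x); ny <- length(series$y)
  paths <- character(length(series$phases))
  for (k in seq_along(series$phases)) {
    df <- data.frame(
      x = rep(series$x, ny), y = rep(series$y, each = nx),
      u = signif(as.vector(series$u[, , k]), digits),
      v = signif(as.vector(series$v[, , k]), digits))
    paths[k] <- file.path(dir, sprintf("phase_%03d.dat", k))
    utils::write.table(df, paths[k], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

#' @rdname write_piv_ascii
#' @param paths per-phase files in phase order.
#' @param phases t/T of each file.
#' @param freestream,freq,plane_z attributes for the result.
#' @export
read_piv_ascii <- function(paths, phases = NULL, freestream = NA_real_,
                           freq = NA_real_, plane_z = 0) {
  if (is.null(phases)) phases <- (seq_along(paths) - 1) / length(paths)
  first <- utils::read.table(paths[1], header = TRUE, sep = "\t")
  x <- sort(unique(first$x)); y <- sort(unique(first$y))
  nx <- length(x); ny <- length(y)
  u <- array(NA_real_, c(nx, ny, length(paths))); v <- u
  for (k in seq_along(paths)) {
    df <- utils::read.table(paths[k], header = TRUE, sep = "\t")
    ord <- order(df$y, df$x)
    u[, , k] <- df$u[ord]; v[, , k] <- df$v[ord]
  }
  phase_series(x, y, u, v, mask = array(is.na(u), dim(u)), phases = phases,
               freestream = freestream, freq = freq, plane_z = plane_z)
}

#' Write ground truth or track tables as JSON
#'
#' @param x a ground-truth list (from \code{\link{generate_wake}}) or a
#'   list of tracks.
#' @param path output path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a wake-scenario configuration file
#'
#' YAML configuration naming a preset (\code{case4_like}, \code{case1_like}
#' or \code{shedding}) plus overrides for its arguments, e.g.:
#' \preformatted{preset: case4_like
#' seed: 7
#' freestream: 0.0595
#' noise_sigma: 0.0002}
#'
#' @param path YAML file path.
#' @return A \code{\link{wake_scenario}}.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$preset)) stop("scenario config needs a 'preset' key")
  fun <- switch(cfg$preset,
                case4_like = scenario_case4_like,
                case1_like = scenario_case1_like,
                shedding = scenario_shedding,
                stop("unknown preset: ", cfg$preset))
  args <- cfg[setdiff(names(cfg), "preset")]
  do.call(fun, args)
}

#' Per-case summary report
#'
#' Gathers the per-case nondimensional numbers and, when a phase series is
#' supplied, the wake summaries: half-cycle circulation totals, number of
#' vortex structures at the final phase, and momentum-surplus statistics.
#'
#' @param case a \code{\link{motion_case}}.
#' @param series optional \code{\link{phase_series}} for this case.
#' @param te_x trailing-edge x-position (m), required with \code{series}.
#' @param threshold vorticity threshold for the circulation budget (1/s).
#' @return A one-row data frame.
#' @export
case_report <- function(case, series = NULL, te_x = NULL, threshold = 1) {
  out <- data.frame(case = as.character(case$case_id),
                    St = strouhal(case),
                    Re = tryCatch(reynolds(case), error = function(e) NA_real_))
  if (!is.null(series)) {
    te <- te_trace(case, length(series$phases))
    circ <- half_cycle_circulation(series, te, te_x = te_x,
                                   threshold = threshold)
    pos <- circ$totals[circ$totals$sign > 0, ]
    surp <- momentum_surplus(series)
    sb <- structures_by_phase(series)
    out$gamma_half_cycle <- if (nrow(pos)) pos$total[1] else NA_real_
    out$n_structures_last_phase <- length(sb$structures[[length(sb$structures)]])
    out$surplus_max <- max(surp$values, na.rm = TRUE)
    out$surplus_mean_positive <- mean(surp$values[surp$values > 0], na.rm = TRUE)
  }
  out
}
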