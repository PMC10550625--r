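# Measurement-path plumbing: synthetic velocity/position records, plateau
# fitting of the terminal velocity, CSV round-tripping with '#' metadata
# headers, and YAML configuration.

#' Measurement record
#'
#' A sampled settling record: strictly increasing times plus velocities
#' and/or positions, with metadata (fluid, particle, noise level, seed, true
#' density contrast when synthetic). This is the exchange format of the
#' inverse, density-measurement path.
#'
#' @param times sample times, s (strictly increasing).
#' @param velocities sampled velocities, m/s (optional if positions given).
#' @param positions sampled positions, m (optional if velocities given).
#' @param meta named list of metadata.
#' @return an object of class `measurement_record`.
#' @export
measurement_record <- function(times, velocities = NULL, positions = NULL,
                               meta = list()) {
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (is.null(velocities) && is.null(positions))
    stop("at least one of 'velocities' or 'positions' is required",
         call. = FALSE)
  for (x in list(velocities, positions))
    if (!is.null(x) && length(x) != length(times))
      stop("velocities/positions must match 'times' in length",
           call. = FALSE)
  structure(list(times = times, velocities = velocities,
                 positions = positions, meta = meta),
            class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("Measurement record: %d samples over %.4g s (%s)\n",
              length(x$times), diff(range(x$times)),
              paste(c("velocities", "positions")[
                c(!is.null(x$velocities), !is.null(x$positions))],
                collapse = " + ")))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize a sedimentation measurement record
#'
#' Simulates the dimensional settling trajectory, samples it at the given
#' rate and adds independent Gaussian noise with standard deviation
#' `noise_rel * v_s` to the velocities; position noise is the running
#' integral of the velocity noise (a random walk), as produced by
#' dead-reckoning a noisy velocity signal. Records are reproducible for a
#' fixed seed.
#'
#' @param particle a [spherical_particle()].
#' @param fluid a [fluid_medium()].
#' @param model a [drag_model()].
#' @param duration record length, s.
#' @param rate sampling rate, Hz.
#' @param noise_rel relative velocity-noise level (fraction of `v_s`).
#' @param seed RNG seed recorded in the metadata (default 0).
#' @param window logical: history-window flag passed to the simulator.
#' @param dt simulation step, s. Defaults to `t_r / 20`.
#' @param trajectory optional precomputed `settling_trajectory` for the same
#'   configuration (a caching hook: reuse one simulation across many noise
#'   realizations). Must extend to `duration`.
#' @return a [measurement_record()] with velocities and positions.
#' @export
synthesize_measurement <- function(particle, fluid, model = drag_model(),
                                   duration, rate = 10, noise_rel = 0,
                                   seed = 0, window = TRUE, dt = NULL,
                                   trajectory = NULL) {
  check_positive(duration, "duration")
  check_positive(rate, "rate")
  check_positive(noise_rel, "noise_rel", strict = FALSE)
  if (duration < 1 / rate)
    stop("'duration' is shorter than one sample interval", call. = FALSE)
  tv <- terminal_velocity(particle, fluid, model)
  if (is.null(trajectory)) {
    if (is.null(dt)) dt <- tv$scales$t_r / 20
    trajectory <- simulate_settling_dimensional(particle, fluid, model,
                                                t_end = duration, dt = dt,
                                                window = window)
  }
  if (max(trajectory$t) < duration - 1e-9)
    stop("supplied 'trajectory' is shorter than 'duration'", call. = FALSE)
  ts <- seq(1 / rate, duration, by = 1 / rate)
  v_clean <- approx(trajectory$t, trajectory$v, xout = ts)$y
  l_clean <- approx(trajectory$t, trajectory$l, xout = ts)$y
  set.seed(as.integer(seed))
  v_noise <- if (noise_rel > 0)
    rnorm(length(ts), sd = noise_rel * tv$v_s) else numeric(length(ts))
  v <- v_clean + v_noise
  l <- l_clean + cumsum(v_noise) / rate
  measurement_record(ts, velocities = v, positions = l,
                     meta = list(rho_f = fluid$rho_f, mu_f = fluid$mu_f,
                                 g = fluid$g, d_p = particle$d_p,
                                 model = model$name, noise_rel = noise_rel,
                                 seed = seed,
                                 delta_rho_true = tv$scales$delta_rho,
                                 v_s_true = tv$v_s))
}

#' Extract the terminal velocity from a settling record
#'
#' Fits a linear trend to the trailing `tail_fraction` of the record and
#' declares a plateau when the fitted relative velocity change across that
#' window is below `plateau_rel_slope`; the estimate is the mean tail
#' velocity with its standard error. When the criterion fails, the record
#' was most likely truncated before the particle settled — the central
#' pitfall the settling-time estimates guard against — and the (biased-low)
#' estimate is still returned, flagged unreliable, with a warning.
#'
#' The window is deliberately not shrunk on failure: the slow `1/sqrt(t)`
#' creep of an unsettled particle always looks flat on a short enough
#' window, so only the full tail window is diagnostic.
#'
#' Records carrying only positions are differenced (central differences) to
#' obtain velocities first.
#'
#' @param record a [measurement_record()].
#' @param plateau_rel_slope maximum admissible relative velocity change
#'   across the fitted tail window (default 0.002, i.e. 0.2%).
#' @param tail_fraction fraction of the record used as the tail window,
#'   in (0, 1) (default 0.2).
#' @return an object of class `terminal_fit`: list with `v_s`, `se`,
#'   `reliable`, `rel_slope`, `window_start` (s), `n_samples`. `coef()`
#'   returns the velocity estimate.
#' @export
fit_terminal_velocity <- function(record, plateau_rel_slope = 0.002,
                                  tail_fraction = 0.2) {
  stopifnot(inherits(record, "measurement_record"))
  if (tail_fraction <= 0 || tail_fraction >= 1)
    stop("'tail_fraction' must lie in (0, 1)", call. = FALSE)
  t <- record$times
  v <- record$velocities
  if (is.null(v)) {
    x <- record$positions
    n <- length(t)
    v <- c((x[2] - x[1]) / (t[2] - t[1]),
           (x[-(1:2)] - x[-((n - 1):n)]) / (t[-(1:2)] - t[-((n - 1):n)]),
           (x[n] - x[n - 1]) / (t[n] - t[n - 1]))
  }
  n <- length(t)
  i0 <- max(1L, n - ceiling(tail_fraction * n) + 1L)
  if (n - i0 + 1L < 3L)
    stop("record too short to fit a plateau", call. = FALSE)
  idx <- i0:n
  mean_v <- mean(v[idx])
  rel_slope <- if (mean_v == 0) 0 else {
    tt <- t[idx]
    abs(unname(coef(lm(v[idx] ~ tt))[2]) * (t[n] - t[i0]) / mean_v)
  }
  reliable <- rel_slope < plateau_rel_slope
  if (!reliable)
    warning(sprintf(paste0(
      "no velocity plateau (relative tail slope %.3g >= %.3g): the ",
      "particle had likely not settled when the record ended; estimate ",
      "flagged unreliable"), rel_slope, plateau_rel_slope),
      call. = FALSE)
  structure(list(v_s = mean_v, se = sd(v[idx]) / sqrt(length(idx)),
                 reliable = reliable, rel_slope = rel_slope,
                 window_start = t[i0], n_samples = length(idx)),
            class = "terminal_fit")
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf("Terminal velocity fit: v_s = %.6g m/s (se %.2g, %d samples%s)\n",
              x$v_s, x$se, x$n_samples,
              if (x$reliable) "" else ", UNRELIABLE: no plateau"))
  invisible(x)
}

#' @export
coef.terminal_fit <- function(object, ...) c(v_s = object$v_s)

# ---- CSV / config I/O -----------------------------------------------------

#' Write / read a measurement record as CSV
#'
#' Comma-separated, '.' decimal, UTF-8, with '#'-prefixed `key=value`
#' metadata header lines followed by a `t_s,v_m_per_s,l_m` table. The two
#' functions round-trip each other.
#'
#' @param record a [measurement_record()].
#' @param path file path.
#' @return `write_measurement_csv` returns `path` invisibly;
#'   `read_measurement_csv` returns a [measurement_record()].
#' @export
write_measurement_csv <- function(record, path) {
  stopifnot(inherits(record, "measurement_record"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(record$meta))
    writeLines(sprintf("# %s=%s", k,
                       format(record$meta[[k]], digits = 17)), con)
  df <- data.frame(t_s = record$times)
  if (!is.null(record$velocities)) df$v_m_per_s <- record$velocities
  if (!is.null(record$positions)) df$l_m <- record$positions
  writeLines(paste(names(df), collapse = ","), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = NA), con,
              sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_measurement_csv
#' @export
read_measurement_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = ",")
  measurement_record(df$t_s,
                     velocities = if ("v_m_per_s" %in% names(df))
                       df$v_m_per_s,
                     positions = if ("l_m" %in% names(df)) df$l_m,
                     meta = meta)
}

#' Read a fluid/particle configuration file
#'
#' YAML with a `fluid:` block (`rho_f`, `mu_f`, `g`) and a `particle:` block
#' (`d_p`, plus `rho_p` or `delta_rho`). Laboratory units are supported via
#' an optional per-block `units:` entry with values among `kg/m3`, `g/cm3`,
#' `Pa.s`, `mPa.s`, `m`, `mm`, `um`. Missing fluid fields fall back to the
#' water defaults of [fluid_medium()].
#'
#' @param path YAML file path.
#' @return a list with elements `fluid` ([fluid_medium()]) and `particle`
#'   ([spherical_particle()]; `NULL` when no particle block is present).
#' @export
read_sedimentation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  conv <- function(x, unit) {
    if (is.null(unit)) return(x)
    switch(unit,
           "kg/m3" = x, "g/cm3" = g_per_cm3(x),
           "Pa.s" = x, "mPa.s" = mPa_s(x),
           "m" = x, "mm" = mm(x), "um" = microns(x),
           stop(sprintf("unknown unit '%s' in config", unit), call. = FALSE))
  }
  fl <- cfg$fluid
  fu <- fl$units
  fluid <- fluid_medium(
    rho_f = conv(if (is.null(fl$rho_f)) 997 else fl$rho_f, fu$rho_f),
    mu_f = conv(if (is.null(fl$mu_f)) 0.89e-3 else fl$mu_f, fu$mu_f),
    g = if (is.null(fl$g)) 9.87 else fl$g)
  particle <- NULL
  if (!is.null(cfg$particle)) {
    pa <- cfg$particle
    pu <- pa$units
    d_p <- conv(pa$d_p, pu$d_p)
    if (!is.null(pa$rho_p))
      particle <- spherical_particle(d_p,
                                     rho_p = conv(pa$rho_p, pu$rho_p),
                                     fluid = NULL)
    else if (!is.null(pa$delta_rho))
      particle <- spherical_particle(d_p,
                                     delta_rho = conv(pa$delta_rho,
                                                      pu$delta_rho),
                                     fluid = fluid)
    else stop("particle block needs 'rho_p' or 'delta_rho'", call. = FALSE)
  }
  list(fluid = fluid, particle = particle)
}
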