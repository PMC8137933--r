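# Steered overdamped-Langevin surrogate of the pulling protocol: a dummy
# particle moves at constant velocity, dragging the peptide coordinate
# through the membrane potential via a harmonic spring; the spring force is
# the steering force. Euler-Maruyama integration; internal units
# kJ mol^-1 (energy), nm (length), ns (time).

KB_KJ_MOL_K <- 0.0083144621

#' Steered-pulling protocol parameters
#'
#' Defaults follow the reference pulling protocol: spring constant 1000
#' (stored numerically; dimensionally kJ mol^-1 nm^-2), constant velocity
#' 1 nm ns^-1, up to 50 ns, five replicas per peptide.
#'
#' @param pull_velocity dummy-atom velocity (nm ns^-1, default 1).
#' @param spring_constant harmonic spring constant (default 1000).
#' @param max_duration pulling cap (ns, default 50).
#' @param time_step integration step (ns, default 0.01).
#' @param friction overdamped friction coefficient (kJ mol^-1 nm^-2 ns,
#'   default 100, i.e. a peptide centre-of-mass diffusivity
#'   D = kT/friction of about 0.025 nm^2 ns^-1 at 300 K).
#' @param temperature thermostat temperature (K, default 300).
#' @param n_replicas replicas per peptide (default 5).
#' @param seed master seed.
#' @return A list of class `smd_protocol`.
#' @export
smd_protocol <- function(pull_velocity = 1, spring_constant = 1000,
                         max_duration = 50, time_step = 0.01,
                         friction = 100, temperature = 300,
                         n_replicas = 5L, seed = 1L) {
  vals <- c(pull_velocity = pull_velocity, spring_constant = spring_constant,
            max_duration = max_duration, time_step = time_step,
            friction = friction, temperature = temperature)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || pull_velocity < 0) {
    stop_validation("protocol parameters must be positive ",
                    "(pull_velocity may be zero)")
  }
  if (max_duration < time_step) {
    stop_validation("max_duration must be >= time_step")
  }
  structure(list(pull_velocity = pull_velocity,
                 spring_constant = spring_constant,
                 max_duration = max_duration, time_step = time_step,
                 friction = friction, temperature = temperature,
                 n_replicas = as.integer(n_replicas),
                 seed = as.integer(seed)),
            class = "smd_protocol")
}

#' @export
print.smd_protocol <- function(x, ...) {
  cat(sprintf(paste0("steered protocol: v = %g nm/ns, k = %g, cap %g ns, ",
                     "dt %g ns, friction %g, T %g K, %d replicas\n"),
              x$pull_velocity, x$spring_constant, x$max_duration,
              x$time_step, x$friction, x$temperature, x$n_replicas))
  invisible(x)
}

new_force_trace <- function(times, forces, extensions, replica = NA_integer_,
                            peptide = NA_character_, protocol = NULL,
                            seed = NA_integer_) {
  if (length(times) == 0L) stop_validation("empty force trace")
  if (length(forces) != length(times) ||
      length(extensions) != length(times)) {
    stop_validation("trace series lengths differ")
  }
  if (any(diff(times) <= 0)) {
    stop_validation("trace times must be strictly increasing")
  }
  structure(list(times = times, forces = forces, extensions = extensions,
                 replica = replica, peptide = peptide, protocol = protocol,
                 seed = seed),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(paste0("force trace%s: %d samples over %.2f ns, ",
                     "max force %.1f kJ/mol/nm\n"),
              if (is.na(x$peptide)) "" else paste0(" (", x$peptide,
                                                  ", replica ", x$replica, ")"),
              length(x$times), max(x$times), max(x$forces)))
  invisible(x)
}

#' Run one steered-pulling replica
#'
#' Overdamped Langevin (Euler-Maruyama) integration of the peptide
#' coordinate `z` under the membrane potential, thermal noise and the
#' spring force `k (z_dummy(t) - z)` with `z_dummy(t) = z0 + v t`. The run
#' terminates when the particle leaves the membrane region (passes the
#' exit coordinate by 0.5 nm) or at `max_duration`. The integration step
#' must satisfy the documented stability bound
#' `dt <= friction / (k + max |U''|)`.
#'
#' @param potential a [membrane_potential()].
#' @param protocol an [smd_protocol()].
#' @param seed integer seed for the thermal noise.
#' @return A `force_trace` whose `forces` equal
#'   `spring_constant * extensions` at every sample.
#' @export
run_steered <- function(potential, protocol, seed = protocol$seed) {
  dt <- protocol$time_step
  gam <- protocol$friction
  k <- protocol$spring_constant
  dt_max <- gam / (k + max_curvature(potential))
  if (dt > dt_max) {
    stop_validation(sprintf(
      "time_step %g exceeds stability bound %g = friction / (k + max|U''|)",
      dt, dt_max))
  }
  n_steps <- floor(protocol$max_duration / dt)
  noise_amp <- sqrt(2 * KB_KJ_MOL_K * protocol$temperature * dt / gam)
  xi <- with_seed(seed, stats::rnorm(n_steps))
  z0 <- potential$entry - 1
  exit_at <- if (is.finite(potential$exit)) potential$exit + 0.5 else Inf
  z <- z0
  times <- numeric(n_steps)
  forces <- numeric(n_steps)
  exts <- numeric(n_steps)
  n_used <- 0L
  for (i in seq_len(n_steps)) {
    t <- i * dt
    zd <- z0 + protocol$pull_velocity * t
    ext <- zd - z
    f_spring <- k * ext
    f_pot <- potential_force(potential, z)
    z <- z + dt * (f_spring + f_pot) / gam + noise_amp * xi[i]
    times[i] <- t
    forces[i] <- f_spring
    exts[i] <- ext
    n_used <- i
    if (z > exit_at) break
  }
  idx <- seq_len(n_used)
  new_force_trace(times[idx], forces[idx], exts[idx],
                  replica = NA_integer_, peptide = potential$label,
                  protocol = protocol, seed = seed)
}

#' Run all replicas of the pulling protocol for one peptide
#'
#' Per-replica seeds are derived from the protocol master seed, the peptide
#' id and the replica index, so replicas are independent and individually
#' reproducible.
#'
#' @inheritParams run_steered
#' @param peptide_id id used in seed derivation and trace annotation.
#' @param smooth_time centered running-mean window (ns) applied to each
#'   trace before reading its maximum (default 1 ns), suppressing the
#'   thermal jitter of the spring while preserving the barrier-scale force
#'   peak; set to 0 for raw maxima.
#' @return A list of class `replica_forces`: `peptide`, `max_forces`
#'   (one per replica) and `traces`.
#' @export
steered_replicas <- function(potential, protocol,
                             peptide_id = potential$label,
                             smooth_time = 1) {
  w <- smooth_window_samples(smooth_time, protocol$time_step)
  traces <- vector("list", protocol$n_replicas)
  for (r in seq_len(protocol$n_replicas)) {
    s <- derive_seed(protocol$seed, "smd", peptide_id, r)
    tr <- run_steered(potential, protocol, seed = s)
    tr$replica <- r
    tr$peptide <- peptide_id
    traces[[r]] <- tr
  }
  structure(list(peptide = peptide_id,
                 max_forces = vapply(traces, max_steering_force, 0,
                                     smooth_window = w),
                 traces = traces),
            class = "replica_forces")
}

# odd sample count covering `smooth_time` ns at the protocol time step
smooth_window_samples <- function(smooth_time, time_step) {
  if (smooth_time <= 0) return(0L)
  w <- max(1L, round(smooth_time / time_step))
  as.integer(if (w %% 2L == 0L) w + 1L else w)
}

#' Maximum steering force of a trace
#'
#' Maximum of the raw force series; an optional centered running-mean
#' window (odd width, default off) smooths the series first.
#'
#' @param trace a `force_trace`.
#' @param smooth_window odd window width in samples; 0 disables smoothing.
#' @return The maximum force (kJ mol^-1 nm^-1).
#' @export
max_steering_force <- function(trace, smooth_window = 0L) {
  if (!inherits(trace, "force_trace")) stop_validation("not a force_trace")
  f <- trace$forces
  if (length(f) == 0L) stop_validation("empty force trace")
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) {
      stop_validation("smooth_window must be odd")
    }
    f <- as.numeric(stats::filter(f, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
    f <- f[!is.na(f)]
  }
  max(f)
}

#' Read a steering-force trace (xvg dialect)
#'
#' Two-column whitespace-separated time/force text; a third column, when
#' present, is read as the spring extension. Lines beginning with `#` or
#' `@` are ignored. Times must be strictly increasing; non-numeric fields
#' are reported with their line number.
#'
#' @param path input file.
#' @param spring_constant when given (or recoverable from a
#'   `@ spring_constant` header comment), extensions are back-computed as
#'   force / spring_constant if the file has no extension column.
#' @return A `force_trace`.
#' @export
read_force_trace <- function(path, spring_constant = NULL) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  lines <- readLines(path)
  header_k <- NA_real_
  header_seed <- NA_integer_
  dat <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#") || startsWith(ln, "@")) {
      m <- regmatches(ln, regexec("spring_constant\\s*=?\\s*([0-9.eE+-]+)", ln))[[1]]
      if (length(m) == 2L) header_k <- as.numeric(m[[2]])
      m <- regmatches(ln, regexec("seed\\s*=?\\s*([0-9]+)", ln))[[1]]
      if (length(m) == 2L) header_seed <- as.integer(m[[2]])
      next
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || length(vals) < 2L) {
      stop_io("non-numeric field at line ", i, " of '", path, "'")
    }
    dat[[length(dat) + 1L]] <- vals[seq_len(min(3L, length(vals)))]
  }
  if (length(dat) == 0L) stop_io("no data rows in '", path, "'")
  times <- vapply(dat, `[`, 0, 1L)
  forces <- vapply(dat, `[`, 0, 2L)
  if (any(diff(times) <= 0)) {
    stop_validation("non-monotone times in '", path, "'")
  }
  k <- if (!is.null(spring_constant)) spring_constant else header_k
  exts <- if (all(lengths(dat) >= 3L)) {
    vapply(dat, `[`, 0, 3L)
  } else if (!is.na(k)) {
    forces / k
  } else {
    rep(NA_real_, length(forces))
  }
  new_force_trace(times, forces, exts, seed = header_seed)
}

#' Write a steering-force trace (xvg dialect)
#'
#' Three whitespace-separated columns (time, force, extension) preceded by
#' `@` comment headers recording the protocol and seed; round-trips with
#' [read_force_trace()].
#'
#' @param trace a `force_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_force_trace <- function(trace, path) {
  if (!inherits(trace, "force_trace") || length(trace$times) == 0L) {
    stop_validation("empty or invalid force trace")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@    title \"steering force\"", con)
  writeLines("@    xaxis label \"time (ns)\"", con)
  writeLines("@    yaxis label \"force (kJ/mol/nm)\"", con)
  if (!is.null(trace$protocol)) {
    writeLines(sprintf("@ spring_constant = %g",
                       trace$protocol$spring_constant), con)
    writeLines(sprintf("@ pull_velocity = %g",
                       trace$protocol$pull_velocity), con)
  }
  if (!is.na(trace$seed)) writeLines(sprintf("@ seed = %d", trace$seed), con)
  if (!is.na(trace$peptide)) writeLines(paste0("# peptide ", trace$peptide), con)
  writeLines(sprintf("%.6g %.10g %.10g", trace$times, trace$forces,
                     trace$extensions), con)
  invisible(path)
}
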