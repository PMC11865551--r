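## Born-Oppenheimer molecular dynamics on an inferred potential energy
## surface: velocity-Verlet NVE, Berendsen weak-coupling NVT, Maxwell-
## Boltzmann initialization, plus trajectory analysis utilities. Internal
## units are atomic throughout (positions bohr, time hbar/E_h, masses in
## electron masses); femtoseconds and Angstrom appear only at I/O.

.amu_to_emass <- function(m) m * evcont_constants$emass_per_amu

#' Instantaneous kinetic temperature
#' @param velocities n x 3 matrix (atomic units)
#' @param masses length-n masses in electron masses
#' @param dof degrees of freedom (default 3n)
#' @return temperature in kelvin
#' @export
kinetic_temperature <- function(velocities, masses, dof = 3 * length(masses)) {
  ke <- 0.5 * sum(masses * rowSums(velocities^2))
  2 * ke / (dof * evcont_constants$kboltz_hartree)
}

#' Maxwell-Boltzmann initial velocities
#'
#' Each Cartesian component is drawn from Normal(0, sqrt(k_B T / m)) in
#' atomic units; optionally the net momentum is removed afterwards.
#'
#' @param masses masses in electron masses (a.u.)
#' @param temperature target temperature in kelvin (>= 0)
#' @param seed integer seed
#' @param remove_com remove centre-of-mass momentum (default TRUE)
#' @return n x 3 velocity matrix in bohr per atomic time unit
#' @export
maxwell_boltzmann_velocities <- function(masses, temperature, seed,
                                         remove_com = TRUE) {
  if (temperature < 0) stop("temperature must be non-negative")
  n <- length(masses)
  set.seed(as.integer(seed))
  if (temperature == 0) return(matrix(0, n, 3))
  sd <- sqrt(evcont_constants$kboltz_hartree * temperature / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  if (remove_com) {
    p <- colSums(v * masses)
    v <- sweep(v, 2, p / sum(masses), "-")
  }
  v
}

#' Berendsen weak-coupling velocity rescale
#'
#' Scales velocities by `lambda = sqrt(1 + (dt/tau)(T_target/T_inst - 1))`,
#' driving the instantaneous temperature exponentially toward the target
#' with time constant tau. Lambda is clamped to [0.8, 1.25] per step to
#' avoid pathological kicks near zero instantaneous temperature.
#'
#' @param velocities n x 3 matrix (a.u.)
#' @param masses masses in electron masses
#' @param T_target target temperature (K)
#' @param tau coupling time constant (atomic time units, >= dt)
#' @param dt integration step (atomic time units)
#' @return rescaled velocity matrix
#' @export
berendsen_rescale <- function(velocities, masses, T_target, tau, dt) {
  if (dt <= 0 || tau < dt) stop("need tau >= dt > 0")
  Tinst <- kinetic_temperature(velocities, masses)
  if (Tinst <= 0) {
    if (T_target > 0) stop("instantaneous temperature is zero; rescale undefined")
    return(velocities)
  }
  lambda <- sqrt(1 + (dt / tau) * (T_target / Tinst - 1))
  lambda <- min(max(lambda, 0.8), 1.25)
  velocities * lambda
}

#' One velocity-Verlet step
#'
#' Standard two-half-kick scheme. The force provider is a function of an
#' n x 3 position matrix returning `list(energy, forces)` (forces n x 3,
#' hartree/bohr).
#'
#' @param state list with `positions`, `velocities` (n x 3), `masses`
#'   (electron masses), `time`
#' @param forces current forces (n x 3)
#' @param dt timestep in atomic time units (> 0)
#' @param force_provider function(positions) -> list(energy, forces, ...)
#' @return list with the new `state`, `forces` and `energy` (and the raw
#'   provider output as `eval`)
#' @export
velocity_verlet_step <- function(state, forces, dt, force_provider) {
  if (dt <= 0) stop("dt must be positive")
  vh <- state$velocities + 0.5 * dt * forces / state$masses
  xn <- state$positions + dt * vh
  ev <- tryCatch(force_provider(xn), error = function(e) {
    stop("force evaluation failed at t = ", state$time + dt, ": ",
         conditionMessage(e), "\npositions:\n",
         paste(utils::capture.output(print(xn)), collapse = "\n"))
  })
  fn <- ev$forces
  vn <- vh + 0.5 * dt * fn / state$masses
  list(state = list(positions = xn, velocities = vn, masses = state$masses,
                    time = state$time + dt),
       forces = fn, energy = ev$energy, eval = ev)
}

#' Run Born-Oppenheimer molecular dynamics
#'
#' NVE velocity Verlet, optionally with a Berendsen thermostat (NVT). The
#' PES provider is either a `function(geometry) -> list(energy, forces, ...)`
#' (e.g. [continuation_pes()]) or a plain `function(positions)` provider.
#'
#' @param initial a [geometry()] (nuclei start at rest unless
#'   `init_temperature` is given) or an MD state list from a previous run
#' @param pes PES provider (see above)
#' @param dt timestep, atomic time units (paper-style default 5 a.u.)
#' @param steps number of integration steps (>= 1)
#' @param ensemble "NVE" or "NVT"
#' @param temperature_K thermostat target (NVT)
#' @param tau_au thermostat time constant (NVT), atomic units
#' @param init_temperature if non-NULL, draw initial velocities from a
#'   Maxwell-Boltzmann distribution at this temperature (K)
#' @param seed seed for velocity initialization
#' @param remove_com remove centre-of-mass momentum at initialization
#' @param observable_stride evaluate `observable_fun` every k-th frame
#' @param observable_fun optional `function(geometry, eval)` returning a list
#'   of per-frame observables
#' @param geom_template geometry carrying atom identities when `initial` is
#'   an MD state
#' @return object of class `trajectory`: fields `times` (a.u.), `times_fs`,
#'   `positions` (list of n x 3), `velocities`, `forces`, `epot`, `ekin`,
#'   `observables`, `dt`, `ensemble`, `final_state`, `geom_template`
#' @export
run_bomd <- function(initial, pes, dt = 5, steps = 100L,
                     ensemble = c("NVE", "NVT"), temperature_K = NULL,
                     tau_au = NULL, init_temperature = NULL, seed = 1L,
                     remove_com = TRUE, observable_stride = NULL,
                     observable_fun = NULL, geom_template = NULL) {
  ensemble <- match.arg(ensemble)
  if (steps < 1) stop("steps must be >= 1")
  if (inherits(initial, "geometry")) {
    geom_template <- initial
    masses <- .amu_to_emass(initial$masses)
    vel <- if (is.null(init_temperature)) {
      matrix(0, n_atoms(initial), 3)
    } else {
      maxwell_boltzmann_velocities(masses, init_temperature, seed,
                                   remove_com = remove_com)
    }
    state <- list(positions = initial$coordinates, velocities = vel,
                  masses = masses, time = 0)
  } else {
    if (is.null(geom_template)) stop("geom_template required for MD-state restart")
    state <- initial
  }
  if (ensemble == "NVT" && (is.null(temperature_K) || is.null(tau_au))) {
    stop("NVT needs temperature_K and tau_au")
  }
  provider <- function(positions) {
    g <- geometry(geom_template$atomic_numbers, positions,
                  charge = geom_template$charge, masses = geom_template$masses)
    pes(g)
  }
  ev0 <- provider(state$positions)
  nfr <- steps + 1L
  times <- numeric(nfr); epot <- numeric(nfr); ekin <- numeric(nfr)
  pos <- vector("list", nfr); vels <- vector("list", nfr)
  frc <- vector("list", nfr); obs <- vector("list", nfr)
  record <- function(i, state, f, e, ev) {
    times[i] <<- state$time
    pos[[i]] <<- state$positions
    vels[[i]] <<- state$velocities
    frc[[i]] <<- f
    epot[i] <<- e
    ekin[i] <<- 0.5 * sum(state$masses * rowSums(state$velocities^2))
    if (!is.null(observable_fun) && !is.null(observable_stride) &&
        ((i - 1L) %% observable_stride == 0L)) {
      g <- geometry(geom_template$atomic_numbers, state$positions,
                    charge = geom_template$charge,
                    masses = geom_template$masses)
      obs[[i]] <<- observable_fun(g, ev)
    }
  }
  record(1L, state, ev0$forces, ev0$energy, ev0)
  f <- ev0$forces
  for (s in seq_len(steps)) {
    stepres <- velocity_verlet_step(state, f, dt, provider)
    state <- stepres$state
    f <- stepres$forces
    if (ensemble == "NVT") {
      state$velocities <- berendsen_rescale(state$velocities, state$masses,
                                            temperature_K, tau_au, dt)
    }
    record(s + 1L, state, f, stepres$energy, stepres$eval)
  }
  structure(list(
    times = times, times_fs = times * evcont_constants$fs_per_au_time,
    positions = pos, velocities = vels, forces = frc,
    epot = epot, ekin = ekin, etot = epot + ekin, observables = obs,
    dt = dt, ensemble = ensemble,
    thermostat = if (ensemble == "NVT") list(temperature_K = temperature_K,
                                             tau_au = tau_au) else NULL,
    final_state = state, geom_template = geom_template
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, dt = %g a.u. (%.4f fs), %s>\n",
              length(x$times), x$dt,
              x$dt * evcont_constants$fs_per_au_time, x$ensemble))
  invisible(x)
}

#' Geometries of the frames of a trajectory
#' @param traj a `trajectory`
#' @param frames optional frame indices (default all)
#' @return list of [geometry()]
#' @export
trajectory_geometries <- function(traj, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(traj$positions)
  tmpl <- traj$geom_template
  lapply(frames, function(i) {
    geometry(tmpl$atomic_numbers, traj$positions[[i]], charge = tmpl$charge,
             masses = tmpl$masses)
  })
}

#' Write a trajectory as extended XYZ
#'
#' One XYZ block per frame with `time_fs=... epot_hartree=...` in the comment
#' line; per-atom force columns are appended after the coordinates.
#' @param traj a `trajectory`
#' @param path output path
#' @export
write_trajectory_xyz <- function(traj, path) {
  tmpl <- traj$geom_template
  sym <- element_symbol(tmpl$atomic_numbers)
  con <- file(path, "w")
  on.exit(close(con))
  bohr <- evcont_constants$bohr_per_angstrom
  for (i in seq_along(traj$positions)) {
    ang <- traj$positions[[i]] / bohr
    f <- traj$forces[[i]]
    writeLines(as.character(length(sym)), con)
    writeLines(sprintf("time_fs=%.6f epot_hartree=%.12f ekin_hartree=%.12f",
                       traj$times_fs[i], traj$epot[i], traj$ekin[i]), con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f %16.10f %16.10f %16.10f",
                       sym, ang[, 1], ang[, 2], ang[, 3],
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Centered running average of a series
#'
#' Moving mean with the stated window; near the edges the window is
#' truncated to the available support.
#' @param series numeric vector
#' @param window integer window length (>= 1, <= length)
#' @return numeric vector, same length
#' @export
running_average <- function(series, window) {
  n <- length(series)
  if (n == 0) stop("empty series")
  if (window < 1 || window > n) stop("window must be in 1..length(series)")
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Gaussian kernel density estimate on a grid
#'
#' @param samples numeric samples (e.g. distances in Angstrom)
#' @param bandwidth Gaussian sigma, same units as samples (> 0)
#' @param n_grid number of grid points
#' @param pad grid padding in bandwidths beyond the sample range
#' @return list with `x` (grid) and `density` (integrates to ~1, trapezoid)
#' @export
kde_distribution <- function(samples, bandwidth, n_grid = 512L, pad = 6) {
  if (length(samples) == 0) stop("no samples")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  lo <- min(samples) - pad * bandwidth
  hi <- max(samples) + pad * bandwidth
  x <- seq(lo, hi, length.out = n_grid)
  d <- vapply(x, function(g) {
    mean(stats::dnorm(g, mean = samples, sd = bandwidth))
  }, 0)
  list(x = x, density = d)
}

#' Interatomic distance along a trajectory
#' @param traj a `trajectory`
#' @param i,j atom indices (1-based)
#' @param angstrom report in Angstrom (default) or bohr
#' @return numeric vector per frame
#' @export
trajectory_distance <- function(traj, i, j, angstrom = TRUE) {
  d <- vapply(traj$positions, function(p) sqrt(sum((p[i, ] - p[j, ])^2)), 0)
  if (angstrom) d / evcont_constants$bohr_per_angstrom else d
}
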