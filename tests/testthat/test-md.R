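# Molecular dynamics: integrator correctness on closed-form systems,
# thermostat behaviour, analysis utilities.

## analytic 1D harmonic oscillator provider (mass m, frequency omega)
harmonic_pes <- function(k) {
  function(positions) {
    list(energy = 0.5 * k * sum(positions^2), forces = -k * positions)
  }
}

test_that("velocity Verlet: free flight, energy conservation, reversibility", {
  m <- 10
  st <- list(positions = matrix(c(0, 0, 0), 1), velocities = matrix(c(0.1, 0, 0), 1),
             masses = m, time = 0)
  ## zero force: uniform motion
  free <- function(p) list(energy = 0, forces = p * 0)
  s1 <- velocity_verlet_step(st, matrix(0, 1, 3), 2.0, free)
  expect_equal(s1$state$positions[1, 1], 0.2, tolerance = 1e-14)

  ## harmonic oscillator, 1000 steps at dt = 0.01/omega
  k <- 2.5
  omega <- sqrt(k / m)
  pes <- harmonic_pes(k)
  st <- list(positions = matrix(c(1, 0, 0), 1), velocities = matrix(0, 1, 3),
             masses = m, time = 0)
  f <- pes(st$positions)$forces
  e0 <- pes(st$positions)$energy
  emax <- 0
  for (i in 1:1000) {
    out <- velocity_verlet_step(st, f, 0.01 / omega, pes)
    st <- out$state; f <- out$forces
    etot <- out$energy + 0.5 * m * sum(st$velocities^2)
    emax <- max(emax, abs(etot - e0))
  }
  expect_lt(emax / e0, 1e-4)
  ## drift (not oscillation amplitude) is tiny
  etot_end <- pes(st$positions)$energy + 0.5 * m * sum(st$velocities^2)
  expect_lt(abs(etot_end - e0) / e0, 1e-4)

  ## time reversal: negate velocities and propagate back
  stb <- list(positions = st$positions, velocities = -st$velocities,
              masses = m, time = 0)
  fb <- pes(stb$positions)$forces
  for (i in 1:1000) {
    out <- velocity_verlet_step(stb, fb, 0.01 / omega, pes)
    stb <- out$state; fb <- out$forces
  }
  expect_lt(max(abs(stb$positions - c(1, 0, 0))), 1e-8)
  expect_error(velocity_verlet_step(st, f, -1, pes), "positive")
})

test_that("Maxwell-Boltzmann velocities have the right statistics", {
  masses <- evcont_constants$emass_per_amu * c(1, 1, 16, 12, 1)
  kB <- evcont_constants$kboltz_hartree
  Temp <- 300
  expect_equal(maxwell_boltzmann_velocities(masses, 0, seed = 1),
               matrix(0, 5, 3))
  expect_identical(maxwell_boltzmann_velocities(masses, Temp, seed = 7),
                   maxwell_boltzmann_velocities(masses, Temp, seed = 7))
  ## mean kinetic energy over many draws ~ (3/2) n kB T within 3 SE
  n_draw <- 1e4
  ke <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    v <- maxwell_boltzmann_velocities(masses, Temp, seed = i, remove_com = FALSE)
    ke[i] <- 0.5 * sum(masses * rowSums(v^2))
  }
  target <- 1.5 * 5 * kB * Temp
  se <- stats::sd(ke) / sqrt(n_draw)
  expect_lt(abs(mean(ke) - target), 3 * se)
  ## COM removal zeroes total momentum
  v <- maxwell_boltzmann_velocities(masses, Temp, seed = 3, remove_com = TRUE)
  expect_lt(max(abs(colSums(v * masses))), 1e-10)
  expect_error(maxwell_boltzmann_velocities(masses, -10, 1), "non-negative")
})

test_that("Berendsen rescaling drives temperature to the target", {
  masses <- rep(1000, 8)
  kB <- evcont_constants$kboltz_hartree
  v <- maxwell_boltzmann_velocities(masses, 600, seed = 5, remove_com = FALSE)
  ## T_inst = T_target: no rescale
  Ti <- kinetic_temperature(v, masses)
  expect_equal(berendsen_rescale(v, masses, Ti, 10, 1), v, tolerance = 1e-12)
  ## tau = dt: instantaneous rescale to the target (within the clamp)
  v2 <- berendsen_rescale(v, masses, Ti * 1.1, 1, 1)
  expect_equal(kinetic_temperature(v2, masses), Ti * 1.1, tolerance = 1e-9)
  expect_error(berendsen_rescale(v * 0, masses, 300, 10, 1), "undefined")
  ## exponential relaxation on a free ideal gas (forces zero, NVT)
  free_pes <- function(g) list(energy = 0, forces = matrix(0, 8, 3))
  geom <- geometry(rep(1L, 8), matrix(stats::rnorm(24, sd = 3), 8, 3),
                   masses = rep(1000 / evcont_constants$emass_per_amu, 8))
  tau <- 50; dt <- 5
  traj <- run_bomd(geom, free_pes, dt = dt, steps = 120, ensemble = "NVT",
                   temperature_K = 300, tau_au = tau, init_temperature = 60,
                   seed = 2, remove_com = FALSE)
  Ts <- vapply(seq_along(traj$times), function(i) {
    kinetic_temperature(traj$velocities[[i]], traj$final_state$masses)
  }, 0)
  ## fit log(T_target - T) ~ t: slope ~ -1/tau
  sel <- which(300 - Ts > 5)
  fit <- stats::lm(log(300 - Ts[sel]) ~ traj$times[sel])
  expect_equal(unname(stats::coef(fit)[2]), -1 / tau, tolerance = 0.25)
})

test_that("run_bomd produces consistent trajectories and restarts", {
  pes <- function(g) {
    ## harmonic bond between two atoms, r0 = 1.4
    d <- g$coordinates[2, ] - g$coordinates[1, ]
    r <- sqrt(sum(d^2))
    k <- 0.3
    fvec <- k * (r - 1.4) * d / r
    list(energy = 0.5 * k * (r - 1.4)^2,
         forces = rbind(fvec, -fvec))
  }
  g <- h_chain(2, 1.6)
  traj <- run_bomd(g, pes, dt = 5, steps = 50)
  expect_length(traj$times, 51L)
  expect_true(all(diff(traj$times) > 0))
  expect_equal(traj$times_fs[2] - traj$times_fs[1], 5 * 0.02418884254,
               tolerance = 1e-12)
  ## bounded energy oscillation of order (dt*omega)^2 relative, no drift
  drift <- max(abs(traj$etot - traj$etot[1]))
  expect_lt(drift, 5e-5)
  ## starting at rest at the minimum: static
  gmin <- h_chain(2, 1.4)
  trajm <- run_bomd(gmin, pes, dt = 5, steps = 20)
  expect_lt(max(abs(trajm$positions[[21]] - gmin$coordinates)), 1e-8)
  ## NVE restart from the midpoint replays bit-identically
  traj_a <- run_bomd(g, pes, dt = 5, steps = 25)
  traj_b <- run_bomd(traj_a$final_state, pes, dt = 5, steps = 25,
                     geom_template = g)
  expect_identical(traj_b$positions[[26]], traj$positions[[51]])
  ## extended-XYZ output round-trips frame count
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, path)
  expect_length(readLines(path), 51 * 4)
})

test_that("running averages and KDE behave as documented", {
  x <- c(5, 5, 5, 5, 5)
  expect_equal(running_average(x, 1), x)
  expect_equal(running_average(x, 3), x)
  ramp <- as.numeric(1:20)
  ra <- running_average(ramp, 5)
  expect_equal(ra[3:18], ramp[3:18])  # interior of a linear ramp is unchanged
  expect_error(running_average(numeric(0), 1), "empty")
  expect_error(running_average(ramp, 25), "window")

  k <- kde_distribution(c(1.5), bandwidth = 0.1)
  expect_equal(k$x[which.max(k$density)], 1.5, tolerance = 1e-2)
  ## integral normalizes to 1 (trapezoid)
  integ <- sum(diff(k$x) * (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_equal(integ, 1, tolerance = 1e-3)
  ## two well-separated samples: two equal modes
  k2 <- kde_distribution(c(0, 10), bandwidth = 0.05, n_grid = 2048)
  d0 <- max(k2$density[abs(k2$x - 0) < 0.2])
  d10 <- max(k2$density[abs(k2$x - 10) < 0.2])
  expect_equal(d0, d10, tolerance = 1e-6)
  expect_error(kde_distribution(numeric(0), 0.1), "no samples")
  expect_error(kde_distribution(1, 0), "positive")
})

test_that("observables are recorded every k-th frame", {
  pes <- function(g) list(energy = 0, forces = matrix(0, 2, 3))
  g <- h_chain(2, 1.5)
  traj <- run_bomd(g, pes, dt = 1, steps = 9, observable_stride = 3L,
                   observable_fun = function(geom, ev) {
                     list(r12 = sqrt(sum((geom$coordinates[1, ] -
                                          geom$coordinates[2, ])^2)))
                   })
  filled <- which(!vapply(traj$observables, is.null, TRUE))
  expect_equal(filled, c(1L, 4L, 7L, 10L))
  expect_equal(traj$observables[[1]]$r12, 1.5, tolerance = 1e-12)
})
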