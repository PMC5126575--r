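# Shared fixtures: the two particle populations of the study and standard
# medium/field/thermal conditions, plus small independent oracles.

p40 <- function() particle_spec(40e-9, 5180, 92, 1.1e4, "40nm")
p10 <- function() particle_spec(10e-9, 5180, 30, 1.1e4, "10nm")
env_water <- function() environment_spec(300, 1.0e-3, "water")
field_765 <- function() field_spec(0.040, 0.030, 765e3)
field_210 <- function() field_spec(0.040, 0.030, 210e3)
th_std <- function(lambda = 0.01)
  thermal_spec(sample_mass = 1e-3, specific_heat = 4186,
               ambient_temperature = 300, loss_coefficient = lambda,
               sample_volume = 1e-6)

# Independent oracle for the attraction radius: plain bisection on the
# co-axial dipole-sum energy, written from scratch (no package internals).
oracle_pair_energy <- function(s, r, p) {
  mu0 <- 4e-7 * pi
  mu <- p$Ms_mass * p$rho_p * pi / 6 * p$d0^3
  e <- 0
  for (j in 0:(s - 1)) e <- e - mu0 * mu^2 / (2 * pi * (r + j * p$d0)^3)
  e
}

oracle_attraction_radius <- function(s, p, Temp = 300) {
  kT <- 1.380649e-23 * Temp
  lo <- p$d0 * 0.5
  hi <- p$d0 * 1000
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_pair_energy(s, mid, p) + kT > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Independent oracle for the merge rule on motionless collinear objects:
# repeatedly merge the closest qualifying pair (tip distance below the
# attraction radius of the longer chain), scalar arithmetic throughout.
oracle_collinear_merge <- function(z, s, p, Temp = 300) {
  repeat {
    m <- length(z)
    if (m < 2) break
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      hi <- (s[i] - 1) * p$d0 / 2; hj <- (s[j] - 1) * p$d0 / 2
      dz <- z[j] - z[i]
      tip <- min(abs(dz + hi + hj), abs(dz + hi - hj),
                 abs(dz - hi + hj), abs(dz - hi - hj))
      ra <- oracle_attraction_radius(max(s[i], s[j]), p, Temp)
      if (tip < ra && (is.null(best) || tip < best$tip))
        best <- list(i = i, j = j, tip = tip)
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    znew <- (z[i] * s[i] + z[j] * s[j]) / (s[i] + s[j])
    snew <- s[i] + s[j]
    keep <- setdiff(1:m, c(i, j))
    z <- c(z[keep], znew); s <- c(s[keep], snew)
  }
  list(z = sort(z), s = sort(s))
}

# clamped step used by the 40 nm / water runs
dt40 <- function() (0.1 * 40e-9)^2 / (2 * 1.380649e-23 * 300 / (3 * pi * 1e-3 * 40e-9))

# auto-clamped step for any particle/medium (RMS step = 0.1 d0)
resolve_dt_for_test <- function(p, env)
  (0.1 * p$d0)^2 / (2 * 1.380649e-23 * env$T / (3 * pi * env$eta * p$d0))
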