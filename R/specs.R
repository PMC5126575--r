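# Domain specifications: particle, field, environment, thermal, simulation.
# Strict SI internally; constructors validate invariants once so downstream
# physics can assume clean inputs.

# vacuum permeability (T m / A) and Boltzmann constant (J/K)
MU0 <- 4e-7 * pi
KB <- 1.380649e-23

#' Physical constants used throughout the package
#'
#' @return Named list with `mu0` (vacuum permeability, T m/A) and
#'   `kB` (Boltzmann constant, J/K).
#' @export
physical_constants <- function() list(mu0 = MU0, kB = KB)

#' Intrinsic particle specification
#'
#' Describes one nanoparticle population by its diameter, mass density,
#' mass saturation magnetization and uniaxial anisotropy constant. Derived
#' quantities (volume, volumetric magnetization, dipole moment) are computed
#' from these four numbers, never stored, so the object cannot go stale.
#'
#' @param diameter Particle diameter d0 in m (> 0).
#' @param mass_density Mass density of the particle material in kg/m^3 (> 0).
#' @param saturation_magnetization Mass saturation magnetization in
#'   A m^2/kg (>= 0).
#' @param anisotropy_constant Uniaxial anisotropy constant K in J/m^3 (>= 0).
#' @param label Free-text label, e.g. `"40nm"`.
#' @return An object of class `particle_spec`.
#' @examples
#' particle_spec(40e-9, 5180, 92, 1.1e4, "40nm")
#' @export
particle_spec <- function(diameter, mass_density, saturation_magnetization,
                          anisotropy_constant, label = "") {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, is.finite(diameter))
  if (diameter <= 0) stop("particle diameter must be > 0")
  if (mass_density <= 0) stop("mass density must be > 0")
  if (saturation_magnetization < 0) stop("saturation magnetization must be >= 0")
  if (anisotropy_constant < 0) stop("anisotropy constant must be >= 0")
  structure(
    list(
      d0 = as.numeric(diameter),
      rho_p = as.numeric(mass_density),
      Ms_mass = as.numeric(saturation_magnetization),
      K = as.numeric(anisotropy_constant),
      label = as.character(label)
    ),
    class = "particle_spec"
  )
}

#' Particle volume (m^3)
#' @param p A [particle_spec()].
#' @export
particle_volume <- function(p) pi / 6 * p$d0^3

#' Volumetric saturation magnetization (A/m)
#' @param p A [particle_spec()].
#' @export
volumetric_magnetization <- function(p) p$Ms_mass * p$rho_p

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec '%s'> d0 = %.3g nm, rho = %g kg/m^3, Ms = %g A m^2/kg, K = %g J/m^3\n",
              x$label, x$d0 * 1e9, x$rho_p, x$Ms_mass, x$K))
  invisible(x)
}

#' Applied-field specification
#'
#' @param static_field Static alignment flux density in T (>= 0); the 40 mT
#'   field that drives chain formation. Moments are assumed saturated along
#'   the field direction, so only its on/off state enters the dynamics.
#' @param ac_amplitude AC field amplitude mu0*H_max in T (>= 0).
#' @param ac_frequency AC frequency f in Hz (> 0 when heating is evaluated).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(static_field = 0.040, ac_amplitude = 0.030,
                       ac_frequency = 765e3) {
  if (static_field < 0 || ac_amplitude < 0) stop("field amplitudes must be >= 0")
  if (ac_frequency <= 0) stop("AC frequency must be > 0")
  structure(
    list(B_align = as.numeric(static_field),
         B_ac = as.numeric(ac_amplitude),
         f = as.numeric(ac_frequency)),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> static %g mT, AC %g mT at %g kHz\n",
              x$B_align * 1e3, x$B_ac * 1e3, x$f / 1e3))
  invisible(x)
}

#' Dispersion-medium specification
#'
#' @param temperature Absolute temperature in K (> 0).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#' @param medium_label Free text, e.g. agarose content.
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(temperature = 300, viscosity = 1.0e-3,
                             medium_label = "water") {
  if (temperature <= 0) stop("temperature must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  structure(
    list(T = as.numeric(temperature), eta = as.numeric(viscosity),
         medium_label = as.character(medium_label)),
    class = "environment_spec"
  )
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf("<environment_spec> T = %g K, eta = %g mPa s (%s)\n",
              x$T, x$eta * 1e3, x$medium_label))
  invisible(x)
}

#' Thermal specification of the calorimetry sample
#'
#' Parameters of the lumped and 1D-conduction heat models. The lumped model
#' needs sample mass, specific heat, ambient temperature and a linear loss
#' coefficient; the conduction model additionally needs conductivity, density
#' and heat capacity of the medium.
#'
#' @param sample_mass Ferrofluid mass m_f in kg.
#' @param specific_heat Specific heat c in J/(kg K).
#' @param ambient_temperature Ambient temperature in K.
#' @param loss_coefficient Linear heat-loss coefficient lambda in W/K (>= 0).
#' @param sample_volume Sample volume V_s in m^3.
#' @param conductivity Thermal conductivity k in W/(m K) (1D model).
#' @param density Medium density in kg/m^3 (1D model).
#' @param heat_capacity Specific heat capacity C_p in J/(kg K) (1D model).
#' @return An object of class `thermal_spec`.
#' @export
thermal_spec <- function(sample_mass = 1e-3, specific_heat = 4186,
                         ambient_temperature = 300, loss_coefficient = 0.01,
                         sample_volume = 1e-6, conductivity = 0.6,
                         density = 1000, heat_capacity = 4186) {
  vals <- c(sample_mass, specific_heat, ambient_temperature, sample_volume,
            conductivity, density, heat_capacity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("thermal parameters must be positive and finite")
  if (loss_coefficient < 0) stop("loss coefficient must be >= 0")
  structure(
    list(m_f = sample_mass, c = specific_heat, T_amb = ambient_temperature,
         lambda = loss_coefficient, V_s = sample_volume, k = conductivity,
         rho = density, C_p = heat_capacity),
    class = "thermal_spec"
  )
}

#' @export
print.thermal_spec <- function(x, ...) {
  cat(sprintf("<thermal_spec> m_f = %g g, c = %g J/(kg K), T_amb = %g K, lambda = %g W/K\n",
              x$m_f * 1e3, x$c, x$T_amb, x$lambda))
  invisible(x)
}

#' Chain-formation simulation configuration
#'
#' The box side is expressed in particle diameters, mirroring the standard
#' (80 d0)^3 computational volume. The time step may be left `NULL`, in which
#' case it is auto-set so that the RMS single-particle step sqrt(2 D1 dt)
#' equals one tenth of a particle diameter; a user-specified step larger than
#' that bound is clamped down to it (the attraction zone, r_a >= d0, must not
#' be tunnelled through in one move).
#'
#' @param n_particles Number of particles N (>= 1).
#' @param box_d0_units Cubic box side in units of d0 (default 80).
#' @param dt Time step in s, or `NULL` for the auto-clamped value.
#' @param total_time Simulated duration in s.
#' @param field_on Logical; static aligning field present?
#' @param seed Integer RNG seed; fixes the whole trajectory.
#' @param boundary `"periodic"` (minimum-image) or `"reflecting"`.
#' @param snapshot_every Record a snapshot every this many steps.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_particles, box_d0_units = 80, dt = NULL,
                              total_time = 2e-3, field_on = TRUE, seed = 1L,
                              boundary = c("periodic", "reflecting"),
                              snapshot_every = 100L) {
  boundary <- match.arg(boundary)
  if (n_particles < 1) stop("need at least one particle")
  if (box_d0_units <= 0) stop("box side must be > 0")
  if (!is.null(dt) && dt <= 0) stop("time step must be > 0")
  if (total_time <= 0) stop("total time must be > 0")
  structure(
    list(N = as.integer(n_particles), box_d0 = box_d0_units, dt = dt,
         total_time = total_time, field_on = isTRUE(field_on),
         seed = as.integer(seed), boundary = boundary,
         snapshot_every = as.integer(snapshot_every)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> N = %d, box = %g d0, t = %g s, field %s, seed %d\n",
              x$N, x$box_d0, x$total_time, if (x$field_on) "on" else "off", x$seed))
  invisible(x)
}

# Largest stable/resolving step: RMS free-particle displacement <= 0.1 d0.
max_time_step <- function(p, env) {
  D1 <- KB * env$T / (3 * pi * env$eta * p$d0)
  (0.1 * p$d0)^2 / (2 * D1)
}

# Resolve the configured dt against the clamp.
resolve_time_step <- function(cfg, p, env) {
  dt_max <- max_time_step(p, env)
  if (is.null(cfg$dt)) dt_max else min(cfg$dt, dt_max)
}
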