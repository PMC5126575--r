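# Heat-transfer models turning the volumetric hysteresis heat source into
# hyperthermia temperature traces: a two-parameter lumped energy balance and
# a 1D spherically symmetric conduction model (desk-scale stand-ins for a
# full 3D finite-element computation).

#' Heating/cooling temperature trace
#'
#' @param time Time samples in s, strictly increasing.
#' @param temperature Temperature samples in K.
#' @param phase Character vector, `"heating"` or `"cooling"`, contiguous.
#' @return An object of class `heating_curve` (a data frame).
#' @export
heating_curve <- function(time, temperature, phase) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (length(time) != length(temperature) || length(time) != length(phase))
    stop("time, temperature and phase must have equal length")
  phase <- match.arg(phase, c("heating", "cooling"), several.ok = TRUE)
  r <- rle(phase)
  if (length(r$values) > 2L) stop("phases must be contiguous")
  structure(data.frame(time = time, temperature = temperature, phase = phase),
            class = c("heating_curve", "data.frame"))
}

#' @export
print.heating_curve <- function(x, ...) {
  cat(sprintf("<heating_curve> %d samples, %.1f s heating / %.1f s cooling, T: %.2f -> %.2f K\n",
              nrow(x), max(c(0, x$time[x$phase == "heating"])),
              diff(range(c(0, x$time[x$phase == "cooling"]))),
              x$temperature[1], max(x$temperature)))
  invisible(x)
}

#' Lumped heating/cooling curve
#'
#' Integrates the lumped energy balance
#' dT/dt = Q V_s / (m_f c) - (lambda / (m_f c)) (T - T_amb)
#' over a heating phase of duration `t_heat` (source on) followed by a
#' cooling phase of `t_cool` (source off), with an adaptive-step ODE solver
#' (relative tolerance 1e-8). For constant Q the heating phase has the
#' closed form T(t) = T_amb + (Q V_s / lambda)(1 - exp(-lambda t / (m_f c))).
#'
#' @param Q Volumetric heat source in W/m^3 (>= 0).
#' @param th A [thermal_spec()].
#' @param t_heat Heating duration in s.
#' @param t_cool Cooling duration in s.
#' @param dt Output sampling interval in s (default 0.4, the instrument rate).
#' @param T0 Initial temperature in K (default ambient).
#' @return A [heating_curve()].
#' @export
lumped_curve <- function(Q, th, t_heat, t_cool = 0, dt = 0.4, T0 = th$T_amb) {
  if (Q < 0) stop("heat source must be >= 0")
  if (t_heat <= 0) stop("heating duration must be > 0")
  tau_inv <- th$lambda / (th$m_f * th$c)
  rhs <- function(t, y, parms) {
    list(parms$q / (th$m_f * th$c) - tau_inv * (y - th$T_amb))
  }
  t_h <- unique(c(seq(0, t_heat, by = dt), t_heat))
  sol_h <- deSolve::ode(c(T = T0), t_h, rhs, list(q = Q * th$V_s),
                        rtol = 1e-8, atol = 1e-10)
  time <- sol_h[, 1]; temp <- sol_h[, 2]; phase <- rep("heating", length(time))
  if (t_cool > 0) {
    t_c <- unique(c(seq(0, t_cool, by = dt), t_cool))
    sol_c <- deSolve::ode(c(T = temp[length(temp)]), t_c, rhs, list(q = 0),
                          rtol = 1e-8, atol = 1e-10)
    time <- c(time, t_heat + sol_c[-1, 1])
    temp <- c(temp, sol_c[-1, 2])
    phase <- c(phase, rep("cooling", nrow(sol_c) - 1L))
  }
  heating_curve(time, temp, phase)
}

#' 1D spherical conduction heating curve
#'
#' Solves rho C_p dT/dt = k (1/r^2) d/dr(r^2 dT/dr) + Q 1(r <= R_source)
#' on a uniform radial grid over a sphere of radius R (derived from the
#' sample volume), by explicit finite differences. The outer boundary is
#' either convective, with film coefficient h = lambda / (4 pi R^2) so the
#' isothermal limit reproduces the lumped model, or held fixed at
#' `T_boundary`. The internal step is auto-set to 0.25 dr^2 / alpha
#' (alpha = k / (rho C_p)); an explicitly requested larger step is refused
#' with the required value.
#'
#' @param Q Volumetric heat source in W/m^3, applied for r <= R_source.
#' @param th A [thermal_spec()].
#' @param t_heat,t_cool Heating/cooling durations in s.
#' @param n_r Number of radial intervals (default 50).
#' @param dt_out Output sampling interval in s.
#' @param dt_int Internal time step in s, or `NULL` for the stable default.
#' @param boundary `"convective"` or `"fixed"`.
#' @param T_boundary Boundary temperature for `boundary = "fixed"`.
#' @param R_source Source radius in m (default: whole sphere).
#' @param T0 Initial temperature (default ambient).
#' @return A [heating_curve()] of the centre-point trace, with attributes
#'   `profile` (final radial temperature profile, data frame `r`, `T`) and
#'   `mean_trace` (volume-averaged temperature at the output times).
#' @export
conduction_1d <- function(Q, th, t_heat, t_cool = 0, n_r = 50, dt_out = 0.4,
                          dt_int = NULL, boundary = c("convective", "fixed"),
                          T_boundary = NULL, R_source = NULL, T0 = th$T_amb) {
  boundary <- match.arg(boundary)
  if (Q < 0) stop("heat source must be >= 0")
  R <- (3 * th$V_s / (4 * pi))^(1/3)
  if (is.null(R_source)) R_source <- R
  dr <- R / n_r
  r <- seq(0, R, by = dr)
  alpha <- th$k / (th$rho * th$C_p)
  dt_stable <- 0.25 * dr^2 / alpha
  if (is.null(dt_int)) {
    dt_int <- dt_stable
  } else if (dt_int > dt_stable) {
    stop(sprintf("explicit step %.3g s is unstable; need dt <= %.3g s",
                 dt_int, dt_stable))
  }
  h <- if (boundary == "convective") th$lambda / (4 * pi * R^2) else NA_real_
  if (boundary == "fixed" && is.null(T_boundary)) T_boundary <- th$T_amb
  n <- length(r)
  Tvec <- rep(T0, n)
  if (boundary == "fixed") Tvec[n] <- T_boundary
  src <- ifelse(r <= R_source, Q, 0) / (th$rho * th$C_p)
  rp <- (r[-n] + dr / 2)^2   # r_{i+1/2}^2 for faces 1..n-1
  # finite-volume cell weights for the volume-averaged temperature
  r_lo <- pmax(r - dr / 2, 0); r_hi <- pmin(r + dr / 2, R)
  w_vol <- r_hi^3 - r_lo^3
  step_field <- function(Tv, q_on, dt) {
    Tn <- Tv
    # centre (i = 1): symmetric limit of the spherical Laplacian
    Tn[1] <- Tv[1] + dt * (6 * alpha * (Tv[2] - Tv[1]) / dr^2 + q_on[1])
    i <- 2:(n - 1)
    lap <- (rp[i] * (Tv[i + 1] - Tv[i]) - rp[i - 1] * (Tv[i] - Tv[i - 1])) /
      (r[i]^2 * dr^2)
    Tn[i] <- Tv[i] + dt * (alpha * lap + q_on[i])
    if (boundary == "convective") {
      # half-cell energy balance at the wall: conduction in, convection out
      flux <- alpha * (rp[n - 1] * (Tv[n - 1] - Tv[n]) / dr -
                         r[n]^2 * (h / th$k) * (Tv[n] - th$T_amb))
      Tn[n] <- Tv[n] + dt * (flux / (r[n]^2 * dr / 2) + q_on[n])
    } else {
      Tn[n] <- T_boundary
    }
    Tn
  }
  advance <- function(Tv, q_on, duration, t0, phase, out) {
    t_local <- 0
    next_out <- dt_out
    while (t_local < duration - 1e-12) {
      dt <- min(dt_int, duration - t_local)
      Tv <- step_field(Tv, q_on, dt)
      t_local <- t_local + dt
      if (t_local >= next_out - 1e-9 || t_local >= duration - 1e-12) {
        out$time <- c(out$time, t0 + t_local)
        out$temp <- c(out$temp, Tv[1])
        out$mean <- c(out$mean, sum(w_vol * Tv) / sum(w_vol))
        out$phase <- c(out$phase, phase)
        next_out <- next_out + dt_out
      }
    }
    list(Tv = Tv, out = out)
  }
  out <- list(time = 0, temp = Tvec[1],
              mean = sum(w_vol * Tvec) / sum(w_vol), phase = "heating")
  st <- advance(Tvec, src, t_heat, 0, "heating", out)
  if (t_cool > 0)
    st <- advance(st$Tv, src * 0, t_cool, t_heat, "cooling", st$out)
  out <- st$out
  curve <- heating_curve(out$time, out$temp, out$phase)
  attr(curve, "profile") <- data.frame(r = r, T = st$Tv)
  attr(curve, "mean_trace") <- out$mean
  curve
}

#' Synthesize chain-vs-random heating cycles from the loss model
#'
#' Runs the full forward path: hysteresis-loop areas for the chain and
#' random configurations -> volumetric heat sources at the given
#' concentration -> lumped heating/cooling traces. Because the initial
#' slope is proportional to Q and hence to A_v, the chain curve rises
#' faster whenever its loop area is larger.
#'
#' @param report Two-row [loss_report()] table (rows chain and random), as
#'   from [compare_configurations()].
#' @param th A [thermal_spec()].
#' @param field A [field_spec()].
#' @param p A [particle_spec()].
#' @param concentration Particle mass concentration in kg/m^3.
#' @param t_heat,t_cool Phase durations in s.
#' @param dt Sampling interval in s.
#' @return Named list of [heating_curve()]s, one per report row, with
#'   attribute `Q` (the heat sources in W/m^3).
#' @export
synthesize_cycle <- function(report, th, field, p, concentration = 4,
                             t_heat = 120, t_cool = 120, dt = 0.4) {
  omega <- volume_fraction(concentration, p)
  Qs <- vapply(report$A_v_Jm3, heat_source, numeric(1), f = field$f,
               omega = omega)
  curves <- lapply(Qs, lumped_curve, th = th, t_heat = t_heat,
                   t_cool = t_cool, dt = dt)
  names(curves) <- report$label
  attr(curves, "Q") <- stats::setNames(Qs, report$label)
  curves
}

#' Fit the loss coefficient from a cooling phase
#'
#' Log-linear fit of T - T_amb over the cooling phase: the lumped model
#' cools as exp(-lambda t / (m_f c)), so the decay-rate estimate times
#' m_f c is lambda.
#'
#' @param curve A [heating_curve()] containing a cooling phase.
#' @param th A [thermal_spec()] (supplies m_f, c, T_amb).
#' @return Estimated lambda in W/K.
#' @export
fit_loss_coefficient <- function(curve, th) {
  cool <- curve[curve$phase == "cooling", ]
  if (nrow(cool) < 5L) stop("need at least 5 cooling samples")
  dT <- cool$temperature - th$T_amb
  if (any(dT <= 0)) stop("cooling trace must stay above ambient")
  fit <- stats::lm(log(dT) ~ cool$time)
  -unname(stats::coef(fit)[2]) * th$m_f * th$c
}

#' Read/write heating curves as CSV
#'
#' Columns `time_s`, `temp_C`, `phase`; temperatures are stored in Celsius
#' at the I/O boundary and kept in Kelvin internally.
#'
#' @param curve A [heating_curve()].
#' @param path File path.
#' @return `write_heating_curve` returns the path; `read_heating_curve`
#'   returns a [heating_curve()].
#' @export
write_heating_curve <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$time,
                              temp_C = curve$temperature - 273.15,
                              phase = curve$phase),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heating_curve
#' @export
read_heating_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "temp_C", "phase")
  if (!all(need %in% names(df)))
    stop("heating-curve CSV must have columns time_s, temp_C, phase")
  heating_curve(df$time_s, df$temp_C + 273.15, df$phase)
}
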