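# Dipolar energetics, attraction zones and the Stoner-Wohlfarth loss model.

test_that("dipole moment follows Ms * rho * V with cubic size scaling", {
  p <- p40()
  expect_equal(dipole_moment(p), 1.596968e-17, tolerance = 1e-6)
  p0 <- particle_spec(40e-9, 5180, 0, 1.1e4)
  expect_identical(dipole_moment(p0), 0)
  p2 <- particle_spec(80e-9, 5180, 92, 1.1e4)
  expect_equal(dipole_moment(p2) / dipole_moment(p), 8, tolerance = 1e-12)
})

test_that("coupling parameter separates the strong and weak regimes", {
  expect_equal(coupling_parameter(p40(), env_water()), 192.4145,
               tolerance = 1e-6)
  expect_gt(coupling_parameter(p40(), env_water()), 100)
  expect_lt(coupling_parameter(p10(), env_water()), 1)
  p0 <- particle_spec(40e-9, 5180, 0, 1.1e4)
  expect_identical(coupling_parameter(p0, env_water()), 0)
})

test_that("coupling parameter equals the contact pair energy over kBT", {
  p <- p40(); env <- env_water()
  kT <- physical_constants()$kB * env$T
  expect_equal(coupling_parameter(p, env),
               abs(chain_tip_energy(1L, p$d0, p)) / kT, tolerance = 1e-14)
})

test_that("chain tip energy is attractive, deepens with s and vanishes far away", {
  p <- p40()
  r <- 2 * p$d0
  e1 <- chain_tip_energy(1L, r, p)
  e2 <- chain_tip_energy(2L, r, p)
  e5 <- chain_tip_energy(5L, r, p)
  expect_lt(e5, e2); expect_lt(e2, e1); expect_lt(e1, 0)
  # closed form for the co-axial pair
  mu0 <- physical_constants()$mu0
  expect_equal(chain_tip_energy(1L, p$d0, p),
               -mu0 * dipole_moment(p)^2 / (2 * pi * p$d0^3),
               tolerance = 1e-14)
  expect_lt(abs(chain_tip_energy(3L, 1e4 * p$d0, p)),
            abs(chain_tip_energy(3L, p$d0, p)) * 1e-11)
  expect_error(chain_tip_energy(1L, -p$d0, p), "must be > 0")
})

test_that("attraction radius is the -kBT root, analytic for s = 1", {
  p <- p40(); env <- env_water()
  gam <- coupling_parameter(p, env)
  expect_equal(attraction_radius(1L, p, env), gam^(1/3) * p$d0,
               tolerance = 1e-12)
  # independent bisection oracle
  for (s in c(1L, 3L, 12L)) {
    expect_equal(attraction_radius(s, p, env),
                 oracle_attraction_radius(s, p), tolerance = 1e-8)
  }
})

test_that("attraction radius roots are accurate and nondecreasing for s = 1..50", {
  p <- p40(); env <- env_water()
  kT <- physical_constants()$kB * env$T
  ra <- vapply(1:50, attraction_radius, numeric(1), p = p, env = env)
  err <- vapply(1:50, function(s) abs(abs(chain_tip_energy(s, ra[s], p)) / kT - 1),
                numeric(1))
  expect_lt(max(err), 1e-6)
  expect_true(all(diff(ra) >= -1e-15))
  # saturates: late increments much smaller than early ones
  expect_lt(ra[50] - ra[40], 0.05 * (ra[10] - ra[1]))
})

test_that("weak coupling signals the no-aggregation regime", {
  expect_error(attraction_radius(1L, p10(), env_water()),
               class = "chainheat_no_aggregation")
  # at the Gamma = 1 boundary the zone closes onto the contact distance
  p <- p40(); env <- env_water()
  Ms1 <- p$Ms_mass / sqrt(coupling_parameter(p, env)) * (1 + 1e-9)
  pb <- particle_spec(p$d0, p$rho_p, Ms1, p$K)
  expect_equal(attraction_radius(1L, pb, env) / p$d0, 1, tolerance = 1e-6)
})

test_that("Stoner-Wohlfarth coercivity has the right limits and f-trend", {
  p <- p40(); f <- field_765()
  mu0 <- physical_constants()$mu0
  HK <- 2 * p$K / (mu0 * volumetric_magnetization(p))
  cold <- environment_spec(temperature = 1e-9)
  expect_equal(coercive_field_sw(p, cold, f, aligned = TRUE), HK,
               tolerance = 1e-6)
  expect_equal(coercive_field_sw(p, cold, f, aligned = FALSE), 0.48 * HK,
               tolerance = 1e-6)
  # 10 nm: barrier K V below the thermal term -> superparamagnetic, Hc = 0
  expect_identical(coercive_field_sw(p10(), env_water(), f), 0)
  # higher frequency leaves less time for activation -> larger Hc
  hc_lo <- coercive_field_sw(p, env_water(), field_210())
  hc_hi <- coercive_field_sw(p, env_water(), field_765())
  expect_gt(hc_hi, hc_lo)
  expect_error(coercive_field_sw(p, env_water(), field_spec(ac_frequency = 1e10)),
               "attempt frequency")
})

test_that("coercivity hits zero exactly at the blocking boundary", {
  p <- p40(); f <- field_765()
  kB <- physical_constants()$kB
  T_block <- p$K * particle_volume(p) / (kB * log(1e10 / f$f))
  at <- coercive_field_sw(p, environment_spec(temperature = T_block), f)
  above <- coercive_field_sw(p, environment_spec(temperature = T_block * 1.01), f)
  just_below <- coercive_field_sw(p, environment_spec(temperature = T_block * 0.999), f)
  expect_equal(at, 0, tolerance = 1e-9)
  expect_identical(above, 0)
  expect_gt(just_below, 0)
  expect_lt(just_below, coercive_field_sw(p, env_water(), f))
})

test_that("hysteresis area applies the squareness, minor-loop rule and linearity", {
  p <- p40(); f <- field_765()
  m0 <- hysteresis_model(0.5, 0)
  expect_identical(hysteresis_area(m0, p, f)$A_v, 0)
  Hc <- 5e3
  a1 <- hysteresis_area(hysteresis_model(0.5, Hc), p, f, Ms_mass = 8)
  a2 <- hysteresis_area(hysteresis_model(0.5, 2 * Hc), p, f, Ms_mass = 8)
  expect_equal(a2$A_v / a1$A_v, 2, tolerance = 1e-12)
  expect_equal(a1$A_m, a1$A_v / p$rho_p, tolerance = 1e-12)
  # drive below the coercive field cannot switch: zero-area minor loop
  H_max <- f$B_ac / physical_constants()$mu0
  blocked <- hysteresis_area(hysteresis_model(0.75, H_max * 1.01), p, f)
  expect_identical(blocked$A_v, 0)
  # printed-input ratio: (0.75 * 18) / (0.5 * 8)
  ch <- hysteresis_area(hysteresis_model(0.75, Hc), p, f, Ms_mass = 18)
  rd <- hysteresis_area(hysteresis_model(0.50, Hc), p, f, Ms_mass = 8)
  expect_equal(ch$A_v / rd$A_v, 3.375, tolerance = 1e-12)
})

test_that("heat source is A * f * omega with a valid volume fraction", {
  expect_identical(heat_source(0, 765e3, 1e-3), 0)
  expect_equal(volume_fraction(4, p40()), 7.722008e-4, tolerance = 1e-6)
  expect_equal(heat_source(1500, 765e3, 7.72e-4) /
                 heat_source(1500, 210e3, 7.72e-4), 765 / 210,
               tolerance = 1e-12)
  expect_error(heat_source(1500, 765e3, 1.2), "volume fraction")
  expect_error(heat_source(1500, 765e3, -0.1), "volume fraction")
})

test_that("predicted SLP is linear in area and frequency", {
  expect_identical(predicted_slp(0, 765e3), 0)
  expect_equal(predicted_slp(0.29, 765e3) / predicted_slp(0.29, 210e3),
               765 / 210, tolerance = 1e-12)
  # degree-1 homogeneity of the whole loss chain in each factor
  p <- p40(); f <- field_765()
  base <- hysteresis_area(hysteresis_model(0.5, 1.4e4), p, f, Ms_mass = 8)
  for (scale in c(2, 0.5)) {
    expect_equal(hysteresis_area(hysteresis_model(0.5 * scale, 1.4e4), p, f,
                                 Ms_mass = 8)$A_v / base$A_v, scale,
                 tolerance = 1e-12)
    expect_equal(hysteresis_area(hysteresis_model(0.5, 1.4e4), p, f,
                                 Ms_mass = 8 * scale)$A_v / base$A_v, scale,
                 tolerance = 1e-12)
    expect_equal(predicted_slp(base$A_m, 765e3 * scale) /
                   predicted_slp(base$A_m, 765e3), scale, tolerance = 1e-12)
  }
})

test_that("chain shape-anisotropy field grows with s toward the zeta(3) limit", {
  p <- p40()
  expect_identical(chain_anisotropy_field(1L, p), 0)
  vals <- vapply(c(2L, 5L, 10L, 50L), chain_anisotropy_field, numeric(1), p = p)
  expect_true(all(diff(vals) > 0))
  expect_gt(chain_anisotropy_field(10L, p, gap = 1),
            chain_anisotropy_field(10L, p, gap = 1.5))
  # lattice-sum factor: sum_{n<s} (s-n)/(s n^3) -> zeta(3)
  fac <- function(s) chain_anisotropy_field(s, p) * 2 * pi * p$d0^3 /
    dipole_moment(p)
  zeta3 <- 1.2020569
  expect_lt(fac(2000), zeta3)
  expect_lt(abs(fac(20000) - zeta3), 2e-4)
})

test_that("loss report and configuration comparison expose the standard columns", {
  p <- p40(); env <- env_water(); f <- field_765()
  rep <- compare_configurations(p, env, f)
  expect_named(rep, c("label", "alpha", "Hc_Am", "A_v_Jm3", "A_m_Jkg",
                      "f_Hz", "SLP_Wg"))
  expect_equal(attr(rep, "slp_ratio"), 3.375, tolerance = 1e-12)
  # shared-Hc default: both rows carry the random-orientation SW value
  expect_equal(rep$Hc_Am[1], rep$Hc_Am[2])
  per <- compare_configurations(p, env, f, hc_mode = "per_orientation")
  expect_equal(per$Hc_Am[1] / per$Hc_Am[2], 1 / 0.48, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loss_report(rep, path)
  back <- read.csv(path)
  expect_equal(back$SLP_Wg, rep$SLP_Wg, tolerance = 1e-9)
})
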