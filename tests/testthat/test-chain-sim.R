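# Brownian dynamics of chain formation: diffusion law, initialization,
# merging and trajectory statistics.

test_that("diffusion coefficients follow Stokes-Einstein and slender-body forms", {
  p <- p40(); env <- env_water()
  D1 <- diffusion_coefficients(1L, p, env)
  expect_equal(D1$D_par, 1.098686e-11, tolerance = 1e-6)
  expect_equal(D1$D_par, D1$D_perp)
  s <- 2:200
  D <- diffusion_coefficients(s, p, env)
  expect_true(all(D$D_par > 0 & D$D_perp > 0))
  # rod forms decay once past the end-correction bump at tiny aspect ratio
  expect_true(all(diff(D$D_par[s >= 4]) < 0))
  expect_true(all(diff(D$D_perp) < 0))
  # axial/lateral ratio rises monotonically toward the slender-body 2
  ratio <- function(s) {
    d <- diffusion_coefficients(s, p, env); d$D_par / d$D_perp
  }
  rs <- vapply(c(10L, 100L, 10000L, 1000000L), ratio, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_true(all(rs < 2))
  expect_gt(ratio(as.integer(1e8)), 1.85)
})

test_that("concentration converts to particle count with override support", {
  p <- p40()
  cfg <- simulation_config(n_particles = 1L, box_d0_units = 80)
  expect_equal(concentration_to_count(1, cfg, p), 189L)
  n1 <- concentration_to_count(1, cfg, p)
  n2 <- concentration_to_count(2, cfg, p)
  expect_equal(n2, 2L * n1, tolerance = 0.01)
  expect_identical(concentration_to_count(1, cfg, p, override = 1520L), 1520L)
  expect_error(concentration_to_count(0, cfg, p), "must be > 0")
})

test_that("initial configurations are non-overlapping and seed-deterministic", {
  p <- p40(); env <- env_water()
  cfg <- simulation_config(n_particles = 120, box_d0_units = 40, seed = 5L)
  st1 <- init_configuration(cfg, p, env)
  st2 <- init_configuration(cfg, p, env)
  expect_identical(st1$pos, st2$pos)
  expect_identical(st1$s, rep(1L, 120))
  # brute-force minimum-image pairwise scan
  L <- st1$L
  mind <- Inf
  for (i in 1:119) for (j in (i + 1):120) {
    d <- st1$pos[i, ] - st1$pos[j, ]
    d <- d - L * round(d / L)
    mind <- min(mind, sqrt(sum(d^2)))
  }
  expect_gte(mind, p$d0)
  # dense regime refused
  cfg_dense <- simulation_config(n_particles = 500, box_d0_units = 5)
  expect_error(init_configuration(cfg_dense, p, env), "packing fraction")
})

test_that("a zero-length step leaves the state untouched and steps conserve particles", {
  p <- p40(); env <- env_water()
  cfg <- simulation_config(n_particles = 50, box_d0_units = 40, seed = 2L)
  st <- init_configuration(cfg, p, env)
  expect_identical(brownian_step(st, cfg, p, env, 0), st)
  st2 <- st
  for (k in 1:25) st2 <- brownian_step(st2, cfg, p, env, dt40())
  expect_identical(sum(st2$s), 50L)
  expect_true(all(st2$pos >= 0 & st2$pos <= st2$L))
})

test_that("merge rule joins qualifying pairs and adds lengths", {
  p <- p40(); env <- env_water()
  cfg <- simulation_config(n_particles = 2, box_d0_units = 80, field_on = TRUE)
  ra1 <- attraction_radius(1L, p, env)
  st <- synthetic_chain_snapshot(c(1L, 1L), spacing = 20 * p$d0, p, env = env)
  st$pos[2, ] <- st$pos[1, ] + c(0, 0, 0.99 * ra1)
  merged <- detect_and_merge(st, cfg, p, env)
  expect_identical(merged$s, 2L)
  expect_identical(merged$merges, 1L)
  # centre of mass of equal partners is the midpoint
  expect_equal(merged$pos[1, 3], st$pos[1, 3] + 0.495 * ra1, tolerance = 1e-12)
  # just outside the zone: nothing happens
  st_out <- synthetic_chain_snapshot(c(1L, 1L), spacing = 20 * p$d0, p, env = env)
  st_out$pos[2, ] <- st_out$pos[1, ] + c(0, 0, 1.01 * ra1)
  expect_identical(detect_and_merge(st_out, cfg, p, env)$s, c(1L, 1L))
  # chains add their lengths: 2 + 3 -> 5
  st23 <- synthetic_chain_snapshot(c(2L, 3L), spacing = 20 * p$d0, p, env = env)
  st23$pos[2, ] <- st23$pos[1, ] +
    c(0, 0, (0.5 + 1) * p$d0 + 0.9 * attraction_radius(3L, p, env))
  expect_identical(detect_and_merge(st23, cfg, p, env)$s, 5L)
})

test_that("no merges happen with the field off or in the weak-coupling regime", {
  p <- p40(); env <- env_water()
  ra1 <- attraction_radius(1L, p, env)
  st <- synthetic_chain_snapshot(c(1L, 1L), spacing = 20 * p$d0, p, env = env)
  st$pos[2, ] <- st$pos[1, ] + c(0, 0, 0.5 * ra1)
  cfg_off <- simulation_config(n_particles = 2, box_d0_units = 80, field_on = FALSE)
  expect_identical(detect_and_merge(st, cfg_off, p, env)$s, c(1L, 1L))
  cfg_on <- simulation_config(n_particles = 2, box_d0_units = 80, field_on = TRUE)
  st_weak <- synthetic_chain_snapshot(c(1L, 1L), spacing = 2 * 10e-9, p10(),
                                      env = env)
  st_weak$pos[2, ] <- st_weak$pos[1, ] + c(0, 0, 1.2 * 10e-9)
  expect_identical(detect_and_merge(st_weak, cfg_on, p10(), env)$s, c(1L, 1L))
})

test_that("the simulator matches a brute-force enumeration on collinear instances", {
  p <- p40(); env <- env_water()
  cfg <- simulation_config(n_particles = 5, box_d0_units = 400, field_on = TRUE)
  cases <- list(
    list(z = c(0, 4, 30, 37, 90), s = c(1L, 1L, 1L, 1L, 1L)),
    list(z = c(0, 5.9, 11.2, 60, 300), s = c(1L, 1L, 1L, 1L, 1L)),
    list(z = c(0, 10, 22, 200), s = c(2L, 1L, 3L, 1L)),
    list(z = c(0, 40, 80), s = c(1L, 1L, 1L))
  )
  for (cs in cases) {
    n <- length(cs$z)
    st <- synthetic_chain_snapshot(cs$s, spacing = 20 * p$d0, p,
                                   box_d0_units = 400, env = env)
    ctr <- st$L / 2
    st$pos <- cbind(rep(ctr, n), rep(ctr, n), ctr + cs$z * p$d0)
    st$upos <- st$pos
    got <- detect_and_merge(st, cfg, p, env)
    want <- oracle_collinear_merge(ctr + cs$z * p$d0, cs$s, p)
    expect_identical(sort(got$s), as.integer(want$s))
    expect_equal(sort(got$pos[, 3]), want$z, tolerance = 1e-9)
  }
})

test_that("trajectories are reproducible, conserving and monotone in mean length", {
  p <- p40(); env <- env_water()
  cfg <- simulation_config(n_particles = 60, box_d0_units = 40,
                           total_time = 500 * dt40(), seed = 11L,
                           snapshot_every = 50L)
  sim1 <- run_simulation(cfg, p, env)
  sim2 <- run_simulation(cfg, p, env)
  expect_identical(sim1$trajectory, sim2$trajectory)
  for (sn in sim1$trajectory) expect_identical(sum(sn$s), 60L)
  ms <- sim1$statistics$timeseries$mean_length
  expect_identical(ms[1], 1)
  expect_true(all(diff(ms) >= 0))
  expect_gt(sim1$state$merges, 0L)
})

test_that("the weak-coupling population never chains", {
  p <- p10(); env <- env_water()
  cfg <- simulation_config(n_particles = 80, box_d0_units = 40,
                           total_time = 300 * resolve_dt_for_test(p, env),
                           seed = 3L, snapshot_every = 100L)
  sim <- run_simulation(cfg, p, env)
  expect_true(all(sim$state$s == 1L))
  expect_identical(sim$state$merges, 0L)
})

test_that("chain statistics match hand-built fixtures", {
  p <- p40()
  # two chains, s = 3 and s = 5, 10 d0 apart laterally
  st <- synthetic_chain_snapshot(c(3L, 5L), spacing = 10 * p$d0, p)
  stats <- compute_statistics(as_trajectory(st))
  ts <- stats$timeseries
  expect_equal(ts$mean_length, 4)
  expect_equal(ts$mean_spacing, 10 * p$d0, tolerance = 1e-12)
  expect_equal(ts$order_parameter, 1)
  expect_identical(stats$n_particles, 8L)
  # all singletons: spacing and order parameter are undefined
  st1 <- synthetic_chain_snapshot(c(1L, 1L, 1L), spacing = 5 * p$d0, p)
  ts1 <- compute_statistics(as_trajectory(st1))$timeseries
  expect_equal(ts1$mean_length, 1)
  expect_true(is.na(ts1$mean_spacing))
  expect_true(is.na(ts1$order_parameter))
  expect_error(compute_statistics(list()), "empty trajectory")
})

test_that("trajectory writers produce well-formed XYZ and CSV", {
  p <- p40(); env <- env_water()
  cfg <- simulation_config(n_particles = 20, box_d0_units = 40,
                           total_time = 100 * dt40(), seed = 4L,
                           snapshot_every = 50L)
  sim <- run_simulation(cfg, p, env)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_xyz(sim$trajectory, xyz)
  write_trajectory_csv(sim$trajectory, csv)
  lines <- readLines(xyz)
  n1 <- as.integer(lines[1])
  expect_identical(n1, nrow(sim$trajectory[[1]]))
  expect_match(lines[3], "^S[0-9]+ ")
  df <- read.csv(csv)
  expect_true(all(tapply(df$s, df$t, sum) == 20L))
})
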