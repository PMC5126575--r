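# On-the-fly coarse-grained Brownian dynamics of field-driven chain
# formation. Simulation objects are single particles or rigid head-to-tail
# chains pinned to the field (z) axis; a chain of s particles is a segment
# of physical extent s*d0 whose bead centres span (s-1)*d0. Objects diffuse
# with anisotropic slender-body coefficients and merge instantaneously when
# a tip enters the dipolar attraction zone of another object. Merging only
# ever grows chains, so the object count decreases and the simulation
# coarsens as it runs.

#' Translational diffusion coefficients of a chain
#'
#' A single particle diffuses isotropically with the Stokes-Einstein
#' coefficient D = kB T / (3 pi eta d0). A chain of s >= 2 particles is
#' treated as a rigid rod of length s*d0 with end-corrected slender-body
#' coefficients
#' D_par = kB T (ln s - 0.207) / (2 pi eta s d0) along the axis and
#' D_perp = kB T (ln s + 0.839) / (4 pi eta s d0) across it, approaching the
#' slender-body ratio D_par/D_perp -> 2 for long chains. The end corrections
#' are only asymptotically accurate: for s in 2-3 they place D_par slightly
#' below D_perp, a known small-aspect-ratio artifact.
#'
#' @param s Integer chain length(s), vectorized.
#' @param p A [particle_spec()].
#' @param env An [environment_spec()].
#' @return List with numeric vectors `D_par` and `D_perp` (m^2/s).
#' @export
diffusion_coefficients <- function(s, p, env) {
  s <- as.integer(s)
  if (any(s < 1)) stop("chain length s must be >= 1")
  kT <- KB * env$T
  D1 <- kT / (3 * pi * env$eta * p$d0)
  D_par <- ifelse(s == 1L, D1, kT * (log(s) - 0.207) / (2 * pi * env$eta * s * p$d0))
  D_perp <- ifelse(s == 1L, D1, kT * (log(s) + 0.839) / (4 * pi * env$eta * s * p$d0))
  list(D_par = D_par, D_perp = D_perp)
}

#' Particle count from mass concentration
#'
#' N = round(c L^3 / (rho_p V)), the number of particles of volume V and
#' density rho_p needed to realize concentration c in the simulation box.
#' An explicit `override` short-circuits the conversion (used to reproduce
#' published counts directly).
#'
#' @param concentration Mass concentration in kg/m^3 (= mg/mL).
#' @param cfg A [simulation_config()] (supplies the box side).
#' @param p A [particle_spec()].
#' @param override Optional integer N to use verbatim.
#' @return Integer particle count.
#' @export
concentration_to_count <- function(concentration, cfg, p, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (concentration <= 0) stop("concentration must be > 0")
  L <- cfg$box_d0 * p$d0
  as.integer(round(concentration * L^3 / (p$rho_p * particle_volume(p))))
}

# ---- internal geometry helpers ------------------------------------------

# minimum-image convention for a vector of coordinate differences
min_image <- function(d, L) d - L * round(d / L)

# centre-line half-extents of chains (bead-centre span / 2)
half_extent <- function(s, d0) (s - 1) * d0 / 2

# Pairwise separations for object pairs (i, j). `seg_dist` is the distance
# between the two z-aligned centre-line segments (< d0 means the bead
# surfaces interpenetrate); `tip_dist` is the minimum of the four
# tip-to-tip distances (the quantity the attraction-zone test uses).
pair_deltas <- function(i, j, pos, L, periodic) {
  dx <- pos[j, 1] - pos[i, 1]
  dy <- pos[j, 2] - pos[i, 2]
  dz <- pos[j, 3] - pos[i, 3]
  if (periodic) {
    dx <- min_image(dx, L); dy <- min_image(dy, L); dz <- min_image(dz, L)
  }
  list(dxy2 = dx^2 + dy^2, dz = dz)
}

pair_seg_dist <- function(del, hi, hj) {
  zgap <- pmax(0, abs(del$dz) - (hi + hj))
  sqrt(del$dxy2 + zgap^2)
}

pair_tip_dist <- function(del, hi, hj, L, periodic) {
  tip_dz <- pmin(abs(del$dz + hi + hj), abs(del$dz + hi - hj),
                 abs(del$dz - hi + hj), abs(del$dz - hi - hj))
  if (periodic) tip_dz <- pmin(tip_dz, abs(L - tip_dz))
  sqrt(del$dxy2 + tip_dz^2)
}

# all i<j index pairs for m objects
pair_index <- function(m) {
  if (m < 2L) return(list(i = integer(0), j = integer(0)))
  j <- rep.int(seq_len(m), seq_len(m) - 1L)
  i <- sequence(seq_len(m) - 1L)
  list(i = i, j = j)
}

# cached attraction radii, indexed by chain length
get_attraction_radii <- function(state, s_needed, p, env) {
  cache <- state$ra_env
  smax <- max(s_needed)
  if (is.null(cache$ra)) cache$ra <- rep(NA_real_, 0)
  if (length(cache$ra) < smax) cache$ra <- c(cache$ra, rep(NA_real_, smax - length(cache$ra)))
  for (sv in unique(s_needed)) {
    if (is.na(cache$ra[sv])) cache$ra[sv] <- attraction_radius(sv, p, env)
  }
  cache$ra[s_needed]
}

# ---- state construction --------------------------------------------------

new_simulation_state <- function(t, ids, s, pos, upos, merges, L, d0, gamma) {
  structure(
    list(t = t, ids = ids, s = s, pos = pos, upos = upos,
         merges = merges, L = L, d0 = d0, gamma = gamma,
         ra_env = new.env(parent = emptyenv())),
    class = "simulation_state"
  )
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> t = %.4g s, %d objects, N = %d particles, <s> = %.2f, %d merges\n",
              x$t, length(x$ids), sum(x$s), mean(x$s), x$merges))
  invisible(x)
}

#' Random non-overlapping initial configuration
#'
#' Places N singleton particles uniformly in the periodic box with minimum
#' pairwise (centre) distance d0, by sequential rejection sampling. The
#' placement is a pure function of the configured seed. Dense systems
#' (particle packing fraction above 0.3) are refused.
#'
#' @param cfg A [simulation_config()].
#' @param p A [particle_spec()].
#' @param env An [environment_spec()].
#' @return A `simulation_state` of N singletons at t = 0.
#' @export
init_configuration <- function(cfg, p, env) {
  L <- cfg$box_d0 * p$d0
  phi <- cfg$N * particle_volume(p) / L^3
  if (phi > 0.3)
    stop(sprintf("packing fraction %.3f > 0.3: dense regime unsupported", phi))
  set.seed(cfg$seed)
  periodic <- cfg$boundary == "periodic"
  pos <- matrix(NA_real_, cfg$N, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < cfg$N) {
    cand <- stats::runif(3, 0, L)
    ok <- TRUE
    if (placed > 0L) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      if (periodic) d <- min_image(d, L)
      ok <- min(rowSums(d^2)) >= p$d0^2
    }
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    attempts <- attempts + 1L
    if (attempts > 2000L * cfg$N)
      stop("failed to place particles without overlap; box too crowded")
  }
  new_simulation_state(t = 0, ids = seq_len(cfg$N),
                       s = rep(1L, cfg$N), pos = pos, upos = pos,
                       merges = 0L, L = L, d0 = p$d0,
                       gamma = coupling_parameter(p, env))
}

#' One Brownian displacement step
#'
#' Every object receives independent Gaussian per-axis displacements with
#' variance 2 D dt, using D_par along the field (z) axis and D_perp along x
#' and y (isotropic D for singletons). Draws are consumed in stable object-id
#' order, so trajectories are reproducible. The boundary rule is applied
#' (periodic wrap or reflection), and a move that would push two objects
#' into overlap (segment distance < d0 and shrinking) without satisfying the
#' attraction-zone test is rejected for both partners this step.
#'
#' @param state A `simulation_state`.
#' @param cfg A [simulation_config()].
#' @param p A [particle_spec()].
#' @param env An [environment_spec()].
#' @param dt Time step in s (0 leaves the state unchanged).
#' @return The advanced `simulation_state`.
#' @export
brownian_step <- function(state, cfg, p, env, dt) {
  if (dt < 0) stop("time step must be >= 0")
  if (dt == 0) return(state)
  m <- length(state$ids)
  D <- diffusion_coefficients(state$s, p, env)
  disp <- matrix(stats::rnorm(3L * m), m, 3)
  disp[, 1] <- disp[, 1] * sqrt(2 * D$D_perp * dt)
  disp[, 2] <- disp[, 2] * sqrt(2 * D$D_perp * dt)
  disp[, 3] <- disp[, 3] * sqrt(2 * D$D_par * dt)
  prop <- state$pos + disp
  L <- state$L
  periodic <- cfg$boundary == "periodic"
  if (periodic) {
    prop <- prop %% L
  } else {
    # reflecting walls; one reflection suffices for steps << L
    prop <- abs(prop)
    prop <- L - abs(L - prop)
  }
  accepted <- rep(TRUE, m)
  if (m >= 2L) {
    idx <- pair_index(m)
    hi <- half_extent(state$s[idx$i], state$d0)
    hj <- half_extent(state$s[idx$j], state$d0)
    new_del <- pair_deltas(idx$i, idx$j, prop, L, periodic)
    new_seg <- pair_seg_dist(new_del, hi, hj)
    overlap <- which(new_seg < state$d0)
    if (length(overlap) > 0L) {
      io <- idx$i[overlap]; jo <- idx$j[overlap]
      cur_del <- pair_deltas(io, jo, state$pos, L, periodic)
      cur_seg <- pair_seg_dist(cur_del, hi[overlap], hj[overlap])
      shrinking <- new_seg[overlap] < cur_seg
      allowed <- rep(FALSE, length(overlap))
      if (cfg$field_on && state$gamma > 1) {
        tip <- pair_tip_dist(new_del, hi, hj, L, periodic)
        ra <- get_attraction_radii(state, pmax(state$s[io], state$s[jo]), p, env)
        allowed <- tip[overlap] < ra
      }
      bad <- which(shrinking & !allowed)
      accepted[io[bad]] <- FALSE
      accepted[jo[bad]] <- FALSE
    }
  }
  state$pos[accepted, ] <- prop[accepted, , drop = FALSE]
  state$upos[accepted, ] <- state$upos[accepted, , drop = FALSE] +
    disp[accepted, , drop = FALSE]
  state$t <- state$t + dt
  state
}

#' Detect attraction-zone contacts and merge chains
#'
#' A pair qualifies for aggregation when the distance from one object's tip
#' to the nearer tip of the other is below the attraction radius r_a of the
#' longer partner. Qualifying pairs are processed closest-first; each merge
#' replaces the two objects by one chain with s = s1 + s2 at their
#' length-weighted centre of mass (minimum-image aware), axis on z, and the
#' scan repeats until no pair qualifies. With the field off, or in the
#' weak-coupling regime Gamma <= 1, this is a no-op: no chains ever form.
#'
#' @inheritParams brownian_step
#' @return The (possibly coarsened) `simulation_state`.
#' @export
detect_and_merge <- function(state, cfg, p, env) {
  if (!cfg$field_on || state$gamma <= 1) return(state)
  periodic <- cfg$boundary == "periodic"
  L <- state$L
  repeat {
    m <- length(state$ids)
    if (m < 2L) break
    idx <- pair_index(m)
    hi <- half_extent(state$s[idx$i], state$d0)
    hj <- half_extent(state$s[idx$j], state$d0)
    del <- pair_deltas(idx$i, idx$j, state$pos, L, periodic)
    tip <- pair_tip_dist(del, hi, hj, L, periodic)
    ra <- get_attraction_radii(state, pmax(state$s[idx$i], state$s[idx$j]), p, env)
    qual <- which(tip < ra)
    if (length(qual) == 0L) break
    k <- qual[which.min(tip[qual])]
    i <- idx$i[k]; j <- idx$j[k]
    si <- state$s[i]; sj <- state$s[j]
    w <- sj / (si + sj)
    dvec <- state$pos[j, ] - state$pos[i, ]
    if (periodic) dvec <- min_image(dvec, L)
    com <- state$pos[i, ] + w * dvec
    if (periodic) com <- com %% L
    keep <- setdiff(seq_len(m), c(i, j))
    new_id <- min(state$ids[c(i, j)])
    state$ids <- c(state$ids[keep], new_id)
    state$s <- c(state$s[keep], si + sj)
    state$pos <- unname(rbind(state$pos[keep, , drop = FALSE], com))
    state$upos <- unname(rbind(state$upos[keep, , drop = FALSE], com))
    ord <- order(state$ids)
    state$ids <- state$ids[ord]
    state$s <- state$s[ord]
    state$pos <- state$pos[ord, , drop = FALSE]
    state$upos <- state$upos[ord, , drop = FALSE]
    state$merges <- state$merges + 1L
  }
  state
}

snapshot_frame <- function(state) {
  data.frame(t = state$t, id = state$ids, s = state$s,
             x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
             ux = state$upos[, 1], uy = state$upos[, 2], uz = state$upos[, 3])
}

#' Run a chain-formation simulation
#'
#' Alternates [brownian_step()] and [detect_and_merge()] for
#' `total_time / dt` steps from a fresh random configuration, recording
#' snapshots every `snapshot_every` steps. The whole trajectory is a pure
#' function of `(cfg, p, env)`: identical configurations and seeds give
#' bit-identical trajectories.
#'
#' @param cfg A [simulation_config()].
#' @param p A [particle_spec()].
#' @param env An [environment_spec()].
#' @return A list of class `chain_simulation` with elements `state` (final
#'   [simulation_state]), `statistics` ([compute_statistics()] output),
#'   `trajectory` (list of snapshot data frames, attributes `L`, `d0`) and
#'   `dt` (the time step actually used).
#' @export
run_simulation <- function(cfg, p, env) {
  dt <- resolve_time_step(cfg, p, env)
  state <- init_configuration(cfg, p, env)   # seeds the RNG
  nsteps <- max(1L, as.integer(round(cfg$total_time / dt)))
  trajectory <- list(snapshot_frame(state))
  for (step in seq_len(nsteps)) {
    state <- brownian_step(state, cfg, p, env, dt)
    state <- detect_and_merge(state, cfg, p, env)
    if (step %% cfg$snapshot_every == 0L || step == nsteps)
      trajectory[[length(trajectory) + 1L]] <- snapshot_frame(state)
  }
  attr(trajectory, "L") <- state$L
  attr(trajectory, "d0") <- state$d0
  structure(list(state = state, statistics = compute_statistics(trajectory),
                 trajectory = trajectory, dt = dt),
            class = "chain_simulation")
}

#' @export
print.chain_simulation <- function(x, ...) {
  ts <- x$statistics$timeseries
  cat(sprintf("<chain_simulation> %d snapshots, final t = %.4g s, final <s> = %.2f (%d objects)\n",
              nrow(ts), ts$t[nrow(ts)], ts$mean_length[nrow(ts)],
              ts$n_objects[nrow(ts)]))
  invisible(x)
}

#' Wrap a hand-built snapshot as a trajectory
#'
#' @param snapshot A snapshot data frame (columns `t`, `id`, `s`, `x`, `y`,
#'   `z`) or a `simulation_state`.
#' @param L Box side in m.
#' @param d0 Particle diameter in m.
#' @return A one-snapshot trajectory usable by [compute_statistics()].
#' @export
as_trajectory <- function(snapshot, L, d0) {
  if (inherits(snapshot, "simulation_state")) {
    L <- snapshot$L; d0 <- snapshot$d0
    snapshot <- snapshot_frame(snapshot)
  }
  traj <- list(snapshot)
  attr(traj, "L") <- L
  attr(traj, "d0") <- d0
  traj
}

#' Chain statistics of a trajectory
#'
#' Per snapshot: mean chain length, object count, bond alignment order
#' parameter <cos^2 theta> (bonds of all chains lie on the field axis, so
#' this is 1 whenever any chain exists and NA in an all-singleton state) and
#' the mean lateral (x-y, minimum-image) nearest-neighbour spacing between
#' chains of s >= 2 (NA when fewer than two chains exist). Also returns the
#' final chain-length histogram.
#'
#' @param trajectory Snapshot list as produced by [run_simulation()] or
#'   [as_trajectory()].
#' @return An object of class `chain_statistics`: list with `timeseries`
#'   (data frame `t`, `mean_length`, `n_objects`, `order_parameter`,
#'   `mean_spacing`), `final_histogram` (named vector) and
#'   `n_particles`.
#' @export
compute_statistics <- function(trajectory) {
  if (length(trajectory) == 0L) stop("empty trajectory")
  L <- attr(trajectory, "L")
  if (is.null(L)) stop("trajectory lacks box-size attribute; use as_trajectory()")
  rows <- lapply(trajectory, function(sn) {
    chains <- sn[sn$s >= 2L, , drop = FALSE]
    nb <- sum(pmax(sn$s - 1L, 0L))         # number of intra-chain bonds
    op <- if (nb > 0L) 1 else NA_real_      # all bonds on the field axis
    sp <- NA_real_
    if (nrow(chains) >= 2L) {
      dx <- min_image(outer(chains$x, chains$x, `-`), L)
      dy <- min_image(outer(chains$y, chains$y, `-`), L)
      dl <- sqrt(dx^2 + dy^2)
      diag(dl) <- Inf
      sp <- mean(apply(dl, 1, min))
    }
    data.frame(t = sn$t[1], mean_length = mean(sn$s),
               n_objects = nrow(sn), order_parameter = op, mean_spacing = sp)
  })
  final <- trajectory[[length(trajectory)]]
  structure(
    list(timeseries = do.call(rbind, rows),
         final_histogram = table(factor(final$s, levels = seq_len(max(final$s)))),
         n_particles = sum(final$s)),
    class = "chain_statistics"
  )
}

#' @export
print.chain_statistics <- function(x, ...) {
  ts <- x$timeseries
  cat(sprintf("<chain_statistics> %d snapshots, N = %d, final <s> = %.2f\n",
              nrow(ts), x$n_particles, ts$mean_length[nrow(ts)]))
  invisible(x)
}

#' Write a trajectory in XYZ format
#'
#' One pseudo-atom per simulation object; the element tag encodes the chain
#' length bucket (`S1` singleton, `S2` for 2-4, `S5` for 5-9, `S10` for
#' >= 10). Coordinates are written in nm.
#'
#' @param trajectory Snapshot list from [run_simulation()].
#' @param path Output file.
#' @export
write_xyz <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sn in trajectory) {
    writeLines(as.character(nrow(sn)), con)
    writeLines(sprintf("t = %.6g s", sn$t[1]), con)
    tag <- cut(sn$s, breaks = c(0, 1, 4, 9, Inf),
               labels = c("S1", "S2", "S5", "S10"))
    writeLines(sprintf("%s %.4f %.4f %.4f", tag,
                       sn$x * 1e9, sn$y * 1e9, sn$z * 1e9), con)
  }
  invisible(path)
}

#' Write a trajectory sidecar CSV
#'
#' Long-format table: `t`, `id`, `s`, `x`, `y`, `z` (SI units).
#'
#' @inheritParams write_xyz
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- do.call(rbind, lapply(trajectory, function(sn)
    sn[, c("t", "id", "s", "x", "y", "z")]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write chain statistics as CSV
#'
#' @param stats A `chain_statistics` object.
#' @param path Output file.
#' @export
write_statistics_csv <- function(stats, path) {
  utils::write.csv(stats$timeseries, path, row.names = FALSE)
  invisible(path)
}
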