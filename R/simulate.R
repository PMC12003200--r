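# Synthetic MINFLUX data generation: jump-step trajectory simulator (the
# forward model used by the mixture fits), scaffold blinking streams, gold
# fiducials and cargo transport cohorts, all ground-truthed and seeded.

.UM2S_TO_NM2S <- 1e6  # 1 um^2/s = 1e6 nm^2/s

#' Species specification for the jump-step simulator
#'
#' One molecular species is described by a diffusion coefficient and three
#' localization-error sources that the simulator adds independently per
#' localization: measurement precision (anisotropic Gaussian), "jiggle"
#' (isotropic Gaussian wobble of the dye about its attachment centroid) and
#' sphere rotation (dye at fixed radius from the particle centroid, direction
#' re-randomized every localization). Unless overridden, the axial precision
#' ratios sigma_x/sigma_y = 0.93 and sigma_x/sigma_z = 1.55 are applied.
#'
#' @param weight mixture fraction in \[0, 1\].
#' @param D diffusion coefficient, um^2/s; scalar (isotropic, per-axis
#'   variance 2Dt) or length-3 `(Dx, Dy, Dz)` for anisotropic drift.
#' @param sigma_x per-localization precision along x, nm.
#' @param sigma_y,sigma_z precisions along y and z, nm; default
#'   `sigma_x/0.93` and `sigma_x/1.55`.
#' @param jiggle sd of the dye wobble about its centroid, nm (per axis).
#' @param sphere_radius dye offset radius from the particle centroid, nm.
#' @return list of class `species_spec`.
#' @export
species_spec <- function(weight = 1, D = 0, sigma_x = 0,
                         sigma_y = sigma_x / 0.93,
                         sigma_z = sigma_x / 1.55,
                         jiggle = 0, sphere_radius = 0) {
  stopifnot(weight >= 0, weight <= 1, all(D >= 0),
            length(D) %in% c(1L, 3L),
            sigma_x >= 0, sigma_y >= 0, sigma_z >= 0,
            jiggle >= 0, sphere_radius >= 0)
  structure(list(weight = weight, D = as.numeric(D),
                 sigma = c(x = sigma_x, y = sigma_y, z = sigma_z),
                 jiggle = jiggle, sphere_radius = sphere_radius),
            class = "species_spec")
}

#' Inter-localization timestep model
#'
#' MINFLUX rejects localization attempts below a minimum photon count and
#' retries, so intervals between accepted localizations are integer multiples
#' of the base scan cycle. Three models are supported: `fixed` (constant
#' `base_ms`), `geometric_retry` (cycle count geometric with failure
#' probability `retry_p`, mean `base_ms/(1 - retry_p)`) and `empirical`
#' (durations drawn from a user table).
#'
#' @param kind `"fixed"`, `"geometric_retry"` or `"empirical"`.
#' @param base_ms base scan-cycle duration, ms.
#' @param retry_p probability a localization attempt fails (geometric mode).
#' @param table data frame with columns `duration_ms`, `freq` (empirical
#'   mode); frequencies must sum to 1.
#' @return list of class `timestep_model`.
#' @export
timestep_model <- function(kind = c("fixed", "geometric_retry", "empirical"),
                           base_ms = 3.3, retry_p = 0, table = NULL) {
  kind <- match.arg(kind)
  if (kind == "empirical") {
    if (is.null(table) || !nrow(table))
      stop("empirical timestep model requires a non-empty table", call. = FALSE)
    stopifnot(all(c("duration_ms", "freq") %in% names(table)),
              all(table$duration_ms > 0),
              abs(sum(table$freq) - 1) < 1e-8)
  } else {
    stopifnot(base_ms > 0, retry_p >= 0, retry_p < 1)
  }
  structure(list(kind = kind, base_ms = base_ms, retry_p = retry_p,
                 table = table),
            class = "timestep_model")
}

#' Sample inter-localization intervals
#'
#' @param model a [timestep_model()].
#' @param n number of intervals.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers embedding this in a larger seeded simulation stay
#'   reproducible).
#' @return numeric vector of `n` durations in milliseconds.
#' @export
sample_timesteps <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "timestep_model"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  switch(model$kind,
    fixed = rep(model$base_ms, n),
    geometric_retry = model$base_ms *
      (1 + stats::rgeom(n, prob = 1 - model$retry_p)),
    empirical = sample(model$table$duration_ms, n, replace = TRUE,
                       prob = model$table$freq))
}

#' Simulation configuration for jump-step trajectories
#'
#' @param seed integer seed (reproducibility: identical seed + config gives
#'   bit-identical output).
#' @param n_traj number of trajectories.
#' @param traj_len localizations per trajectory (>= 2).
#' @param species list of [species_spec()]; weights must sum to 1.
#' @param timesteps a [timestep_model()].
#' @param drift_D length-3 `(Dx, Dy, Dz)` in um^2/s: sample drift applied as
#'   a single random walk shared by every localization in acquisition order
#'   (zero by default).
#' @param traj_gap_s idle time inserted between consecutive trajectories on
#'   the shared acquisition clock, seconds.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_traj = 100L, traj_len = 10L,
                              species = list(species_spec()),
                              timesteps = timestep_model("fixed", 3.3),
                              drift_D = c(0, 0, 0), traj_gap_s = 0.05) {
  if (inherits(species, "species_spec")) species <- list(species)
  w <- vapply(species, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop("species weights must sum to 1 (got ", sum(w), ")", call. = FALSE)
  stopifnot(traj_len >= 2, n_traj >= 1, length(drift_D) == 3,
            all(drift_D >= 0), inherits(timesteps, "timestep_model"))
  structure(list(seed = as.integer(seed), n_traj = as.integer(n_traj),
                 traj_len = as.integer(traj_len), species = species,
                 timesteps = timesteps, drift_D = as.numeric(drift_D),
                 traj_gap_s = traj_gap_s),
            class = "simulation_config")
}

# Per-axis diffusion sds (nm) for one species over timesteps dt_s.
.axis_step_sd <- function(D_um2s, dt_s) {
  D3 <- if (length(D_um2s) == 3) D_um2s else rep(D_um2s, 3)
  sqrt(outer(dt_s, 2 * D3 * .UM2S_TO_NM2S))  # n x 3, nm
}

#' Simulate jump-step trajectories with a full localization-error model
#'
#' Trajectories perform unconstrained 3D diffusion: per-axis true increments
#' over a timestep `t` are Gaussian with variance `2 D t` (so the 3D step
#' variance is `6 D t`). Each observed localization independently adds
#' measurement-precision noise `N(0, sigma_axis^2)`, jiggle `N(0, jiggle^2)`
#' per axis, and a sphere-rotation offset (uniform point on a sphere of the
#' species' `sphere_radius`) — jiggle and rotation re-randomize every
#' localization. `drift_D` adds one shared sample-drift random walk across
#' the whole acquisition. Timesteps come from the configured model, emulating
#' photon-limited retries.
#'
#' @param config a [simulation_config()].
#' @return list with `points` (data frame: `traj_id`, `species`, `t` seconds
#'   on the shared clock, observed `x`,`y`,`z` nm, true positions
#'   `x_true`,`y_true`,`z_true`) and `config`.
#' @export
simulate_jump_trajectories <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_traj; L <- config$traj_len
  nstep <- n * (L - 1L); npts <- n * L
  k <- length(config$species)
  dt_ms <- sample_timesteps(config$timesteps, nstep)
  dt_s <- dt_ms / 1000
  sp <- if (k == 1L) rep(1L, n) else
    sample.int(k, n, replace = TRUE,
               prob = vapply(config$species, `[[`, numeric(1), "weight"))
  # Draws happen in a fixed order and are skipped only for error sources
  # disabled in every species, so the RNG stream depends on which sources
  # are active but never on their values (common random numbers for the
  # simulation-based fits, where a species' active sources are fixed).
  need_diff <- any(vapply(config$species, function(s) any(s$D > 0), TRUE))
  need_prec <- any(vapply(config$species, function(s) any(s$sigma > 0), TRUE))
  need_jig <- any(vapply(config$species, function(s) s$jiggle > 0, TRUE))
  need_sph <- any(vapply(config$species, function(s) s$sphere_radius > 0, TRUE))
  z_diff <- if (need_diff) matrix(stats::rnorm(3 * nstep), nstep, 3)
  z_prec <- if (need_prec) matrix(stats::rnorm(3 * npts), npts, 3)
  z_jig  <- if (need_jig) matrix(stats::rnorm(3 * npts), npts, 3)
  z_sph  <- if (need_sph) matrix(stats::rnorm(3 * npts), npts, 3)

  traj_of_step <- rep(seq_len(n), each = L - 1L)
  traj_of_pt <- rep(seq_len(n), each = L)
  sp_step <- sp[traj_of_step]; sp_pt <- sp[traj_of_pt]

  true_inc <- matrix(0, nstep, 3)
  err <- matrix(0, npts, 3)
  for (j in seq_len(k)) {
    spec <- config$species[[j]]
    is_j <- sp_step == j
    if (any(is_j) && need_diff && any(spec$D > 0))
      true_inc[is_j, ] <- z_diff[is_j, , drop = FALSE] *
        .axis_step_sd(spec$D, dt_s[is_j])
    ip <- sp_pt == j
    if (any(ip)) {
      e <- matrix(0, sum(ip), 3)
      if (need_prec)
        e <- e + sweep(z_prec[ip, , drop = FALSE], 2, spec$sigma, `*`)
      if (need_jig)
        e <- e + z_jig[ip, , drop = FALSE] * spec$jiggle
      if (need_sph && spec$sphere_radius > 0) {
        dir <- z_sph[ip, , drop = FALSE]
        nrm <- sqrt(rowSums(dir^2)); nrm[nrm == 0] <- 1
        e <- e + dir / nrm * spec$sphere_radius
      }
      err[ip, ] <- e
    }
  }

  # cumulative true positions per trajectory (start at origin)
  pos <- matrix(0, npts, 3)
  step_rows <- which(rep(c(FALSE, rep(TRUE, L - 1L)), n))
  traj_ends <- cumsum(rep(L - 1L, n))
  for (a in 1:3) {
    cum <- cumsum(true_inc[, a])
    prev_end <- c(0, cum[traj_ends[-n]])
    pos[step_rows, a] <- cum - rep(prev_end, each = L - 1L)
  }

  # shared acquisition clock: trajectory steps plus inter-trajectory gaps
  gap <- config$traj_gap_s
  dt_full <- numeric(npts)
  first_pt <- seq(1L, npts, by = L)
  dt_full[-first_pt] <- dt_s
  dt_full[first_pt[-1]] <- gap
  t_all <- cumsum(dt_full)

  obs <- pos + err
  if (any(config$drift_D > 0)) {
    dtg <- diff(t_all); dtg[dtg < 0] <- 0  # defensive; clock is monotone
    drift <- matrix(0, npts, 3)
    zd <- matrix(stats::rnorm(3 * (npts - 1L)), npts - 1L, 3)
    for (a in 1:3) {
      sd_a <- sqrt(2 * config$drift_D[a] * .UM2S_TO_NM2S * dtg)
      drift[, a] <- c(0, cumsum(zd[, a] * sd_a))
    }
    obs <- obs + drift
  }

  points <- data.frame(traj_id = traj_of_pt, species = sp_pt, t = t_all,
                       x = obs[, 1], y = obs[, 2], z = obs[, 3],
                       x_true = pos[, 1], y_true = pos[, 2], z_true = pos[, 3])
  list(points = points, config = config)
}

#' Ground-truth poses for a field of NPC scaffolds
#'
#' Pores are laid out on a jittered grid with a minimum centre separation,
#' each with a double-ring geometry (shared ring radius, cytoplasmic ring at
#' `+ring_spacing/2`, nucleoplasmic at `-ring_spacing/2`) and a uniform
#' random eightfold phase in \[0, 45).
#'
#' @param n_pores number of pores.
#' @param ring_radius nm; default 53.5 (a structural convention for the
#'   NUP96 ring, configurable — not a measured constant of this pipeline).
#' @param ring_spacing nm between the two rings (default 51.5, the
#'   astigmatism reference value).
#' @param spacing_nm centre-to-centre grid pitch, nm.
#' @param z0_sd sd of pore centre height about z = 0, nm.
#' @param seed integer seed.
#' @return data frame of class `scaffold_truth`: `pore_id`, `x0`, `y0`,
#'   `z0`, `ring_radius`, `ring_spacing`, `phase_deg`, `tilt_deg`.
#' @export
make_scaffold_truth <- function(n_pores, ring_radius = 53.5,
                                ring_spacing = 51.5, spacing_nm = 400,
                                z0_sd = 15, seed = 1L) {
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_pores))
  ix <- (seq_len(n_pores) - 1L) %% ncol_grid
  iy <- (seq_len(n_pores) - 1L) %/% ncol_grid
  jit <- spacing_nm * 0.15
  truth <- data.frame(
    pore_id = seq_len(n_pores),
    x0 = ix * spacing_nm + stats::runif(n_pores, -jit, jit),
    y0 = iy * spacing_nm + stats::runif(n_pores, -jit, jit),
    z0 = stats::rnorm(n_pores, 0, z0_sd),
    ring_radius = ring_radius,
    ring_spacing = ring_spacing,
    phase_deg = stats::runif(n_pores, 0, 45),
    tilt_deg = 0)
  stopifnot(all(truth$tilt_deg < 10), all(truth$ring_spacing > 0))
  class(truth) <- c("scaffold_truth", "data.frame")
  truth
}

#' Simulate a scaffold-channel blinking-dye localization stream
#'
#' Emitters sit on the 16 corner sites of each pore (2 rings x 8 corners at
#' 45 degree intervals starting at the pore's phase). Each occupied corner
#' produces a number of blinking bursts; each burst is a run of
#' localizations at the base scan cycle carrying that corner's position plus
#' per-localization noise from `sigma_spec`. Every burst gets its own
#' `trace_id` (as acquisition software assigns). Photometric columns are
#' drawn from scaffold-dye-like ranges so the stream passes EFO/CFR gates.
#'
#' @param truth a [make_scaffold_truth()] data frame.
#' @param sigma_spec [species_spec()] supplying the localization noise
#'   (default sigma_x = 4.1 nm, typical scaffold-dye precision).
#' @param mean_bursts_per_corner Poisson mean number of bursts per corner.
#' @param mean_locs_per_burst mean localizations per burst (>= 1).
#' @param occupancy probability a corner site carries a labelled emitter.
#' @param base_cycle_ms intra-burst localization interval, ms.
#' @param deterministic if `TRUE`, every corner emits exactly
#'   `mean_bursts_per_corner` bursts of exactly `mean_locs_per_burst`
#'   localizations (construction tests); otherwise counts are Poisson.
#' @param seed integer seed.
#' @return list with `records` (localization data frame, channel
#'   `"scaffold"`) and `labels` (data frame `pore_id`, `corner`, `ring` per
#'   localization).
#' @export
simulate_scaffold_stream <- function(truth,
                                     sigma_spec = species_spec(sigma_x = 4.1),
                                     mean_bursts_per_corner = 2,
                                     mean_locs_per_burst = 4,
                                     occupancy = 0.9,
                                     base_cycle_ms = 3.3,
                                     deterministic = FALSE,
                                     seed = 1L) {
  stopifnot(inherits(truth, "data.frame"))
  set.seed(seed)
  rows <- list(); labs <- list()
  trace <- 0L; t0 <- 0
  for (p in seq_len(nrow(truth))) {
    po <- truth[p, ]
    for (ring in c(1, -1)) {
      zc <- po$z0 + ring * po$ring_spacing / 2
      for (corner in 0:7) {
        if (!deterministic && stats::runif(1) > occupancy) next
        ang <- (po$phase_deg + corner * 45) * pi / 180
        cx <- po$x0 + po$ring_radius * cos(ang)
        cy <- po$y0 + po$ring_radius * sin(ang)
        nb <- if (deterministic) mean_bursts_per_corner
          else stats::rpois(1, mean_bursts_per_corner)
        for (b in seq_len(nb)) {
          nl <- if (deterministic) mean_locs_per_burst
            else 1L + stats::rpois(1, max(mean_locs_per_burst - 1, 0))
          trace <- trace + 1L
          tt <- t0 + (seq_len(nl) - 1L) * base_cycle_ms / 1000
          t0 <- tt[nl] + 0.05
          efo <- stats::runif(nl, 27, 58)
          cfr <- stats::runif(nl, 0.25, 0.7)
          rows[[length(rows) + 1L]] <- data.frame(
            trace_id = trace, t = tt,
            x = cx + stats::rnorm(nl, 0, sigma_spec$sigma["x"]),
            y = cy + stats::rnorm(nl, 0, sigma_spec$sigma["y"]),
            z = zc + stats::rnorm(nl, 0, sigma_spec$sigma["z"]),
            efo = efo, efc = cfr * efo, cfr = cfr,
            dcr = stats::runif(nl, 0.85, 1), channel = "scaffold")
          labs[[length(labs) + 1L]] <- data.frame(
            pore_id = rep(po$pore_id, nl), corner = corner,
            ring = if (ring > 0) "cytoplasmic" else "nucleoplasmic")
        }
      }
    }
  }
  records <- do.call(rbind, rows); rownames(records) <- NULL
  labels <- do.call(rbind, labs); rownames(labels) <- NULL
  list(records = records, labels = labels)
}

#' Define a ground-truth cohort of cargo tracks
#'
#' Assigns each track a transport class and (except background) a pore.
#'
#' @param scaffold a [make_scaffold_truth()] data frame.
#' @param n_import,n_export,n_abortive_import,n_abortive_export,n_background
#'   class counts.
#' @param seed integer seed.
#' @return data frame of class `track_truth`: `track_id`, `class`,
#'   `pore_id` (NA for background).
#' @export
make_track_cohort <- function(scaffold, n_import = 10, n_export = 10,
                              n_abortive_import = 5, n_abortive_export = 5,
                              n_background = 10, seed = 1L) {
  set.seed(seed)
  cls <- c(rep("import", n_import), rep("export", n_export),
           rep("abortive_import", n_abortive_import),
           rep("abortive_export", n_abortive_export),
           rep("background", n_background))
  n <- length(cls)
  truth <- data.frame(
    track_id = seq_len(n), class = cls,
    pore_id = ifelse(cls == "background", NA_integer_,
                     sample(scaffold$pore_id, n, replace = TRUE)))
  class(truth) <- c("track_truth", "data.frame")
  truth
}

# deterministic z waypoint path for one track class (pore frame, cytoplasm +z)
.track_z_path <- function(class, n_in, z_min_abort) {
  switch(class,
    import = c(seq(90, 30, length.out = 4),
               seq(25, -25, length.out = n_in),
               seq(-30, -90, length.out = 4)),
    export = -c(seq(90, 30, length.out = 4),
                seq(25, -25, length.out = n_in),
                seq(-30, -90, length.out = 4)),
    abortive_import = c(seq(90, 30, length.out = 4),
                        seq(25, z_min_abort, length.out = ceiling(n_in / 2)),
                        seq(z_min_abort + 2, 25, length.out = floor(n_in / 2) + 1),
                        seq(30, 90, length.out = 4)),
    abortive_export = -c(seq(90, 30, length.out = 4),
                         seq(25, z_min_abort, length.out = ceiling(n_in / 2)),
                         seq(z_min_abort + 2, 25, length.out = floor(n_in / 2) + 1),
                         seq(30, 90, length.out = 4)))
}

#' Simulate a cargo-channel tracking dataset
#'
#' Import and export tracks cross the pore midplane along an annulus of
#' configurable radius, angularly confined to one 45-degree lobe (azimuth
#' scatter `angular_sigma_deg` about a per-track reference); abortive tracks
#' approach but never cross z = 0; background tracks wander outside every
#' 400-nm pore cube. Localization noise is added per point from
#' `sigma_spec`. Photometric columns are drawn so true cargo passes the
#' track filters; a configurable fraction of decoy tracks carries
#' out-of-window DCR, and a fraction of genuine tracks is given doubled EFO
#' (two-dye labelling). All geometry is generated in the pore frame with the
#' cytoplasm at +z, then rotated by the pore's phase and translated to the
#' lab frame.
#'
#' @param truth a [make_track_cohort()] data frame.
#' @param scaffold the matching [make_scaffold_truth()] data frame.
#' @param sigma_spec [species_spec()] for the cargo localization noise
#'   (default sigma_x = 8.2 nm, typical tracking precision); use
#'   `species_spec(sigma_x = 0)` for noiseless construction tests.
#' @param annulus_radius_nm radius of the transport annulus (default 23).
#' @param angular_sigma_deg sd of in-pore azimuth about the track reference
#'   (default 19).
#' @param n_in_pore mean number of in-pore (|z| <= 25 nm) points per
#'   transiting track.
#' @param timesteps [timestep_model()] for cargo (default geometric retry,
#'   0.55 ms base cycle with retry probability 0.75, mean interval
#'   ~2.2 ms — consistent with a ~14 ms median residence over ~7 in-pore
#'   points).
#' @param decoy_frac fraction of additional decoy tracks (relative to cohort
#'   size) with out-of-window DCR near pores.
#' @param double_dye_frac fraction of genuine tracks with two dyes
#'   (EFO roughly doubled).
#' @param seed integer seed.
#' @return list with `records` (localization data frame, channel `"cargo"`;
#'   `trace_id` equals the cohort `track_id`, decoys get ids beyond it) and
#'   `truth` (the cohort with decoy rows appended, class `"background"`,
#'   `decoy` flag).
#' @export
simulate_cargo_dataset <- function(truth, scaffold,
                                   sigma_spec = species_spec(sigma_x = 8.2),
                                   annulus_radius_nm = 23,
                                   angular_sigma_deg = 19,
                                   n_in_pore = 7,
                                   timesteps = timestep_model("geometric_retry",
                                                              base_ms = 0.55,
                                                              retry_p = 0.75),
                                   decoy_frac = 0.2,
                                   double_dye_frac = 0.12,
                                   seed = 1L) {
  set.seed(seed)
  rows <- list(); t0 <- 0
  sc <- scaffold[match(truth$pore_id, scaffold$pore_id), ]
  dbl <- stats::runif(nrow(truth)) < double_dye_frac & truth$class != "background"
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    if (cls == "background") {
      # random walk kept > 400 nm (in xy) from every pore centre
      n <- 8L + stats::rpois(1, 6)
      repeat {
        ox <- stats::runif(1, min(scaffold$x0) - 2000, max(scaffold$x0) + 2000)
        oy <- stats::runif(1, min(scaffold$y0) - 2000, max(scaffold$y0) + 2000)
        if (min(sqrt((scaffold$x0 - ox)^2 + (scaffold$y0 - oy)^2)) > 700) break
      }
      xyz <- cbind(ox + cumsum(stats::rnorm(n, 0, 15)),
                   oy + cumsum(stats::rnorm(n, 0, 15)),
                   stats::rnorm(n, 120, 30))
    } else {
      n_in <- max(2L, stats::rpois(1, n_in_pore))
      zp <- .track_z_path(cls, n_in, stats::runif(1, 4, 18))
      n <- length(zp)
      ref <- stats::runif(1, 0, 360)
      theta <- (ref + stats::rnorm(n, 0, angular_sigma_deg)) * pi / 180
      rr <- pmax(5, stats::rnorm(n, annulus_radius_nm, 3))
      # outside the pore the cargo fans out laterally
      outside <- abs(zp) > 25
      rr[outside] <- rr[outside] + (abs(zp[outside]) - 25) * 0.6
      xp <- rr * cos(theta); yp <- rr * sin(theta)
      ph <- sc$phase_deg[i] * pi / 180
      xyz <- cbind(sc$x0[i] + xp * cos(ph) - yp * sin(ph),
                   sc$y0[i] + xp * sin(ph) + yp * cos(ph),
                   sc$z0[i] + zp)
    }
    xyz <- xyz + cbind(stats::rnorm(n, 0, sigma_spec$sigma["x"]),
                       stats::rnorm(n, 0, sigma_spec$sigma["y"]),
                       stats::rnorm(n, 0, sigma_spec$sigma["z"]))
    dt <- sample_timesteps(timesteps, n - 1L) / 1000
    tt <- t0 + c(0, cumsum(dt)); t0 <- tt[n] + 0.1
    efo_med <- 32
    efo <- stats::rlnorm(n, log(if (dbl[i]) 2.1 * efo_med else efo_med), 0.12)
    cfr <- stats::runif(n, 0.2, 0.7)
    rows[[length(rows) + 1L]] <- data.frame(
      trace_id = truth$track_id[i], t = tt,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      efo = efo, efc = cfr * efo, cfr = cfr,
      dcr = stats::runif(n, 0.35, 0.75), channel = "cargo")
  }
  # decoys: near-pore tracks whose DCR falls outside the cargo window
  n_decoy <- round(decoy_frac * nrow(truth))
  decoy_truth <- NULL
  if (n_decoy > 0) {
    decoy_ids <- max(truth$track_id) + seq_len(n_decoy)
    for (j in seq_len(n_decoy)) {
      po <- scaffold[sample.int(nrow(scaffold), 1), ]
      n <- 6L + stats::rpois(1, 4)
      xyz <- cbind(po$x0 + cumsum(stats::rnorm(n, 0, 20)),
                   po$y0 + cumsum(stats::rnorm(n, 0, 20)),
                   po$z0 + stats::rnorm(n, 60, 40))
      dt <- sample_timesteps(timesteps, n - 1L) / 1000
      tt <- t0 + c(0, cumsum(dt)); t0 <- tt[n] + 0.1
      efo <- stats::rlnorm(n, log(20), 0.2)
      cfr <- stats::runif(n, 0.2, 0.7)
      rows[[length(rows) + 1L]] <- data.frame(
        trace_id = decoy_ids[j], t = tt,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        efo = efo, efc = cfr * efo, cfr = cfr,
        dcr = stats::runif(n, 0, 0.22), channel = "cargo")
    }
    decoy_truth <- data.frame(track_id = decoy_ids, class = "background",
                              pore_id = NA_integer_)
  }
  records <- do.call(rbind, rows); rownames(records) <- NULL
  truth_out <- rbind(cbind(truth, decoy = FALSE),
                     if (!is.null(decoy_truth)) cbind(decoy_truth, decoy = TRUE))
  truth_out$double_dye <- c(dbl, rep(FALSE, n_decoy))
  rownames(truth_out) <- NULL
  list(records = records, truth = truth_out)
}

#' Simulate paired gold-bead fiducials for two channels
#'
#' Beads are placed uniformly over a square field; the cargo channel sees
#' them through a rigid xy rotation + translation, a z scale and a per-cell
#' z offset, each coordinate carrying Gaussian measurement noise in both
#' channels.
#'
#' @param n_beads number of beads.
#' @param field_um side of the square field, micrometres.
#' @param angle_deg true rotation from cargo to scaffold frame.
#' @param shift_nm length-2 true translation, nm.
#' @param z_scale true axial scale factor of the raw cargo channel.
#' @param z_offset_nm true per-cell z offset, nm.
#' @param noise_nm per-axis measurement noise sd in each channel, nm.
#' @param n_repeats repeated measurements per bead per channel.
#' @param seed integer seed.
#' @return data frame with columns `bead_id`, `channel`
#'   (`"scaffold"`/`"cargo"`), `t`, `x`, `y`, `z`.
#' @export
simulate_fiducials <- function(n_beads = 9, field_um = 20, angle_deg = 5,
                               shift_nm = c(120, -60), z_scale = 0.67,
                               z_offset_nm = 8, noise_nm = 1,
                               n_repeats = 1, seed = 1L) {
  set.seed(seed)
  fx <- stats::runif(n_beads, 0, field_um * 1000)
  fy <- stats::runif(n_beads, 0, field_um * 1000)
  fz <- stats::rnorm(n_beads, 0, 40)
  a <- angle_deg * pi / 180
  # cargo-frame positions such that rotating by angle + shifting recovers scaffold
  cx <- cos(a) * (fx - shift_nm[1]) + sin(a) * (fy - shift_nm[2])
  cy <- -sin(a) * (fx - shift_nm[1]) + cos(a) * (fy - shift_nm[2])
  cz <- (fz + z_offset_nm) / z_scale
  one <- function(id, ch, x, y, z, rep_i)
    data.frame(bead_id = id, channel = ch, t = rep_i * 5,
               x = x + stats::rnorm(length(x), 0, noise_nm),
               y = y + stats::rnorm(length(x), 0, noise_nm),
               z = z + stats::rnorm(length(x), 0, noise_nm))
  out <- do.call(rbind, c(
    lapply(seq_len(n_repeats), function(r)
      one(seq_len(n_beads), "scaffold", fx, fy, fz, r)),
    lapply(seq_len(n_repeats), function(r)
      one(seq_len(n_beads), "cargo", cx, cy, cz, r))))
  rownames(out) <- NULL
  attr(out, "truth") <- list(angle_deg = angle_deg, shift_nm = shift_nm,
                             z_scale = z_scale, z_offset_nm = z_offset_nm)
  out
}
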