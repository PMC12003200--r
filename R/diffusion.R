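# Jump-step and R^2/t analysis: closed-form displacement distributions for
# pure diffusion, histogram construction with variable timesteps, and
# simulation-based 1-3 species mixture fits matched jointly to both
# histograms.

.UM2S_TO_NM2MS <- 1000  # 1 um^2/s = 1000 nm^2/ms

#' Histogram specification
#'
#' @param b bin size (nm for jump histograms, nm^2/ms for R^2/t).
#' @param lo,hi histogram range; bins are contiguous `[lo, hi)`.
#' @param d spatial dimension (1, 2 or 3).
#' @return list of class `histogram_spec`.
#' @export
histogram_spec <- function(b, lo = 0, hi, d = 3) {
  stopifnot(b > 0, hi > lo, d %in% 1:3)
  breaks <- seq(lo, hi, by = b)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, breaks[length(breaks)] + b)
  structure(list(b = b, lo = lo, hi = breaks[length(breaks)], d = as.integer(d),
                 breaks = breaks, mid = breaks[-length(breaks)] + b / 2),
            class = "histogram_spec")
}

.binned <- function(spec, p, kind) {
  structure(list(spec = spec, mid = spec$mid, p = p, kind = kind),
            class = "binned_pdf")
}

#' Binned jump-distance distribution for pure diffusion
#'
#' Evaluates the closed-form displacement densities for isotropic diffusion
#' at the bin centres times the bin width: in 1D a folded Gaussian
#' `2b/sqrt(4 pi D t) exp(-x^2/4Dt)`, in 2D `b r/(2Dt) exp(-r^2/4Dt)`, in
#' 3D `b R^2/(sqrt(4 pi) (Dt)^{3/2}) exp(-R^2/4Dt)`. Probabilities are
#' normalized to sum to one; if the requested range truncates more than
#' 1e-3 of the mass a warning is raised first.
#'
#' @param d dimension (1, 2, 3).
#' @param D diffusion coefficient, um^2/s.
#' @param t timestep, seconds.
#' @param spec a [histogram_spec()] in nm (its `d` is ignored in favour of
#'   `d`).
#' @return `binned_pdf` with probabilities per bin.
#' @export
jump_pdf <- function(d, D, t, spec) {
  stopifnot(D > 0, t > 0, inherits(spec, "histogram_spec"), d %in% 1:3)
  s2 <- 2 * D * 1e6 * t                     # per-axis variance, nm^2
  r <- spec$mid; b <- spec$b
  dens <- switch(d,
    `1` = 2 / sqrt(2 * pi * s2) * exp(-r^2 / (2 * s2)),
    `2` = r / s2 * exp(-r^2 / (2 * s2)),
    `3` = sqrt(2 / pi) * r^2 / s2^1.5 * exp(-r^2 / (2 * s2)))
  p <- dens * b
  mass_out <- 1 - (stats::pchisq(spec$breaks[length(spec$breaks)]^2 / s2, d) -
                     stats::pchisq(spec$lo^2 / s2, d))
  if (mass_out > 1e-3)
    warning(sprintf("histogram range truncates %.2g of the jump mass", mass_out))
  .binned(spec, p / sum(p), "jump")
}

#' Binned time-independent R^2/t distribution for pure diffusion
#'
#' The change of variables `u = R^2/t` removes the timestep from the pure
#' diffusion densities: `b/sqrt(4 pi D u) exp(-u/4D)` (1D),
#' `b/(4D) exp(-u/4D)` (2D, exponential with mean 4D) and
#' `b sqrt(u)/(4 sqrt(pi) D^{3/2}) exp(-u/4D)` (3D). `u` and the bin size
#' are in nm^2/ms.
#'
#' @param d dimension (1, 2, 3).
#' @param D diffusion coefficient, um^2/s.
#' @param spec a [histogram_spec()] in nm^2/ms.
#' @return `binned_pdf` with probabilities per bin.
#' @export
u_pdf <- function(d, D, spec) {
  stopifnot(D > 0, inherits(spec, "histogram_spec"), d %in% 1:3)
  Dn <- D * .UM2S_TO_NM2MS                  # nm^2/ms
  u <- spec$mid; b <- spec$b
  dens <- switch(d,
    `1` = 1 / sqrt(4 * pi * Dn * u) * exp(-u / (4 * Dn)),
    `2` = 1 / (4 * Dn) * exp(-u / (4 * Dn)),
    `3` = sqrt(u) / (4 * sqrt(pi) * Dn^1.5) * exp(-u / (4 * Dn)))
  p <- dens * b
  mass_out <- 1 - (stats::pchisq(spec$breaks[length(spec$breaks)] / (2 * Dn), d) -
                     stats::pchisq(spec$lo / (2 * Dn), d))
  if (mass_out > 1e-3)
    warning(sprintf("histogram range truncates %.2g of the u mass", mass_out))
  .binned(spec, p / sum(p), "u")
}

#' Weighted mixture of binned distributions
#'
#' @param components list of `binned_pdf` objects on identical bins.
#' @param weights numeric weights in \[0, 1\] summing to 1.
#' @return `binned_pdf` convex combination.
#' @export
mixture_pdf <- function(components, weights) {
  stopifnot(length(components) == length(weights))
  if (any(weights < 0 | weights > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  mids <- lapply(components, `[[`, "mid")
  if (!all(vapply(mids, function(m) isTRUE(all.equal(m, mids[[1]])), logical(1))))
    stop("components must share identical bins", call. = FALSE)
  p <- Reduce(`+`, Map(function(cp, w) w * cp$p, components, weights))
  .binned(components[[1]]$spec, p, components[[1]]$kind)
}

#' Build a jump sample from successive localizations
#'
#' Computes, within each trajectory, the 3D distances between successive
#' localizations, the corresponding intervals and the time-normalized
#' statistic `u = R^2/t` (t in ms, so u is in nm^2/ms).
#'
#' @param points data frame with a trajectory id column plus `t` (seconds)
#'   and `x`, `y`, `z` (nm).
#' @param id_col name of the trajectory id column (default `"traj_id"`,
#'   falling back to `"trace_id"` if absent).
#' @return data frame of class `jump_sample`: `R` (nm), `dt` (s), `u`
#'   (nm^2/ms).
#' @export
as_jump_sample <- function(points, id_col = NULL) {
  if (is.null(id_col))
    id_col <- if ("traj_id" %in% names(points)) "traj_id" else "trace_id"
  stopifnot(id_col %in% names(points))
  n <- nrow(points)
  if (n < 2) {
    out <- data.frame(R = numeric(0), dt = numeric(0))
  } else {
    ord <- order(points[[id_col]], points$t)
    id <- points[[id_col]][ord]
    x <- points$x[ord]; y <- points$y[ord]
    z <- points$z[ord]; tt <- points$t[ord]
    same <- id[-1] == id[-n]
    out <- data.frame(
      R = sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)[same],
      dt = diff(tt)[same])
  }
  out$u <- ifelse(out$dt > 0, out$R^2 / (out$dt * 1000), NA_real_)
  class(out) <- c("jump_sample", "data.frame")
  out
}

#' Default histogram specifications for a jump sample
#'
#' Ranges cover the 99.8th percentile of the data with headroom; ~60 bins.
#'
#' @param sample a [as_jump_sample()] data frame.
#' @return list `jump`, `u` of [histogram_spec()].
#' @export
default_histogram_specs <- function(sample) {
  rmax <- max(stats::quantile(sample$R, 0.998) * 1.3, 20)
  umax <- max(stats::quantile(sample$u, 0.998) * 1.3, 50)
  list(jump = histogram_spec(b = rmax / 60, hi = rmax, d = 3),
       u = histogram_spec(b = umax / 60, hi = umax, d = 3))
}

.hist_freq <- function(values, spec) {
  cut_idx <- findInterval(values, spec$breaks, rightmost.closed = FALSE)
  nb <- length(spec$mid)
  counts <- tabulate(cut_idx[cut_idx >= 1 & cut_idx <= nb], nbins = nb)
  list(counts = counts, freq = if (sum(counts)) counts / sum(counts)
       else rep(0, nb))
}

#' Build jump and R^2/t histograms from a sample
#'
#' @param sample a [as_jump_sample()] data frame (positive `dt` required).
#' @param specs list with `jump` and `u` [histogram_spec()]s; default
#'   [default_histogram_specs()].
#' @return list of class `jump_histograms`: `jump`, `u` (each with
#'   `counts`, `freq`, `spec`), `n`, `specs`.
#' @export
build_histograms <- function(sample, specs = default_histogram_specs(sample)) {
  if (!nrow(sample)) stop("empty jump sample", call. = FALSE)
  if (any(sample$dt <= 0)) stop("non-positive dt in jump sample", call. = FALSE)
  hj <- .hist_freq(sample$R, specs$jump)
  hu <- .hist_freq(sample$u, specs$u)
  structure(list(jump = c(hj, list(spec = specs$jump)),
                 u = c(hu, list(spec = specs$u)),
                 n = nrow(sample), specs = specs),
            class = "jump_histograms")
}

# --- simulation-based mixture fitting --------------------------------------

# Streamlined forward simulator for independent jumps (trajectories of
# length 2): the same error model as simulate_jump_trajectories — per-axis
# diffusion variance 2Dt plus independent anisotropic precision noise at
# both endpoints — without the trajectory/clock bookkeeping. Statistical
# equivalence with the full simulator is asserted by the test suite.
.sim_jump_kernel <- function(D, sigma_x, tsmodel, seed, n_steps) {
  set.seed(seed)
  dt_ms <- sample_timesteps(tsmodel, n_steps)
  dt_s <- dt_ms / 1000
  sig <- c(sigma_x, sigma_x / 0.93, sigma_x / 1.55)
  d2 <- matrix(0, n_steps, 3)
  if (any(D > 0))
    d2 <- matrix(stats::rnorm(3 * n_steps), n_steps, 3) *
      .axis_step_sd(D, dt_s)
  if (any(sig > 0)) {
    e1 <- matrix(stats::rnorm(3 * n_steps), n_steps, 3)
    e2 <- matrix(stats::rnorm(3 * n_steps), n_steps, 3)
    d2 <- d2 + sweep(e2 - e1, 2, sig, `*`)
  }
  R <- sqrt(rowSums(d2^2))
  list(R = R, u = R^2 / dt_ms)
}

# per-species jump/u model histogram frequencies by seeded forward
# simulation (common random numbers: identical seed per species across
# objective evaluations)
.model_species_hist <- function(D, sigma_x, tsmodel, specs, seed, n_steps) {
  s <- .sim_jump_kernel(D, sigma_x, tsmodel, seed, n_steps)
  c(.hist_freq(s$R, specs$jump)$freq, .hist_freq(s$u, specs$u)$freq)
}

# equality-constrained nonnegative least squares: min ||Hw-y||, sum w = 1,
# w >= 0; tiny active-set suitable for <= 3 columns
.solve_weights <- function(H, y) {
  k <- ncol(H)
  solve_eq <- function(cols) {
    m <- length(cols)
    G <- crossprod(H[, cols, drop = FALSE]) + diag(1e-10, m)
    KKT <- rbind(cbind(2 * G, rep(1, m)), c(rep(1, m), 0))
    rhs <- c(2 * crossprod(H[, cols, drop = FALSE], y), 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) rep(NA_real_, m + 1))
    sol[seq_len(m)]
  }
  active <- seq_len(k)
  repeat {
    w_act <- solve_eq(active)
    if (anyNA(w_act)) { w_act <- rep(1 / length(active), length(active)) }
    if (all(w_act >= -1e-12) || length(active) == 1L) break
    active <- active[-which.min(w_act)]
  }
  w <- numeric(k)
  w[active] <- pmax(w_act, 0)
  w / sum(w)
}

#' Fit a multi-species diffusion/precision mixture jointly to jump and
#' R^2/t histograms
#'
#' Model curves are generated by seeded forward simulation through
#' [simulate_jump_trajectories()] with the same localization-error model
#' used throughout (anisotropic precision with fixed axis ratios 0.93 and
#' 1.55, timesteps resampled from the data by default), so the fit
#' accounts for variable timesteps exactly as the measurement produced
#' them. The objective is the equal-weight sum of squared differences of
#' normalized frequencies over both histograms; mixture weights are solved
#' exactly (constrained least squares) at every evaluation, and the
#' nonlinear parameters (per-species `sigma_x`, mobile-species D) are
#' optimized by a coarse grid followed by Nelder-Mead refinement from the
#' best starts. Fixed simulation seeds make the objective deterministic.
#' By default only the last species diffuses (`D` of the others pinned at
#' 0, mirroring a bound/confined/mobile decomposition); set `free_D` for
#' per-species diffusion coefficients.
#'
#' @param sample a [as_jump_sample()] data frame.
#' @param n_species 1, 2 or 3.
#' @param timesteps optional [timestep_model()] for the model curves;
#'   default resamples the sample's own `dt` values (empirical).
#' @param seed integer seed for the forward-model simulations.
#' @param specs histogram specs (default from the data).
#' @param free_D allow every species its own diffusion coefficient.
#' @param n_model_steps simulated steps per species per model evaluation.
#' @param sigma_grid,D_grid coarse-grid candidate values (nm, um^2/s).
#' @param n_starts Nelder-Mead refinements from the best grid points.
#' @return object of class `species_fit`: `species` data frame (`weight`,
#'   `D`, `sigma_x`, `sigma_y`, `sigma_z`), `goodness` (per-histogram SSE
#'   and total), `curves` (model frequencies on the data bins),
#'   `histograms` (the data), `boundary_flags`, `seed`.
#' @export
fit_species_model <- function(sample, n_species = 1, timesteps = NULL,
                              seed = 1L, specs = default_histogram_specs(sample),
                              free_D = FALSE, n_model_steps = 10000L,
                              sigma_grid = c(2.5, 4.5, 8, 13),
                              D_grid = c(0.01, 0.03, 0.08, 0.2),
                              n_starts = 2L) {
  stopifnot(n_species %in% 1:3)
  hists <- build_histograms(sample, specs)
  y <- c(hists$jump$freq, hists$u$freq)
  if (is.null(timesteps)) {
    # collapse to unique durations (retry-cycle data has few); continuous
    # dt values are grouped at 10-us resolution
    dt_tab <- table(round(sample$dt * 1000, 2))
    timesteps <- timestep_model("empirical",
                                table = data.frame(
                                  duration_ms = as.numeric(names(dt_tab)),
                                  freq = as.numeric(dt_tab) / sum(dt_tab)))
  }
  k <- n_species
  n_D <- if (free_D) k else 1L      # mobile D count (last species if not free)
  # theta = c(log sigma_x[1..k], log D[mobile...]); immobile species have
  # D pinned at exactly 0 (no diffusion draws)
  unpack <- function(theta) {
    sig <- exp(theta[seq_len(k)])
    Ds <- rep(0, k)
    Ds[if (free_D) seq_len(k) else k] <- exp(theta[k + seq_len(n_D)])
    list(sigma = sig, D = Ds)
  }
  cache <- new.env(parent = emptyenv())
  eval_model <- function(theta, n_steps = n_model_steps, use_cache = FALSE) {
    pp <- unpack(theta)
    H <- vapply(seq_len(k), function(j) {
      if (use_cache) {
        key <- paste0(j, "_", signif(pp$D[j], 8), "_", signif(pp$sigma[j], 8))
        h <- cache[[key]]
        if (is.null(h)) {
          h <- .model_species_hist(pp$D[j], pp$sigma[j], timesteps, specs,
                                   seed = seed + j, n_steps = n_steps)
          cache[[key]] <- h
        }
        h
      } else .model_species_hist(pp$D[j], pp$sigma[j], timesteps, specs,
                                 seed = seed + j, n_steps = n_steps)
    }, numeric(length(y)))
    H <- matrix(H, ncol = k)
    w <- .solve_weights(H, y)
    list(sse = sum((H %*% w - y)^2), w = w, H = H, par = pp)
  }
  objective <- function(theta) eval_model(theta)$sse

  # coarse grid (species histograms cached: immobile species revisit the
  # same sigma values); non-decreasing sigma kills label switching
  sig_combos <- if (k == 1) matrix(sigma_grid, ncol = 1) else {
    g <- as.matrix(expand.grid(rep(list(sigma_grid), k)))
    g[apply(g, 1, function(r) all(diff(r) >= 0)), , drop = FALSE]
  }
  D_combos <- as.matrix(expand.grid(rep(list(D_grid), n_D)))
  grid <- do.call(rbind, lapply(seq_len(nrow(sig_combos)), function(i)
    cbind(matrix(rep(sig_combos[i, ], nrow(D_combos)), ncol = k, byrow = TRUE),
          D_combos)))
  thetas <- log(grid)
  sses <- apply(thetas, 1, function(th) eval_model(th, use_cache = TRUE)$sse)
  ord <- order(sses)
  best <- NULL
  for (s in seq_len(min(n_starts, length(ord)))) {
    op <- stats::optim(thetas[ord[s], ], objective, method = "Nelder-Mead",
                       control = list(maxit = 120, reltol = 1e-7))
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("mixture fit failed to converge from any start",
                          call. = FALSE)
  # polish at a larger simulation size to shrink Monte-Carlo bias
  polish_steps <- 4L * n_model_steps
  op2 <- stats::optim(best$par,
                      function(th) eval_model(th, n_steps = polish_steps)$sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 60, reltol = 1e-7))
  best <- op2
  fin <- eval_model(best$par, n_steps = polish_steps)
  pp <- fin$par
  sig <- pp$sigma
  nb_j <- length(hists$jump$freq)
  resid <- as.vector(fin$H %*% fin$w - y)
  sse_jump <- sum(resid[seq_len(nb_j)]^2)
  sse_u <- sum(resid[-seq_len(nb_j)]^2)
  bflag <- c(sigma_low = any(sig <= min(sigma_grid) * 0.2),
             sigma_high = any(sig >= max(sigma_grid) * 5),
             D_low = any(pp$D[pp$D > 0] <= min(D_grid) * 0.05),
             D_high = any(pp$D >= max(D_grid) * 20),
             weight_zero = any(fin$w < 1e-6))
  species <- data.frame(weight = fin$w, D = pp$D,
                        sigma_x = sig, sigma_y = sig / 0.93,
                        sigma_z = sig / 1.55)
  structure(list(species = species,
                 goodness = c(sse_jump = sse_jump, sse_u = sse_u,
                              sse_total = fin$sse),
                 curves = list(
                   jump = as.vector(fin$H[seq_len(nb_j), , drop = FALSE] %*% fin$w),
                   u = as.vector(fin$H[-seq_len(nb_j), , drop = FALSE] %*% fin$w)),
                 histograms = hists, boundary_flags = bflag,
                 convergence = best$convergence, seed = seed,
                 n_species = k, free_D = free_D),
            class = "species_fit")
}

#' @export
print.species_fit <- function(x, ...) {
  cat(sprintf("%d-species jump/R^2:t mixture fit (n = %d jumps)\n",
              x$n_species, x$histograms$n))
  sp <- x$species
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  species %d: weight %.3f, D = %.4f um^2/s, sigma_x = %.2f nm\n",
                i, sp$weight[i], sp$D[i], sp$sigma_x[i]))
  cat(sprintf("  goodness: SSE jump %.3e, SSE u %.3e\n",
              x$goodness["sse_jump"], x$goodness["sse_u"]))
  if (any(x$boundary_flags))
    cat("  flags:", paste(names(x$boundary_flags)[x$boundary_flags],
                          collapse = ", "), "\n")
  invisible(x)
}
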