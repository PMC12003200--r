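# NPC scaffold reconstruction: pore clustering, double-circle fits,
# eightfold symmetry phase, alignment/averaging, centroid-deviation
# precision and early/late stability diagnostics.

#' Cluster scaffold localizations into candidate pores
#'
#' Groups localizations by single-linkage agglomeration in 3D cut at a
#' distance threshold, keeping clusters of at least `min_points`. Pores in
#' a field are hundreds of nm apart while a pore's own localizations span
#' ~130 nm, so a linkage cut-off between those scales separates them;
#' stray background points fall into sub-threshold groups and are left
#' unassigned.
#'
#' @param records scaffold-channel localization data frame (registered).
#' @param eps linkage distance cut-off, nm (default 80).
#' @param min_points minimum cluster size (default 30).
#' @return list of data frames (the clusters), each with attribute
#'   `member_rows` (row indices into `records`); empty list if nothing
#'   qualifies.
#' @export
cluster_localizations <- function(records, eps = 80, min_points = 30) {
  n <- nrow(records)
  if (!n) return(list())
  xyz <- as.matrix(records[, c("x", "y", "z")])
  if (n == 1) memb <- 1L else {
    hc <- stats::hclust(stats::dist(xyz), method = "single")
    memb <- stats::cutree(hc, h = eps)
  }
  keep <- names(which(table(memb) >= min_points))
  out <- lapply(keep, function(g) {
    rows <- which(memb == as.integer(g))
    cl <- records[rows, , drop = FALSE]
    rownames(cl) <- NULL
    attr(cl, "member_rows") <- rows
    cl
  })
  # stable ordering: by cluster centroid x then y
  if (length(out) > 1) {
    cx <- vapply(out, function(cl) mean(cl$x), numeric(1))
    cy <- vapply(out, function(cl) mean(cl$y), numeric(1))
    out <- out[order(cx, cy)]
  }
  out
}

#' Fit the double-circle model to one pore cluster
#'
#' The two NUP96 rings are modelled as congruent circles parallel to the
#' xy plane, centres on a common z axis: parameters are the pore centre
#' `(x0, y0, z0)`, the shared `ring_radius` and the `ring_spacing`. The
#' fit minimizes the squared residuals of (cylindrical radius -
#' ring_radius) and (|z - z0| - ring_spacing/2); localizations are
#' assigned to the upper/lower ring by the sign of `z - z0` (ties to the
#' nearer ring) and the fit is iterated with 3-sigma outlier trimming and
#' ring re-assignment until stable.
#'
#' @param cluster localization data frame for one pore.
#' @param min_points minimum cluster size (default 30).
#' @param max_iter trimming iterations.
#' @return list of class `npc_scaffold`: `centre`, `ring_radius`,
#'   `ring_spacing`, `phase_deg` (NA until [fit_symmetry_phase()]),
#'   `n_localizations`, `rms_residual`, `member_rows`, `degenerate`.
#' @export
fit_double_circle <- function(cluster, min_points = 30, max_iter = 10) {
  if (nrow(cluster) < min_points)
    stop("cluster has fewer than min_points = ", min_points, " localizations",
         call. = FALSE)
  x <- cluster$x; y <- cluster$y; z <- cluster$z
  keep <- rep(TRUE, length(x))
  fit1 <- NULL
  for (iter in seq_len(max_iter)) {
    xi <- x[keep]; yi <- y[keep]; zi <- z[keep]
    # split rings about the count-weighted mean, then iterate to the
    # balanced midpoint (a plain median sits inside the fuller ring)
    z0 <- mean(zi)
    up <- zi > z0
    for (zi_it in 1:5) {
      if (all(up) || !any(up)) break
      z0_new <- (mean(zi[up]) + mean(zi[!up])) / 2
      up_new <- zi > z0_new
      if (identical(up_new, up)) { z0 <- z0_new; break }
      up <- up_new; z0 <- z0_new
    }
    if (all(up) || !any(up)) {
      # single plane: spacing unidentifiable
      return(structure(list(centre = c(x0 = mean(xi), y0 = mean(yi), z0 = z0),
                            ring_radius = NA_real_, ring_spacing = NA_real_,
                            phase_deg = NA_real_, n_localizations = sum(keep),
                            rms_residual = NA_real_,
                            member_rows = attr(cluster, "member_rows"),
                            degenerate = TRUE),
                       class = "npc_scaffold"))
    }
    mu_u <- mean(zi[up]); mu_l <- mean(zi[!up])
    z0 <- (mu_u + mu_l) / 2
    spacing <- mu_u - mu_l
    # xy circle centre: Kasa algebraic fit, then Gauss-Newton refinement
    A <- cbind(2 * xi, 2 * yi, 1)
    bb <- xi^2 + yi^2
    ab <- tryCatch(qr.solve(A, bb), error = function(e) c(mean(xi), mean(yi), 0))
    cx <- ab[1]; cy <- ab[2]
    for (gn in 1:15) {
      ri <- sqrt((xi - cx)^2 + (yi - cy)^2)
      ri[ri == 0] <- 1e-9
      rad <- mean(ri)
      J <- cbind(-(xi - cx) / ri + mean((xi - cx) / ri),
                 -(yi - cy) / ri + mean((yi - cy) / ri))
      res <- ri - rad
      step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0))
      cx <- cx + step[1]; cy <- cy + step[2]
      if (sqrt(sum(step^2)) < 1e-9) break
    }
    ri <- sqrt((xi - cx)^2 + (yi - cy)^2)
    rad <- mean(ri)
    res_r <- ri - rad
    res_z <- abs(zi - z0) - spacing / 2
    resid <- sqrt(res_r^2 + res_z^2)
    rms <- sqrt(mean(resid^2))
    fit1 <- list(cx = cx, cy = cy, z0 = z0, rad = rad, spacing = spacing,
                 rms = rms)
    # trim 3-sigma outliers (against all original points) and iterate
    ra <- sqrt((x - cx)^2 + (y - cy)^2)
    res_all <- sqrt((ra - rad)^2 + (abs(z - z0) - spacing / 2)^2)
    sdr <- stats::sd(resid)
    new_keep <- if (is.finite(sdr) && sdr > 0) res_all <= 3 * sdr + rms
      else rep(TRUE, length(x))
    if (sum(new_keep) < min_points) break
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  structure(list(centre = c(x0 = fit1$cx, y0 = fit1$cy, z0 = fit1$z0),
                 ring_radius = fit1$rad, ring_spacing = fit1$spacing,
                 phase_deg = NA_real_, n_localizations = sum(keep),
                 rms_residual = fit1$rms,
                 member_rows = attr(cluster, "member_rows"),
                 degenerate = FALSE),
            class = "npc_scaffold")
}

#' @export
print.npc_scaffold <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("NPC scaffold fit: DEGENERATE (single ring plane; spacing unidentifiable)\n")
    return(invisible(x))
  }
  cat(sprintf("NPC scaffold fit: centre (%.1f, %.1f, %.1f) nm\n",
              x$centre[1], x$centre[2], x$centre[3]))
  cat(sprintf("  ring radius %.2f nm, ring spacing %.2f nm, phase %s\n",
              x$ring_radius, x$ring_spacing,
              if (is.na(x$phase_deg)) "unset" else
                sprintf("%.2f deg", x$phase_deg)))
  cat(sprintf("  n = %d, rms residual %.2f nm\n", x$n_localizations,
              x$rms_residual))
  invisible(x)
}

#' Fit the eightfold symmetry phase of one pore
#'
#' Azimuths of the cluster's localizations about the fitted centre are
#' reduced modulo 45 degrees (eightfold periodicity), binned, and fitted
#' with `offset + amplitude * cos(8 * (theta - phase))` by least squares
#' with a dense phase search over \[0, 45) followed by refinement, so the
#' 45-degree-periodic likelihood cannot trap the fit in a local minimum.
#'
#' @param cluster the pore's localization data frame.
#' @param fit its [fit_double_circle()] result.
#' @param bin_deg azimuthal bin width, degrees (default 3).
#' @return list of class `symmetry_fit`: `phase_deg` in \[0, 45),
#'   `amplitude`, `offset`, `goodness` (reduced chi-square),
#'   `low_confidence` (amplitude < 2 x its standard error).
#' @export
fit_symmetry_phase <- function(cluster, fit, bin_deg = 3) {
  stopifnot(inherits(fit, "npc_scaffold"))
  th <- atan2(cluster$y - fit$centre["y0"], cluster$x - fit$centre["x0"]) *
    180 / pi
  th45 <- th %% 45
  breaks <- seq(0, 45, by = bin_deg)
  bi <- findInterval(th45, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bi, nbins = length(breaks) - 1)
  mids <- breaks[-length(breaks)] + bin_deg / 2
  # linearize: counts ~ offset + a*cos(8 th) + b*sin(8 th); phase from (a, b)
  c8 <- cos(8 * mids * pi / 180); s8 <- sin(8 * mids * pi / 180)
  co <- stats::lm(counts ~ c8 + s8)
  a <- stats::coef(co)["c8"]; b <- stats::coef(co)["s8"]
  amp <- sqrt(a^2 + b^2)
  # the binned LS fixes amplitude/offset/goodness; the phase itself comes
  # from the unbinned eightfold resultant (the bin-width -> 0 limit of the
  # same least squares), which removes the half-bin quantization
  th8 <- th45 * 8 * pi / 180
  phase <- (atan2(mean(sin(th8)), mean(cos(th8))) * 180 / pi / 8) %% 45
  se <- sqrt(sum(summary(co)$coefficients[c("c8", "s8"), "Std. Error"]^2 *
                   c(a, b)^2) / max(amp^2, 1e-12))
  dof <- max(length(mids) - 3, 1)
  expct <- pmax(stats::fitted(co), 1e-9)
  chi2 <- sum((counts - expct)^2 / pmax(expct, 0.5)) / dof
  structure(list(phase_deg = unname(phase), amplitude = unname(amp),
                 offset = unname(stats::coef(co)[1]), goodness = chi2,
                 low_confidence = unname(amp < 2 * se)),
            class = "symmetry_fit")
}

#' Align pores and build an averaged composite
#'
#' Each pore's localizations are translated so the fitted centre sits at
#' the origin and rotated in xy by minus the pore's symmetry phase; the
#' pooled set is returned with composite 2D histograms (xy top view and
#' rz side view, 2-nm bins) scaled to percent of maximum.
#'
#' @param scaffolds list of [fit_double_circle()] results with phases set
#'   (assign `phase_deg` from [fit_symmetry_phase()] first).
#' @param clusters matching list of localization data frames.
#' @param bin_nm histogram bin size, nm (default 2).
#' @param extent_nm half-width of the composite grids, nm.
#' @return list of class `npc_composite`: `points` (pooled pore-frame data
#'   frame with `pore_index`), `xy` and `rz` (list: `x`/`y` bin edges,
#'   `percent` matrix), `z_profile` (data frame `z`, `count`).
#' @export
align_and_average <- function(scaffolds, clusters, bin_nm = 2,
                              extent_nm = 80) {
  stopifnot(length(scaffolds) == length(clusters), length(scaffolds) >= 1)
  pooled <- do.call(rbind, lapply(seq_along(scaffolds), function(i) {
    f <- scaffolds[[i]]; cl <- clusters[[i]]
    ph <- if (is.na(f$phase_deg)) 0 else f$phase_deg
    a <- -ph * pi / 180
    dx <- cl$x - f$centre["x0"]; dy <- cl$y - f$centre["y0"]
    data.frame(pore_index = i,
               x = dx * cos(a) - dy * sin(a),
               y = dx * sin(a) + dy * cos(a),
               z = cl$z - f$centre["z0"])
  }))
  rownames(pooled) <- NULL
  edges <- seq(-extent_nm, extent_nm, by = bin_nm)
  hist2d <- function(u, v) {
    nb <- length(edges) - 1L
    iu <- findInterval(u, edges, rightmost.closed = TRUE)
    iv <- findInterval(v, edges, rightmost.closed = TRUE)
    ok <- iu >= 1 & iu <= nb & iv >= 1 & iv <= nb
    m <- matrix(tabulate((iv[ok] - 1L) * nb + iu[ok], nbins = nb * nb), nb, nb)
    m
  }
  mxy <- hist2d(pooled$x, pooled$y)
  r_signed <- sign(pooled$x) * sqrt(pooled$x^2 + pooled$y^2)
  mrz <- hist2d(r_signed, pooled$z)
  as_pct <- function(m) if (max(m) > 0) 100 * m / max(m) else m * 0
  zedges <- seq(-extent_nm, extent_nm, by = bin_nm)
  zi <- findInterval(pooled$z, zedges, rightmost.closed = TRUE)
  zc <- tabulate(zi[zi >= 1 & zi < length(zedges)], nbins = length(zedges) - 1)
  structure(list(points = pooled,
                 xy = list(x = edges, y = edges, percent = as_pct(mxy)),
                 rz = list(x = edges, y = edges, percent = as_pct(mrz)),
                 z_profile = data.frame(z = zedges[-length(zedges)] + bin_nm / 2,
                                        count = zc)),
            class = "npc_composite")
}

#' Ring spacing of a composite from its z profile
#'
#' Peak-to-peak distance between the mean z of the upper and lower halves
#' of the composite's axial distribution.
#'
#' @param composite an [align_and_average()] result.
#' @return spacing in nm.
#' @export
composite_ring_spacing <- function(composite) {
  z <- composite$points$z
  mean(z[z > 0]) - mean(z[z <= 0])
}

#' Localization precision from within-burst centroid deviations
#'
#' Pools, over every burst/trajectory with at least `min_points`
#' localizations, the per-axis deviations from that burst's centroid and
#' fits a Gaussian per axis. The pooled variance uses `n - 1` degrees of
#' freedom per burst, correcting the sqrt((n-1)/n) shrinkage that
#' deviations-from-the-sample-mean would otherwise impose. Any slow
#' movement of the emitter during a burst inflates this estimate — which
#' is exactly the diagnostic the jump-step comparison exposes.
#'
#' @param bursts list of burst data frames ([split_bursts()]) or a single
#'   data frame with a `trace_id`/`traj_id` column.
#' @param min_points minimum localizations per burst (default 20).
#' @return list of class `precision_estimate`: `sigma` (named x/y/z, nm),
#'   `se`, `n_localizations`, `n_clusters`.
#' @export
estimate_precision_centroid <- function(bursts, min_points = 20) {
  if (is.data.frame(bursts)) {
    id <- if ("traj_id" %in% names(bursts)) bursts$traj_id else bursts$trace_id
    bursts <- split(bursts[, intersect(c("x", "y", "z", "t"), names(bursts))], id)
  }
  bursts <- Filter(function(b) nrow(b) >= min_points, bursts)
  if (!length(bursts))
    stop("no burst has >= ", min_points, " localizations", call. = FALSE)
  ss <- c(x = 0, y = 0, z = 0); dof <- 0; npts <- 0
  for (b in bursts) {
    for (ax in c("x", "y", "z"))
      ss[ax] <- ss[ax] + sum((b[[ax]] - mean(b[[ax]]))^2)
    dof <- dof + nrow(b) - 1L
    npts <- npts + nrow(b)
  }
  sigma <- sqrt(ss / dof)
  structure(list(sigma = sigma, se = sigma / sqrt(2 * dof),
                 n_localizations = npts, n_clusters = length(bursts)),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "Centroid-deviation precision (%d clusters, %d localizations):\n",
    x$n_clusters, x$n_localizations))
  cat(sprintf("  sigma_x = %.2f +/- %.2f nm, sigma_y = %.2f +/- %.2f nm, sigma_z = %.2f +/- %.2f nm\n",
              x$sigma["x"], x$se["x"], x$sigma["y"], x$se["y"],
              x$sigma["z"], x$se["z"]))
  r <- precision_ratios(x)
  cat(sprintf("  sigma_x/sigma_y = %.2f, sigma_x/sigma_z = %.2f\n",
              r["xy"], r["xz"]))
  invisible(x)
}

#' Axis-ratio summary of a precision triplet
#'
#' @param sigma a `precision_estimate` or a named/plain numeric triplet
#'   `(sigma_x, sigma_y, sigma_z)`.
#' @return named vector `xy = sigma_x/sigma_y`, `xz = sigma_x/sigma_z`
#'   (full precision; round to 2 dp for display).
#' @export
precision_ratios <- function(sigma) {
  if (inherits(sigma, "precision_estimate")) sigma <- sigma$sigma
  stopifnot(length(sigma) == 3)
  c(xy = unname(sigma[1] / sigma[2]), xz = unname(sigma[1] / sigma[3]))
}

#' Early/late stability check of pore positions
#'
#' Splits each pore's localizations at the median acquisition time and
#' reports the displacement between the early and late centroids — a
#' positional-stability diagnostic for long acquisitions.
#'
#' @param clusters list of pore localization data frames (must carry `t`).
#' @param min_half minimum localizations required in each half.
#' @return data frame: `pore_index`, `n_early`, `n_late`, `dx`, `dy`,
#'   `dz`, `displacement` (nm); excluded pores carry `NA` displacement.
#' @export
stability_split <- function(clusters, min_half = 10) {
  out <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    tsplit <- stats::median(cl$t)
    early <- cl[cl$t <= tsplit, ]; late <- cl[cl$t > tsplit, ]
    if (nrow(early) < min_half || nrow(late) < min_half)
      return(data.frame(pore_index = i, n_early = nrow(early),
                        n_late = nrow(late), dx = NA_real_, dy = NA_real_,
                        dz = NA_real_, displacement = NA_real_))
    d <- colMeans(late[, c("x", "y", "z")]) - colMeans(early[, c("x", "y", "z")])
    data.frame(pore_index = i, n_early = nrow(early), n_late = nrow(late),
               dx = d[1], dy = d[2], dz = d[3],
               displacement = sqrt(sum(d^2)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
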