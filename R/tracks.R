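# Cargo-track curation and transport classification: photometric filters,
# pore assignment, transit detection, import/export/abortive calls, angular
# confinement and residence times.

#' Track filter parameters
#'
#' Defaults follow the tracking-channel curation: tracks need at least 5
#' consecutive passing localizations, CFR below 0.8, EFO inside the
#' acquisition profile's window, and DCR inside the cargo dye's spectral
#' window (default \[0.3, 0.8\] — background leaking from the scaffold dye
#' sits at high DCR, autofluorescence at low). Tracks whose median EFO
#' exceeds `double_dye_efo_factor` times the dataset median are flagged as
#' carrying two dyes but retained.
#'
#' @param min_len minimum consecutive passing localizations (>= 2).
#' @param cfr_max CFR upper limit.
#' @param efo_min_kHz,efo_max_kHz EFO window, kHz.
#' @param dcr_window length-2 DCR window `[lo, hi]`.
#' @param double_dye_efo_factor multiplier on the dataset median EFO above
#'   which a track is flagged as double-dye.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_len = 5, cfr_max = 0.8,
                          efo_min_kHz = 15, efo_max_kHz = 100,
                          dcr_window = c(0.3, 0.8),
                          double_dye_efo_factor = 1.7) {
  stopifnot(min_len >= 2, dcr_window[1] < dcr_window[2],
            efo_min_kHz < efo_max_kHz)
  structure(list(min_len = as.integer(min_len), cfr_max = cfr_max,
                 efo_min_kHz = efo_min_kHz, efo_max_kHz = efo_max_kHz,
                 dcr_window = dcr_window,
                 double_dye_efo_factor = double_dye_efo_factor),
            class = "filter_params")
}

#' Filter cargo localizations into candidate track segments
#'
#' Within each `trace_id`, localizations failing any per-point gate (CFR,
#' EFO window, DCR window) break the run; every maximal run of consecutive
#' passing localizations with length >= `min_len` becomes a track segment.
#' A rejection log counts localizations removed per reason and tracks
#' dropped for length. Missing (`NA`) photometric values pass their gate
#' (absence is not evidence of background). Filtering is idempotent:
#' re-filtering the surviving segments changes nothing.
#'
#' @param records cargo-channel localization data frame.
#' @param params a [filter_params()].
#' @return list of class `track_set`: `segments` (list of localization
#'   data frames, each with attributes `track_id` and `double_dye_flag`)
#'   and `rejection_log` (named integer vector: `cfr`, `efo_low`,
#'   `efo_high`, `dcr`, `too_short` — the last counts dropped fragments).
#' @export
filter_tracks <- function(records, params = filter_params()) {
  log <- c(cfr = 0L, efo_low = 0L, efo_high = 0L, dcr = 0L, too_short = 0L)
  segments <- list()
  if (nrow(records)) {
    efo_med <- stats::median(records$efo, na.rm = TRUE)
    fail_cfr <- !is.na(records$cfr) & records$cfr >= params$cfr_max
    fail_efo_lo <- !is.na(records$efo) & records$efo < params$efo_min_kHz
    fail_efo_hi <- !is.na(records$efo) & records$efo > params$efo_max_kHz
    fail_dcr <- !is.na(records$dcr) &
      (records$dcr < params$dcr_window[1] | records$dcr > params$dcr_window[2])
    log["cfr"] <- sum(fail_cfr)
    log["efo_low"] <- sum(fail_efo_lo & !fail_cfr)
    log["efo_high"] <- sum(fail_efo_hi & !fail_cfr & !fail_efo_lo)
    log["dcr"] <- sum(fail_dcr & !fail_cfr & !fail_efo_lo & !fail_efo_hi)
    pass <- !(fail_cfr | fail_efo_lo | fail_efo_hi | fail_dcr)
    frag <- 0L
    for (rows in split(seq_len(nrow(records)), records$trace_id)) {
      p <- pass[rows]
      runs <- rle(p)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (ri in which(runs$values)) {
        seg_rows <- rows[starts[ri]:ends[ri]]
        if (length(seg_rows) < params$min_len) {
          log["too_short"] <- log["too_short"] + 1L
          next
        }
        frag <- frag + 1L
        seg <- records[seg_rows, , drop = FALSE]
        rownames(seg) <- NULL
        attr(seg, "track_id") <- seg$trace_id[1] * 1000L + frag
        attr(seg, "double_dye_flag") <-
          !is.na(efo_med) && isTRUE(stats::median(seg$efo, na.rm = TRUE) >
                                      params$double_dye_efo_factor * efo_med)
        segments[[length(segments) + 1L]] <- seg
      }
    }
  }
  structure(list(segments = segments, rejection_log = log,
                 params = params),
            class = "track_set")
}

#' Assign track segments to NPCs and move them into pore frames
#'
#' A track is assigned to a pore if any of its localizations falls inside
#' a cube of side `cube_nm` centred on that pore; with several candidate
#' pores the one whose centre is nearest at the track's closest approach
#' wins (deterministically). Assigned tracks get pore-frame coordinates
#' `xp`, `yp`, `zp`: translated to the pore centre, rotated in xy by minus
#' the pore's phase, cytoplasm at +z. Unassigned tracks are classed
#' `background`.
#'
#' @param track_set a [filter_tracks()] result (or bare list of segments).
#' @param scaffolds data frame of pore fits with columns `pore_id`, `x0`,
#'   `y0`, `z0`, `phase_deg` (see [scaffold_table()]), or a list of
#'   `npc_scaffold` objects.
#' @param cube_nm cube side length (default 400).
#' @return the track set with per-segment attributes `pore_id` (NA if
#'   background) and added pore-frame columns for assigned segments.
#' @export
assign_tracks_to_npcs <- function(track_set, scaffolds, cube_nm = 400) {
  segments <- if (inherits(track_set, "track_set")) track_set$segments
    else track_set
  sc <- if (is.data.frame(scaffolds)) scaffolds else scaffold_table(scaffolds)
  half <- cube_nm / 2
  out <- lapply(segments, function(seg) {
    best <- NA_integer_; best_d <- Inf
    for (p in seq_len(nrow(sc))) {
      dx <- seg$x - sc$x0[p]; dy <- seg$y - sc$y0[p]; dz <- seg$z - sc$z0[p]
      inside <- abs(dx) <= half & abs(dy) <= half & abs(dz) <= half
      if (any(inside)) {
        d <- min(sqrt(dx^2 + dy^2 + dz^2))
        if (d < best_d) { best_d <- d; best <- p }
      }
    }
    if (is.na(best)) {
      attr(seg, "pore_id") <- NA_integer_
      return(seg)
    }
    ph <- sc$phase_deg[best]
    if (is.na(ph)) ph <- 0
    a <- -ph * pi / 180
    dx <- seg$x - sc$x0[best]; dy <- seg$y - sc$y0[best]
    seg$xp <- dx * cos(a) - dy * sin(a)
    seg$yp <- dx * sin(a) + dy * cos(a)
    seg$zp <- seg$z - sc$z0[best]
    attr(seg, "pore_id") <- sc$pore_id[best]
    seg
  })
  if (inherits(track_set, "track_set")) {
    track_set$segments <- out
    track_set
  } else out
}

#' Tabulate a list of scaffold fits
#'
#' @param scaffolds list of `npc_scaffold` objects.
#' @return data frame `pore_id,x0,y0,z0,ring_radius,ring_spacing,phase_deg,n,rms`.
#' @export
scaffold_table <- function(scaffolds) {
  out <- do.call(rbind, lapply(seq_along(scaffolds), function(i) {
    f <- scaffolds[[i]]
    data.frame(pore_id = i, x0 = unname(f$centre["x0"]),
               y0 = unname(f$centre["y0"]), z0 = unname(f$centre["z0"]),
               ring_radius = f$ring_radius, ring_spacing = f$ring_spacing,
               phase_deg = f$phase_deg, n = f$n_localizations,
               rms = f$rms_residual)
  }))
  rownames(out) <- NULL
  out
}

#' Detect a pore transit
#'
#' A track is transiting if any localization lies within
#' `half_thickness_nm` of the pore midplane (|z| <= threshold,
#' inclusive).
#'
#' @param track pore-frame track data frame (needs `zp`).
#' @param half_thickness_nm central-channel half thickness (default 25).
#' @return list: `transit` (logical), `in_pore` (ordered indices with
#'   |zp| <= threshold).
#' @export
detect_transit <- function(track, half_thickness_nm = 25) {
  stopifnot("zp" %in% names(track))
  idx <- which(abs(track$zp) <= half_thickness_nm)
  list(transit = length(idx) > 0, in_pore = idx)
}

#' Classify a transit-flagged track
#'
#' Uses the compartment threshold (+/- `half_thickness_nm`) on the
#' pore-frame z axis, cytoplasm at +z: `import` starts cytoplasmic
#' (z > +25) and ends nucleoplasmic (z < -25); `export` is the mirror;
#' `abortive_import` enters from the cytoplasmic side, never attains
#' z < 0 and returns to z > +25; `abortive_export` mirrors that;
#' anything else is `unclassified`.
#'
#' @param track pore-frame track data frame.
#' @param half_thickness_nm compartment threshold (default 25).
#' @return one of `"import"`, `"export"`, `"abortive_import"`,
#'   `"abortive_export"`, `"unclassified"`.
#' @export
classify_track <- function(track, half_thickness_nm = 25) {
  z <- track$zp
  h <- half_thickness_nm
  z1 <- z[1]; zn <- z[length(z)]
  if (z1 > h && zn < -h) return("import")
  if (z1 < -h && zn > h) return("export")
  if (z1 > h && zn > h && min(z) <= h && min(z) > 0) return("abortive_import")
  if (z1 < -h && zn < -h && max(z) >= -h && max(z) < 0) return("abortive_export")
  "unclassified"
}

#' Classify every assigned track in a set
#'
#' @param track_set an [assign_tracks_to_npcs()] result.
#' @param half_thickness_nm compartment threshold (default 25).
#' @return data frame: `track_id`, `pore_id`, `class`, `transit`,
#'   `n_points`, `n_in_pore`, `residence_s`, `double_dye_flag`. Tracks
#'   without a pore are `background`; assigned tracks that never transit
#'   are `unclassified` with `transit = FALSE`.
#' @export
classify_tracks <- function(track_set, half_thickness_nm = 25) {
  segments <- if (inherits(track_set, "track_set")) track_set$segments
    else track_set
  out <- lapply(segments, function(seg) {
    pid <- attr(seg, "pore_id")
    tid <- attr(seg, "track_id")
    dd <- isTRUE(attr(seg, "double_dye_flag"))
    if (is.null(pid) || is.na(pid))
      return(data.frame(track_id = tid, pore_id = NA_integer_,
                        class = "background", transit = FALSE,
                        n_points = nrow(seg), n_in_pore = 0L,
                        residence_s = 0, double_dye_flag = dd))
    tr <- detect_transit(seg, half_thickness_nm)
    cls <- if (tr$transit) classify_track(seg, half_thickness_nm)
      else "unclassified"
    res <- if (tr$transit) residence_time(seg, half_thickness_nm)
      else list(seconds = 0, n_in_pore = 0L)
    data.frame(track_id = tid, pore_id = pid, class = cls,
               transit = tr$transit, n_points = nrow(seg),
               n_in_pore = res$n_in_pore, residence_s = res$seconds,
               double_dye_flag = dd)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Residence time within the central pore
#'
#' Sums the inter-localization intervals between consecutive in-pore
#' points (|z| <= threshold); a single in-pore point contributes zero.
#'
#' @param track pore-frame track data frame (needs `zp` and `t`).
#' @param half_thickness_nm central-channel half thickness (default 25).
#' @return list: `seconds`, `n_in_pore`.
#' @export
residence_time <- function(track, half_thickness_nm = 25) {
  idx <- detect_transit(track, half_thickness_nm)$in_pore
  if (length(idx) < 2) return(list(seconds = 0, n_in_pore = length(idx)))
  consec <- idx[which(diff(idx) == 1)]
  secs <- sum(track$t[consec + 1L] - track$t[consec])
  list(seconds = secs, n_in_pore = length(idx))
}

#' Angular confinement of transiting tracks
#'
#' For each track the reference is the azimuth (pore frame,
#' `atan2(yp, xp)` in degrees) of the in-pore localization nearest the
#' midplane; angular differences of all other in-pore localizations from
#' that reference are pooled over tracks, wrapped to (-180, 180], and a
#' zero-centred Gaussian is fitted. Tracks with fewer than two in-pore
#' points contribute nothing. A chi-square goodness test against the
#' fitted Gaussian flags azimuthally unconfined (e.g. uniform) data.
#'
#' @param track_set assigned track set, or list of pore-frame track data
#'   frames.
#' @param half_thickness_nm central-channel half thickness (default 25).
#' @param min_width_deg lower bound (regularization) on the fitted width.
#' @return list of class `angular_stats`: `differences_deg`,
#'   `gaussian_width_deg`, `n_tracks`, `goodness_p` (chi-square p-value;
#'   small means the Gaussian model fits poorly).
#' @export
angular_analysis <- function(track_set, half_thickness_nm = 25,
                             min_width_deg = 0.5) {
  segments <- if (inherits(track_set, "track_set")) track_set$segments
    else track_set
  diffs <- numeric(0); n_tracks <- 0L
  for (seg in segments) {
    if (!"zp" %in% names(seg)) next
    idx <- which(abs(seg$zp) <= half_thickness_nm)
    if (length(idx) < 2) next
    ref_i <- idx[which.min(abs(seg$zp[idx]))]
    az <- atan2(seg$yp[idx], seg$xp[idx]) * 180 / pi
    ref <- atan2(seg$yp[ref_i], seg$xp[ref_i]) * 180 / pi
    d <- (az[idx != ref_i] - ref + 180) %% 360 - 180
    d[d == -180] <- 180
    diffs <- c(diffs, d)
    n_tracks <- n_tracks + 1L
  }
  if (!length(diffs))
    stop("no track contributed >= 2 in-pore localizations", call. = FALSE)
  width <- max(sqrt(mean(diffs^2)), min_width_deg)
  # goodness: chi-square of the binned differences against N(0, width)
  nb <- max(6, min(24, floor(length(diffs) / 5)))
  edges <- seq(-180, 180, length.out = nb + 1)
  bi <- findInterval(diffs, edges, rightmost.closed = TRUE)
  counts <- tabulate(bi, nbins = nb)
  pr <- stats::pnorm(edges[-1], 0, width) - stats::pnorm(edges[-(nb + 1)], 0, width)
  pr <- pr / sum(pr)
  expct <- pr * length(diffs)
  ok <- expct > 0.5
  chi2 <- sum((counts[ok] - expct[ok])^2 / expct[ok])
  pval <- stats::pchisq(chi2, df = max(sum(ok) - 2, 1), lower.tail = FALSE)
  structure(list(differences_deg = diffs, gaussian_width_deg = width,
                 n_tracks = n_tracks, goodness_p = pval),
            class = "angular_stats")
}

#' @export
print.angular_stats <- function(x, ...) {
  cat(sprintf("Angular confinement: Gaussian width %.1f deg (%d tracks, %d differences)\n",
              x$gaussian_width_deg, x$n_tracks, length(x$differences_deg)))
  if (x$goodness_p < 0.01)
    cat("  warning: Gaussian model fits poorly (p < 0.01); distribution may be unconfined\n")
  invisible(x)
}

#' Export a track classification table
#'
#' @param classification a [classify_tracks()] data frame.
#' @param path CSV path.
#' @return invisibly `path`.
#' @export
write_track_table <- function(classification, path) {
  out <- classification
  out$residence_ms <- out$residence_s * 1000
  out$residence_s <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
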