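# Channel registration: axial scale calibration from the double-ring
# spacing, and fiducial-based rigid xy alignment of the cargo channel onto
# the scaffold channel.

#' Axial scaling factor from a reference ring spacing
#'
#' Raw MINFLUX z coordinates are compressed by the refractive-index mismatch
#' between sample and immersion medium. The scale factor is calibrated as
#' the ratio of an independently measured (astigmatism) cytoplasmic-to-
#' nucleoplasmic ring spacing to the spacing seen in the raw MINFLUX data;
#' with the reference 51.5 nm and a raw spacing of 76.8 nm the factor is
#' 51.5/76.8 = 0.67 (2 dp). Full precision is kept internally; only the
#' display rounds.
#'
#' @param reference_spacing independently calibrated ring spacing, nm.
#' @param raw_spacing ring spacing in the raw MINFLUX data, nm.
#' @return the scale factor (full precision double).
#' @export
compute_z_scale <- function(reference_spacing, raw_spacing) {
  if (!is.finite(reference_spacing) || reference_spacing <= 0 ||
      !is.finite(raw_spacing) || raw_spacing <= 0)
    stop("ring spacings must be positive and finite", call. = FALSE)
  reference_spacing / raw_spacing
}

#' Axial calibration object
#'
#' @param reference_spacing,raw_spacing nm, see [compute_z_scale()].
#' @param z_offset_per_cell per-cell z offset (nm) subtracted after scaling.
#' @return list of class `axial_calibration` with `z_scale` equal to the
#'   exact quotient.
#' @export
axial_calibration <- function(reference_spacing = 51.5, raw_spacing = 76.8,
                              z_offset_per_cell = 0) {
  stopifnot(is.finite(z_offset_per_cell))
  structure(list(z_scale = compute_z_scale(reference_spacing, raw_spacing),
                 z_offset_per_cell = z_offset_per_cell,
                 reference_spacing = reference_spacing,
                 raw_spacing = raw_spacing),
            class = "axial_calibration")
}

#' @export
print.axial_calibration <- function(x, ...) {
  cat(sprintf("Axial calibration: z_scale = %.2f (%.1f nm / %.1f nm), z offset = %.1f nm\n",
              x$z_scale, x$reference_spacing, x$raw_spacing,
              x$z_offset_per_cell))
  invisible(x)
}

#' Fit a rigid xy transform (plus mean z deviation) from fiducial pairs
#'
#' Least-squares orthogonal Procrustes in the xy plane only — rotation and
#' translation, no scaling, reflections corrected to a proper rotation (and
#' flagged) — mapping the source (cargo) beads onto the target (scaffold)
#' beads. Repeated measurements of a bead are collapsed to per-bead medians
#' before fitting (robust to transient outliers). The z axis is handled
#' separately: the mean per-bead deviation `mean(source_z * z_scale -
#' target_z)` becomes the per-cell z offset of the calibration.
#'
#' @param fiducials data frame as from [read_fiducials()] /
#'   [simulate_fiducials()] with both channels, or a list
#'   `list(source, target)` of matched n x 3 matrices.
#' @param z_scale axial scale applied to source z before the offset is
#'   measured (default 1).
#' @param source,target channel names when `fiducials` is a data frame.
#' @return list of class `rigid_transform2d`: `rotation` (2 x 2, det +1),
#'   `translation` (nm), `rms_residual_xy` (nm), `z_offset` (nm),
#'   `reflection_corrected`, `n_beads`.
#' @export
fit_rigid_transform <- function(fiducials, z_scale = 1,
                                source = "cargo", target = "scaffold") {
  if (is.data.frame(fiducials)) {
    med <- function(ch) {
      d <- fiducials[fiducials$channel == ch, ]
      if (!nrow(d)) stop("no fiducials for channel '", ch, "'", call. = FALSE)
      agg <- stats::aggregate(d[, c("x", "y", "z")],
                              by = list(bead_id = d$bead_id), FUN = stats::median)
      agg[order(agg$bead_id), ]
    }
    S <- med(source); T_ <- med(target)
    common <- intersect(S$bead_id, T_$bead_id)
    if (length(common) < 2)
      stop("need at least 2 beads present in both channels", call. = FALSE)
    S <- as.matrix(S[match(common, S$bead_id), c("x", "y", "z")])
    T_ <- as.matrix(T_[match(common, T_$bead_id), c("x", "y", "z")])
  } else {
    S <- as.matrix(fiducials$source); T_ <- as.matrix(fiducials$target)
    if (nrow(S) != nrow(T_) || nrow(S) < 2)
      stop("need >= 2 matched source/target beads", call. = FALSE)
  }
  sxy <- S[, 1:2, drop = FALSE]; txy <- T_[, 1:2, drop = FALSE]
  sc <- colMeans(sxy); tc <- colMeans(txy)
  A <- sweep(sxy, 2, sc); B <- sweep(txy, 2, tc)
  H <- t(A) %*% B
  if (qr(A)$rank < 2)
    stop("fiducials are collinear or duplicated; xy rotation unidentifiable",
         call. = FALSE)
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  reflected <- det(R) < 0
  if (reflected) {            # force a proper rotation (Kabsch correction)
    V <- sv$v; V[, 2] <- -V[, 2]
    R <- V %*% t(sv$u)
  }
  tr <- tc - as.vector(R %*% sc)
  fitted <- sweep(sxy %*% t(R), 2, tr, `+`)
  rms <- sqrt(mean(rowSums((fitted - txy)^2)))
  z_offset <- mean(S[, 3] * z_scale - T_[, 3])
  structure(list(rotation = R, translation = tr, rms_residual_xy = rms,
                 z_offset = z_offset, reflection_corrected = reflected,
                 n_beads = nrow(S)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  ang <- atan2(x$rotation[2, 1], x$rotation[1, 1]) * 180 / pi
  cat(sprintf("Rigid xy transform: rotation %.4f deg, translation (%.2f, %.2f) nm\n",
              ang, x$translation[1], x$translation[2]))
  cat(sprintf("  rms xy residual %.3f nm over %d beads; mean z deviation %.2f nm\n",
              x$rms_residual_xy, x$n_beads, x$z_offset))
  if (x$reflection_corrected)
    cat("  note: reflection-optimal solution corrected to a proper rotation\n")
  invisible(x)
}

#' Register cargo-channel localizations into the scaffold frame
#'
#' Applies the rigid xy transform, then scales z by the axial calibration
#' factor and subtracts the per-cell z offset (scale strictly before
#' offset). Row order and all photometric fields are preserved.
#'
#' @param records localization data frame.
#' @param transform a [fit_rigid_transform()] result (or `NULL` for
#'   identity).
#' @param calib an [axial_calibration()]; its `z_offset_per_cell` is used
#'   unless the transform carries a fitted `z_offset`, which wins.
#' @return the transformed localization data frame.
#' @export
apply_registration <- function(records, transform = NULL,
                               calib = axial_calibration(51.5, 51.5)) {
  stopifnot(inherits(calib, "axial_calibration"))
  out <- records
  if (!is.null(transform)) {
    stopifnot(inherits(transform, "rigid_transform2d"))
    xy <- as.matrix(records[, c("x", "y")]) %*% t(transform$rotation)
    out$x <- xy[, 1] + transform$translation[1]
    out$y <- xy[, 2] + transform$translation[2]
  }
  z_off <- if (!is.null(transform) && !is.null(transform$z_offset))
    transform$z_offset else calib$z_offset_per_cell
  out$z <- records$z * calib$z_scale - z_off
  out
}
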