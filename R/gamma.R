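#' Gamma comparison criteria
#'
#' Criteria for the absolute 2D gamma index. The dose criterion is a
#' percentage of the normalization dose: the reference plane's central-axis
#' dose (`"global_cax"`, the default — absolute planes are anchored to the
#' measured CAX point dose) or its maximum (`"global_max"`). The evaluated
#' plane is bilinearly subsampled on a lattice of `subsample_step_mm` within
#' a search disc of radius `search_radius_factor * dta_mm`; a step of at most
#' a third of the DTA is required for a convergent minimum (default: a
#' tenth).
#'
#' @param dose_percent Dose-difference criterion, percent of the
#'   normalization dose (default 3).
#' @param dta_mm Distance-to-agreement criterion in mm (default 3).
#' @param normalization `"global_cax"` or `"global_max"`.
#' @param search_radius_factor Search radius as a multiple of the DTA
#'   (default 3).
#' @param subsample_step_mm Subsampling step in mm (default `dta_mm / 10`).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent = 3, dta_mm = 3,
                           normalization = c("global_cax", "global_max"),
                           search_radius_factor = 3,
                           subsample_step_mm = dta_mm / 10) {
  normalization <- match.arg(normalization)
  if (dose_percent <= 0 || dta_mm <= 0) stop("criteria must be positive")
  if (subsample_step_mm > dta_mm / 3 + 1e-12)
    stop("subsample step must be at most dta/3 for a convergent search")
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 normalization = normalization,
                 search_radius_factor = search_radius_factor,
                 subsample_step_mm = subsample_step_mm),
            class = "gamma_criteria")
}

#' Square field region-of-interest mask
#'
#' Boolean mask over a plane's grid selecting the square field area projected
#' to the plane's depth: the full-field edge is `fs * (ssd + depth) / 100`
#' (field size is defined at 100 cm from source), and the central-80% region
#' scales that edge by 0.8 (linear edge scaling, so it contains 64% of the
#' full-field points).
#'
#' @param plane A [dose_plane()].
#' @param fs Field size (cm); defaults to the plane's.
#' @param depth Depth (cm); defaults to the plane's.
#' @param ssd Source-to-surface distance (cm, default 100).
#' @param area_fraction Edge scaling factor: 1.0 for the full field, 0.8 for
#'   the central 80%.
#' @return A logical matrix aligned with `plane$dose`.
#' @export
field_roi <- function(plane, fs = plane$field_size, depth = plane$depth,
                      ssd = 100, area_fraction = 1.0) {
  stopifnot(inherits(plane, "dose_plane"))
  half <- area_fraction * fs * (ssd + depth) / 200
  if (half > max(plane$x_coords) + 1e-9 || half > -min(plane$x_coords) + 1e-9 ||
      half > max(plane$y_coords) + 1e-9 || half > -min(plane$y_coords) + 1e-9)
    stop("field ROI (half-edge ", format(half), " cm) exceeds the plane extent")
  outer(abs(plane$x_coords) <= half + 1e-9,
        abs(plane$y_coords) <= half + 1e-9, "&")
}

#' Pass rate of a gamma grid over a mask
#'
#' @param gamma Numeric matrix of gamma values (NA counts as failure).
#' @param mask Logical matrix of the same shape.
#' @return Percent of masked points with gamma <= 1.
#' @export
pass_rate <- function(gamma, mask) {
  stopifnot(all(dim(gamma) == dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("empty ROI mask")
  100 * sum(!is.na(gamma[mask]) & gamma[mask] <= 1) / n
}

.gamma_norm_dose <- function(ref, crit) {
  dnorm <- switch(crit$normalization,
                  global_cax = plane_cax_dose(ref),
                  global_max = max(ref$dose))
  if (!is.finite(dnorm) || dnorm <= 0)
    stop("zero or invalid normalization dose for gamma comparison")
  dnorm
}

#' 2D absolute gamma index
#'
#' Computes the gamma index of an evaluated dose plane against a reference
#' plane (convention: reference = measured, evaluated = TPS-computed). For
#' each reference grid point,
#' \deqn{\gamma = \min_{r} \sqrt{\left(\frac{D_e(r) - D_r}{\Delta D}\right)^2
#'   + \frac{|r|^2}{\delta^2}}}
#' over evaluated-plane positions within the search radius, where
#' \eqn{\Delta D} is `dose_percent` of the normalization dose and
#' \eqn{\delta} the DTA. A point passes when gamma <= 1. Pass rates are
#' reported over the full projected field area and over its central 80%
#' (see [field_roi()]); set `rois = FALSE` to report rates over the whole
#' grid instead (useful for planes without field geometry).
#'
#' @param ref Reference [dose_plane()].
#' @param eval Evaluated [dose_plane()]; must be at the same depth and cover
#'   the reference ROI plus the search radius.
#' @param crit A [gamma_criteria()].
#' @param ssd Source-to-surface distance (cm) for the ROI projection.
#' @param rois Compute field-area ROI masks and their pass rates (default
#'   `TRUE`).
#' @return An object of class `gamma_result`: gamma grid aligned to the
#'   reference plane, pass rates (`pass_rate_full`, `pass_rate_80`), ROI
#'   masks, criteria and normalization dose.
#' @export
gamma_index <- function(ref, eval, crit = gamma_criteria(), ssd = 100,
                        rois = TRUE) {
  stopifnot(inherits(ref, "dose_plane"), inherits(eval, "dose_plane"),
            inherits(crit, "gamma_criteria"))
  if (abs(ref$depth - eval$depth) > 1e-9)
    stop("reference and evaluated planes are at different depths")
  dnorm <- .gamma_norm_dose(ref, crit)
  dcrit <- crit$dose_percent / 100 * dnorm
  dta_cm <- crit$dta_mm / 10
  radius_cm <- crit$search_radius_factor * dta_cm
  step_cm <- crit$subsample_step_mm / 10

  masks <- NULL
  if (rois) {
    masks <- list(full = field_roi(ref, ssd = ssd, area_fraction = 1.0),
                  central80 = field_roi(ref, ssd = ssd, area_fraction = 0.8))
    roi_half <- ref$field_size * (ssd + ref$depth) / 200
    if (roi_half + radius_cm > max(eval$x_coords) + 1e-9 ||
        -(roi_half + radius_cm) < min(eval$x_coords) - 1e-9 ||
        roi_half + radius_cm > max(eval$y_coords) + 1e-9 ||
        -(roi_half + radius_cm) < min(eval$y_coords) - 1e-9)
      stop("evaluated plane too small to cover the field ROI plus the ",
           "gamma search radius")
  }

  g <- .gamma_kernel(ref$x_coords, ref$y_coords, ref$dose,
                     eval$x_coords, eval$y_coords, eval$dose,
                     dcrit, dta_cm, radius_cm, step_cm)
  if (is.null(masks)) {
    all_mask <- matrix(TRUE, nrow(g), ncol(g))
    pr_full <- pass_rate(g, all_mask); pr_80 <- pr_full
  } else {
    pr_full <- pass_rate(g, masks$full)
    pr_80 <- pass_rate(g, masks$central80)
  }
  structure(
    list(gamma = g, pass_rate_full = pr_full, pass_rate_80 = pr_80,
         criteria = crit, roi_masks = masks, normalization_dose = dnorm,
         depth = ref$depth, field_size = ref$field_size),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %g%%/%g mm (%s), fs %g cm, depth %g cm\n",
    x$criteria$dose_percent, x$criteria$dta_mm, x$criteria$normalization,
    x$field_size, x$depth))
  cat(sprintf("  pass rate: %.1f%% (full field), %.1f%% (central 80%%)\n",
              x$pass_rate_full, x$pass_rate_80))
  invisible(x)
}

#' Exhaustive-search gamma reference implementation
#'
#' Slow, direct evaluation of the gamma index used as an independent check
#' of [gamma_index()]: for every reference point it enumerates the complete
#' offset lattice inside the search disc (no early termination) and
#' interpolates the evaluated plane with [pracma::interp2()]. Intended for
#' small planes and testing only.
#'
#' @inheritParams gamma_index
#' @return Numeric matrix of gamma values aligned to the reference grid.
#' @export
gamma_exhaustive <- function(ref, eval, crit = gamma_criteria()) {
  dnorm <- .gamma_norm_dose(ref, crit)
  dcrit <- crit$dose_percent / 100 * dnorm
  dta_cm <- crit$dta_mm / 10
  radius_cm <- crit$search_radius_factor * dta_cm
  step_cm <- crit$subsample_step_mm / 10
  k <- ceiling(radius_cm / step_cm + 1e-9)
  off <- expand.grid(dx = seq(-k, k) * step_cm, dy = seq(-k, k) * step_cm)
  off$r2 <- off$dx^2 + off$dy^2
  off <- off[off$r2 <= radius_cm^2 + 1e-12, ]
  rx <- range(eval$x_coords); ry <- range(eval$y_coords)
  g <- matrix(NA_real_, length(ref$x_coords), length(ref$y_coords))
  for (i in seq_along(ref$x_coords)) {
    for (j in seq_along(ref$y_coords)) {
      x0 <- ref$x_coords[i]; y0 <- ref$y_coords[j]
      px <- x0 + off$dx; py <- y0 + off$dy
      keep <- px >= rx[1] - 1e-12 & px <= rx[2] + 1e-12 &
        py >= ry[1] - 1e-12 & py <= ry[2] + 1e-12
      if (!any(abs(off$dx[keep]) < 1e-12 & abs(off$dy[keep]) < 1e-12)) next
      de <- pracma::interp2(x = eval$y_coords, y = eval$x_coords,
                            Z = eval$dose,
                            xp = pmin(pmax(py[keep], ry[1]), ry[2]),
                            yp = pmin(pmax(px[keep], rx[1]), rx[2]),
                            method = "linear")
      g2 <- ((de - ref$dose[i, j]) / dcrit)^2 + off$r2[keep] / dta_cm^2
      g[i, j] <- sqrt(min(g2))
    }
  }
  g
}
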