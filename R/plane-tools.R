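# Profile and dose-plane geometry tools: central-axis normalization,
# cross-multiplication plane synthesis, axis/diagonal extraction, and
# relative profile comparison.

# bilinear interpolation on a dose plane; xq/yq vectors of equal length.
# dose[i, j] corresponds to (x_coords[i], y_coords[j]); pracma::interp2 uses
# the MATLAB convention Z[length(y), length(x)], so axes are swapped in the
# call.
.plane_at <- function(plane, xq, yq) {
  rx <- range(plane$x_coords); ry <- range(plane$y_coords)
  if (any(xq < rx[1] - 1e-9 | xq > rx[2] + 1e-9 |
          yq < ry[1] - 1e-9 | yq > ry[2] + 1e-9))
    stop("query outside the dose plane extent")
  pracma::interp2(x = plane$y_coords, y = plane$x_coords, Z = plane$dose,
                  xp = pmin(pmax(yq, ry[1]), ry[2]),
                  yp = pmin(pmax(xq, rx[1]), rx[2]), method = "linear")
}

#' Central-axis dose of a plane
#'
#' Bilinear interpolation of the plane at (0, 0).
#'
#' @param plane A [dose_plane()].
#' @return Dose at the central axis (cGy).
#' @export
plane_cax_dose <- function(plane) .plane_at(plane, 0, 0)

#' Normalize a scan profile to the central axis
#'
#' Divides a profile by its value at position 0 (linearly interpolated when 0
#' is not a sample point), the convention used for relative profile
#' comparison. Idempotent, and invariant under overall scaling of the input.
#'
#' @param p A [scan_profile()].
#' @return A relative [scan_profile()] with `value(0) = 1`.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "scan_profile"))
  cax <- interpolate(p, 0)
  if (cax <= 0) stop("central-axis value must be positive to normalize")
  scan_profile(p$axis, p$depth, p$field_size, p$positions, p$values / cax,
               relative = TRUE)
}

#' Synthesize a 2D absolute dose plane from two orthogonal 1D profiles
#'
#' Cross-multiplication construction: the crossline and inline profiles are
#' normalized to the central axis and their outer product, scaled by the
#' measured central-axis point dose, gives the plane:
#' `plane(x, y) = n_px(x) * n_py(y) * d_cax`, so `plane(0, 0) = d_cax`.
#' Planes built this way are exactly separable; true corner dose is not, a
#' known limitation of the construction (it is accurate to within the level
#' that 2D-array validations resolve).
#'
#' @param px,py [scan_profile()]s at the same depth and field size (the two
#'   orthogonal scan axes).
#' @param d_cax Measured central-axis dose (cGy) at that depth.
#' @param spacing Grid spacing (cm, default 0.2, the scan resolution).
#' @param extent_factor Plane half-extent as a multiple of the projected
#'   field half-width (default 1.6, covering penumbra and out-of-field
#'   tails); the extent is clipped to the scanned range of the profiles.
#' @param ssd Source-to-surface distance (cm) used to project the field width
#'   to depth.
#' @return A [dose_plane()].
#' @export
synthesize_plane <- function(px, py, d_cax, spacing = 0.2,
                             extent_factor = 1.6, ssd = 100) {
  stopifnot(inherits(px, "scan_profile"), inherits(py, "scan_profile"))
  if (abs(px$depth - py$depth) > 1e-9)
    stop("profiles are at different depths (", px$depth, " vs ", py$depth,
         " cm)")
  if (abs(px$field_size - py$field_size) > 1e-9)
    stop("profiles are at different field sizes")
  if (d_cax <= 0) stop("central-axis dose must be positive")
  nx <- normalize_profile(px); ny <- normalize_profile(py)
  half_field <- px$field_size * (ssd + px$depth) / (2 * ssd)
  half <- min(extent_factor * half_field,
              -min(nx$positions), max(nx$positions),
              -min(ny$positions), max(ny$positions))
  k <- floor(half / spacing + 1e-9)
  coords <- seq(-k, k) * spacing
  vx <- interpolate(nx, coords)
  vy <- interpolate(ny, coords)
  dose_plane(px$depth, px$field_size, coords, coords,
             pmax(outer(vx, vy), 0) * d_cax)
}

#' Extract a 1D profile from a dose plane
#'
#' Samples the plane along the crossline (y = 0), inline (x = 0) or diagonal
#' (x = y) axis through the central axis, by bilinear interpolation. Diagonal
#' positions are signed radial distances along the diagonal (water-tank
#' diagonal scan convention), i.e. a position `s` samples the point
#' `(s / sqrt(2), s / sqrt(2))`.
#'
#' @param plane A [dose_plane()].
#' @param axis `"crossline"`, `"inline"` or `"diagonal"`.
#' @param spacing Sample spacing along the profile (cm); defaults to the
#'   plane's grid spacing.
#' @return A [scan_profile()] in absolute dose.
#' @export
extract_profile <- function(plane, axis = c("crossline", "inline", "diagonal"),
                            spacing = NULL) {
  axis <- match.arg(axis)
  h <- plane$x_coords[2] - plane$x_coords[1]
  if (is.null(spacing)) spacing <- h
  if (spacing <= 0) stop("spacing must be positive")
  lim_x <- min(-min(plane$x_coords), max(plane$x_coords))
  lim_y <- min(-min(plane$y_coords), max(plane$y_coords))
  lim <- switch(axis,
                crossline = lim_x,
                inline = lim_y,
                diagonal = min(lim_x, lim_y) * sqrt(2))
  k <- floor(lim / spacing + 1e-9)
  pos <- seq(-k, k) * spacing
  xy <- switch(axis,
               crossline = cbind(pos, 0),
               inline = cbind(0, pos),
               diagonal = cbind(pos / sqrt(2), pos / sqrt(2)))
  scan_profile(axis, plane$depth, plane$field_size, pos,
               .plane_at(plane, xy[, 1], xy[, 2]))
}

#' Compare two relative profiles
#'
#' Resamples profile `b` onto the positions of profile `a` (restricted to
#' their overlap) and reports per-position differences `b - a`, with each
#' position labelled by region: `"field"` for the inner 80% of the projected
#' field width, `"shoulder"` for the remaining in-field band, `"out"`
#' outside the field edge. No smoothing is applied.
#'
#' @param a,b Relative [scan_profile()]s (normalized to the central axis).
#' @param ssd Source-to-surface distance (cm) for the field-width projection.
#' @return A list with `table` (data frame: `position_cm`, `a`, `b`, `diff`,
#'   `region`), `max_abs_field` and `max_abs_shoulder`.
#' @export
compare_relative_profiles <- function(a, b, ssd = 100) {
  stopifnot(inherits(a, "scan_profile"), inherits(b, "scan_profile"))
  lo <- max(min(a$positions), min(b$positions))
  hi <- min(max(a$positions), max(b$positions))
  if (lo >= hi) stop("profiles have no overlapping position range")
  pos <- a$positions[a$positions >= lo - 1e-9 & a$positions <= hi + 1e-9]
  av <- interpolate(a, pos)
  bv <- interpolate(b, pos)
  half_field <- a$field_size * (ssd + a$depth) / (2 * ssd)
  region <- ifelse(abs(pos) <= 0.8 * half_field, "field",
                   ifelse(abs(pos) <= half_field, "shoulder", "out"))
  d <- bv - av
  list(table = data.frame(position_cm = pos, a = av, b = bv, diff = d,
                          region = region, stringsAsFactors = FALSE),
       max_abs_field = if (any(region == "field"))
         max(abs(d[region == "field"])) else NA_real_,
       max_abs_shoulder = if (any(region == "shoulder"))
         max(abs(d[region == "shoulder"])) else NA_real_)
}
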