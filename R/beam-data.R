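#' Percentage depth-dose curve
#'
#' Constructs a validated PDD curve for one square field size. Values are in
#' percent, normalised so that the maximum is 100; depths are in cm measured
#' from the beam entry surface.
#'
#' @param field_size Square field side in cm, defined at 100 cm from source.
#' @param depths Numeric vector of depths (cm), strictly increasing.
#' @param values Numeric vector of PDD values (percent); `max(values)` must be
#'   100 to within 1e-9 and all values must be positive.
#' @return An object of class `pdd_curve` with fields `field_size`, `depths`,
#'   `values` and `dmax` (the depth at which the maximum occurs).
#' @examples
#' d <- seq(0, 32, by = 0.5)
#' v <- 100 * exp(-0.04 * (d - 1.5)) * (1 - exp(-3.5 * (d + 0.1)))
#' pdd <- pdd_curve(10, d, 100 * v / max(v))
#' @export
pdd_curve <- function(field_size, depths, values) {
  stopifnot(is.numeric(depths), is.numeric(values),
            length(depths) == length(values), length(depths) >= 2)
  if (any(diff(depths) <= 0))
    stop("PDD depth grid must be strictly increasing")
  if (abs(max(values) - 100) > 1e-9)
    stop("PDD not normalized to 100 (max value ", format(max(values)), ")")
  if (any(values <= 0))
    stop("PDD values must be positive")
  structure(
    list(field_size = as.numeric(field_size),
         depths = as.numeric(depths),
         values = as.numeric(values),
         dmax = depths[which.max(values)]),
    class = "pdd_curve"
  )
}

#' Field-size output factor table
#'
#' Output factors relative to the 10 x 10 cm reference field; `factor(10)`
#' must equal 1 exactly and factors must increase strictly with field size
#' (photon beams).
#'
#' @param field_sizes Numeric vector of square field sides (cm).
#' @param factors Dimensionless output factors, same length.
#' @return An object of class `of_table`.
#' @export
of_table <- function(field_sizes, factors) {
  stopifnot(length(field_sizes) == length(factors))
  o <- order(field_sizes)
  field_sizes <- as.numeric(field_sizes[o])
  factors <- as.numeric(factors[o])
  if (!any(field_sizes == 10))
    stop("reference field size missing (no 10 cm row in output factor table)")
  if (factors[field_sizes == 10] != 1)
    stop("output factor at the 10 cm reference field must be exactly 1")
  if (any(diff(factors) <= 0))
    stop("output factors must be strictly increasing with field size")
  structure(list(field_sizes = field_sizes, factors = factors),
            class = "of_table")
}

#' 1D scan profile
#'
#' Off-axis dose samples at a fixed depth along one scan axis, in the
#' water-tank convention: position 0 is the central axis, positions in cm.
#' Diagonal positions are signed radial distances along the diagonal.
#'
#' @param axis One of `"crossline"`, `"inline"`, `"diagonal"`.
#' @param depth Depth of the scan plane (cm).
#' @param field_size Square field side (cm, at 100 cm from source).
#' @param positions Off-axis positions (cm), strictly increasing, bracketing 0.
#' @param values Dose values (cGy for absolute profiles, dimensionless for
#'   relative ones).
#' @param relative Logical; `TRUE` for a dimensionless profile.
#' @return An object of class `scan_profile`.
#' @export
scan_profile <- function(axis, depth, field_size, positions, values,
                         relative = FALSE) {
  axis <- match.arg(axis, c("crossline", "inline", "diagonal"))
  stopifnot(length(positions) == length(values), length(positions) >= 2)
  if (any(diff(positions) <= 0))
    stop("profile positions must be strictly increasing")
  if (min(positions) > 0 || max(positions) < 0)
    stop("profile must contain or bracket the central axis (position 0)")
  structure(
    list(axis = axis, depth = as.numeric(depth),
         field_size = as.numeric(field_size),
         positions = as.numeric(positions), values = as.numeric(values),
         relative = isTRUE(relative)),
    class = "scan_profile"
  )
}

#' 2D absolute dose plane
#'
#' A rectangular dose grid at fixed depth, central-axis-centred coordinates
#' in cm, uniform spacing, dose in cGy. `dose[i, j]` is the dose at
#' `(x_coords[i], y_coords[j])`.
#'
#' @param depth Depth of the plane (cm).
#' @param field_size Square field side (cm, at 100 cm).
#' @param x_coords,y_coords Uniformly spaced coordinates (cm).
#' @param dose Matrix of doses (cGy), `length(x_coords)` rows by
#'   `length(y_coords)` columns, non-negative.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(depth, field_size, x_coords, y_coords, dose) {
  stopifnot(is.matrix(dose),
            nrow(dose) == length(x_coords), ncol(dose) == length(y_coords))
  for (co in list(x_coords, y_coords)) {
    dc <- diff(co)
    if (any(dc <= 0) || diff(range(dc)) > 1e-9)
      stop("dose plane coordinates must be uniformly spaced and increasing")
  }
  if (any(dose < 0)) stop("dose plane contains negative dose")
  structure(
    list(depth = as.numeric(depth), field_size = as.numeric(field_size),
         x_coords = as.numeric(x_coords), y_coords = as.numeric(y_coords),
         dose = dose),
    class = "dose_plane"
  )
}

#' Central-axis dose measurement records
#'
#' A set of point-dose measurements at the central axis, each characterised by
#' field size, depth and backscatter thickness. Charge readings are converted
#' to dose through [charge_to_dose()] before building a measurement set; the
#' stored record always carries dose in cGy.
#'
#' @param machine_id Machine label.
#' @param field_size,depth,backscatter Numeric vectors (cm), recycled to a
#'   common length.
#' @param dose Measured dose (cGy), positive.
#' @param mu Monitor units delivered per measurement (default 100).
#' @param ssd Source-to-surface distance per measurement (cm, default 100).
#' @return A `data.frame` of class `dose_measurements` with columns
#'   `machine_id`, `field_size_cm`, `depth_cm`, `backscatter_cm`, `dose_cgy`,
#'   `mu`, `ssd_cm`.
#' @export
dose_measurements <- function(machine_id, field_size, depth, backscatter,
                              dose, mu = 100, ssd = 100) {
  df <- data.frame(machine_id = machine_id,
                   field_size_cm = field_size, depth_cm = depth,
                   backscatter_cm = backscatter, dose_cgy = dose,
                   mu = mu, ssd_cm = ssd,
                   stringsAsFactors = FALSE)
  if (any(df$dose_cgy <= 0)) stop("measured dose must be positive")
  class(df) <- c("dose_measurements", "data.frame")
  df
}

# Range within which a backscatter correction factor is physically plausible
# for 6 MV entrance/exit geometries; values marginally above 1 arise from
# measurement noise and are tolerated with a warning, never clamped.
.bcf_lower <- 0.9
.bcf_upper <- 1.01

.check_bcf_values <- function(x, what, upper = .bcf_upper) {
  bad <- x[!is.na(x) & (x <= .bcf_lower | x > upper)]
  if (length(bad))
    stop(what, " BCF outside (", .bcf_lower, ", ", upper, "]: ",
         paste(format(bad), collapse = ", "))
  over <- x[!is.na(x) & x > 1]
  if (length(over))
    warning(length(over), " ", what,
            " BCF value(s) exceed 1 (max ", format(max(over)),
            "); kept unclamped", call. = FALSE)
  invisible(x)
}

#' Backscatter correction factor table
#'
#' BCF = dose without backscatter / dose with full backscatter. The table has
#' two blocks mirroring how the factors are measured: an entrance block at
#' fixed depth 1.5 cm, keyed by field size and backscatter thickness, and an
#' exit block at fixed backscatter thickness 1.5 cm, keyed by field size and
#' depth. By symmetry of the geometry the exit BCF at depth 1.5 cm equals the
#' entrance BCF at backscatter thickness 1.5 cm, so the exit block starts at
#' 6.5 cm; lookups at exit depth 1.5 cm fall through to the entrance block.
#'
#' Values in (1, 1.01] are accepted with a warning (measurement noise can push
#' a factor marginally above unity); values outside (0.9, 1.01] are rejected.
#'
#' @param machine_id Machine label.
#' @param tpr2010 Beam-quality index TPR20,10 of the beam.
#' @param entrance Matrix of entrance BCFs, rows = field sizes, columns =
#'   backscatter thicknesses; `dimnames` give the numeric keys.
#' @param exit Matrix of exit BCFs, rows = field sizes, columns = depths.
#' @param max_bcf Upper plausibility bound. 1.01 (the default) suits measured
#'   and serialized tables; tables derived from single noisy measurement
#'   sessions may need 1.02 (a 3-sigma excursion of 0.5% session noise above
#'   a near-unity factor).
#' @return An object of class `bcf_table`.
#' @export
bcf_table <- function(machine_id, tpr2010, entrance, exit, max_bcf = 1.01) {
  for (m in list(entrance, exit)) {
    stopifnot(is.matrix(m), !is.null(dimnames(m)))
    fs <- as.numeric(rownames(m)); key <- as.numeric(colnames(m))
    if (anyNA(fs) || anyNA(key))
      stop("BCF block dimnames must be numeric field sizes / thicknesses")
    if (anyDuplicated(fs) || anyDuplicated(key))
      stop("duplicate (field size, thickness/depth) key in BCF block")
    if (is.unsorted(fs, strictly = TRUE) || is.unsorted(key, strictly = TRUE))
      stop("BCF block keys must be strictly increasing")
  }
  .check_bcf_values(entrance, "entrance", upper = max_bcf)
  .check_bcf_values(exit, "exit", upper = max_bcf)
  structure(
    list(machine_id = machine_id, tpr2010 = as.numeric(tpr2010),
         entrance = entrance, exit = exit),
    class = "bcf_table"
  )
}

#' Beam dataset
#'
#' Everything needed to reconstruct a central-axis dose with full backscatter:
#' per-field-size PDD curves, the output factor table, scan profiles, and the
#' reference calibration dose at dmax (cGy per MU for the 10 x 10 field).
#'
#' @param machine_id Machine label.
#' @param pdd Named list of [pdd_curve()] objects (names are field sizes).
#' @param of An [of_table()].
#' @param profiles List of [scan_profile()] objects (may be empty).
#' @param d_dmax Dose at dmax for the reference 10 x 10 field, cGy per MU
#'   (1 for a machine calibrated to 1 cGy/MU).
#' @param ssd Nominal source-to-surface distance (cm).
#' @return An object of class `beam_dataset`.
#' @export
beam_dataset <- function(machine_id, pdd, of, profiles = list(),
                         d_dmax = 1, ssd = 100) {
  stopifnot(inherits(of, "of_table"), is.list(pdd), length(pdd) >= 1)
  ok <- vapply(pdd, inherits, logical(1), what = "pdd_curve")
  if (!all(ok)) stop("pdd must be a list of pdd_curve objects")
  fs <- vapply(pdd, function(p) p$field_size, numeric(1))
  pdd <- pdd[order(fs)]
  names(pdd) <- format(sort(fs))
  if (!any(sort(fs) == 10))
    stop("reference field size missing (no 10 cm PDD curve)")
  if (d_dmax <= 0) stop("d_dmax must be positive")
  if (length(profiles)) {
    # canonical order so datasets compare equal regardless of input order
    key <- vapply(profiles, function(p)
      sprintf("%s_%07.2f_%07.2f", p$axis, p$field_size, p$depth), "")
    profiles <- profiles[order(key)]
  }
  structure(
    list(machine_id = machine_id, pdd = pdd, of = of, profiles = profiles,
         d_dmax = as.numeric(d_dmax), ssd = as.numeric(ssd)),
    class = "beam_dataset"
  )
}

#' @export
print.pdd_curve <- function(x, ...) {
  cat(sprintf("<pdd_curve> fs %g cm, %d depths [%g, %g] cm, dmax %g cm\n",
              x$field_size, length(x$depths), min(x$depths), max(x$depths),
              x$dmax))
  invisible(x)
}

#' @export
print.bcf_table <- function(x, ...) {
  cat(sprintf("<bcf_table> %s (TPR20,10 = %.3f)\n", x$machine_id, x$tpr2010))
  cat("entrance (depth 1.5 cm):\n"); print(x$entrance)
  cat("exit (backscatter 1.5 cm):\n"); print(x$exit)
  invisible(x)
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf(
    "<dose_plane> fs %g cm, depth %g cm, %d x %d grid, spacing %.3g cm, CAX %.3g cGy\n",
    x$field_size, x$depth, nrow(x$dose), ncol(x$dose),
    x$x_coords[2] - x$x_coords[1], plane_cax_dose(x)))
  invisible(x)
}

#' @export
print.beam_dataset <- function(x, ...) {
  cat(sprintf(
    "<beam_dataset> %s: %d PDD curves (fs %s cm), %d output factors, %d profiles, d_dmax %g cGy/MU\n",
    x$machine_id, length(x$pdd),
    paste(vapply(x$pdd, function(p) format(p$field_size), ""), collapse = "/"),
    length(x$of$field_sizes), length(x$profiles), x$d_dmax))
  invisible(x)
}
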