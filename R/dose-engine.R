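#' Charge-to-dose calibration factor
#'
#' Relative dosimetry scheme: an ionization-chamber reading is first taken in
#' charge mode at the machine's calibration condition (output 1 cGy/MU at
#' dmax, 10 x 10 field), which fixes the chamber-specific charge-to-dose
#' conversion factor; all subsequent charge readings are converted with it.
#' This also corrects for daily output variation.
#'
#' @param machine_id Machine label.
#' @param charge_reading Charge reading (detector units) at calibration.
#' @param dose_delivered Dose delivered at calibration (cGy), e.g. 100 for
#'   100 MU on a machine calibrated to 1 cGy/MU.
#' @return An object of class `calibration_factor` with field `factor`
#'   (cGy per detector unit).
#' @export
calibration_factor <- function(machine_id, charge_reading, dose_delivered) {
  if (charge_reading <= 0 || dose_delivered <= 0)
    stop("calibration charge and dose must be positive")
  structure(list(machine_id = machine_id,
                 factor = dose_delivered / charge_reading),
            class = "calibration_factor")
}

#' Convert a charge reading to dose
#'
#' @param charge Charge reading (detector units), positive.
#' @param calib A [calibration_factor()].
#' @return Dose in cGy, `charge * factor`.
#' @export
charge_to_dose <- function(charge, calib) {
  stopifnot(inherits(calib, "calibration_factor"))
  if (any(charge <= 0)) stop("charge reading must be positive")
  charge * calib$factor
}

#' Central-axis dose with full backscatter
#'
#' The reference ("full backscatter") central-axis dose at field size `fs`
#' and depth `d` for `mu` monitor units:
#'
#' \deqn{D_{fs,d} = D_{dmax} \cdot MU \cdot \frac{PDD_{fs,d}}{100} \cdot OF_{fs}}
#'
#' where \eqn{D_{dmax}} is the beam's calibration dose at the depth of maximum
#' for the 10 x 10 reference field (cGy/MU), \eqn{PDD_{fs,d}} the percentage
#' depth dose, and \eqn{OF_{fs}} the field-size output factor. PDD is
#' interpolated linearly in depth within each tabulated curve and then
#' linearly across field size; OF linearly in field size.
#'
#' @param beam A [beam_dataset()].
#' @param fs Field size (cm, at 100 cm from source).
#' @param d Depth (cm).
#' @param mu Monitor units (default 100).
#' @return Dose in cGy.
#' @export
dose_full_backscatter <- function(beam, fs, d, mu = 100) {
  stopifnot(inherits(beam, "beam_dataset"))
  n <- max(length(fs), length(d))
  fs <- rep_len(fs, n); d <- rep_len(d, n)
  fs_grid <- vapply(beam$pdd, function(p) p$field_size, numeric(1))
  if (any(fs < min(fs_grid) - 1e-12 | fs > max(fs_grid) + 1e-12))
    stop("field size outside tabulated PDD range [", min(fs_grid), ", ",
         max(fs_grid), "]")
  # PDD(fs, d): depth interpolation per curve, then linear across field size
  per_curve <- vapply(beam$pdd, function(p) interpolate(p, d), numeric(n))
  per_curve <- matrix(per_curve, nrow = n)
  pdd <- vapply(seq_len(n), function(i) {
    .lin1(fs_grid, per_curve[i, ], fs[i], "field size")
  }, numeric(1))
  of <- interpolate(beam$of, fs)
  beam$d_dmax * mu * pdd / 100 * of
}

#' Expected entrance or exit dose with backscatter correction
#'
#' Predicts the dose an in-vivo detector should read at the entrance point
#' (depth 1.5 cm, variable backscatter thickness) or exit point (backscatter
#' thickness 1.5 cm, variable depth) of a phantom or patient: the
#' full-backscatter dose from [dose_full_backscatter()] multiplied by the
#' backscatter correction factor for that geometry,
#' \eqn{D_{expected} = D_{fs,d} \cdot BCF}.
#'
#' The entrance/exit geometry is enforced: an entrance request at a depth
#' other than 1.5 cm, or an exit request at a backscatter thickness other
#' than 1.5 cm, is an error rather than a guess. BCF tables are derived at
#' SSD 100 cm but are SSD-independent to within measurement uncertainty, so
#' isocentric (variable-SSD) queries reuse the same table unless
#' `allow_variable_ssd = FALSE`.
#'
#' @param beam A [beam_dataset()].
#' @param bcf A [bcf_table()] for the same beam.
#' @param kind `"entrance"` or `"exit"`.
#' @param fs Field size (cm).
#' @param d Depth (cm); must equal `entrance_depth` for entrance queries.
#' @param backscatter Backscatter thickness (cm); must equal `entrance_depth`
#'   for exit queries.
#' @param mu Monitor units.
#' @param ssd Source-to-surface distance of the query geometry (cm).
#' @param allow_variable_ssd If `FALSE`, any `ssd != 100` errors instead of
#'   reusing the fixed-SSD BCF table.
#' @param entrance_depth The entrance/exit reference depth (cm); 1.5 cm gives
#'   electronic equilibrium for a 6 MV beam.
#' @return An object of class `expected_dose`: a list with
#'   `dose_full_backscatter` (cGy), `bcf_applied`, `dose_expected` (cGy) and
#'   the query context.
#' @export
expected_dose <- function(beam, bcf, kind = c("entrance", "exit"), fs, d,
                          backscatter, mu = 100, ssd = 100,
                          allow_variable_ssd = TRUE, entrance_depth = 1.5) {
  kind <- match.arg(kind)
  stopifnot(inherits(bcf, "bcf_table"))
  if (!allow_variable_ssd && abs(ssd - 100) > 1e-9)
    stop("variable-SSD query refused (allow_variable_ssd = FALSE)")
  if (kind == "entrance" && abs(d - entrance_depth) > 1e-9)
    stop("entrance dose is defined at depth ", entrance_depth,
         " cm; got d = ", d)
  if (kind == "exit" && abs(backscatter - entrance_depth) > 1e-9)
    stop("exit dose is defined at backscatter thickness ", entrance_depth,
         " cm; got backscatter = ", backscatter)
  full <- dose_full_backscatter(beam, fs, d, mu)
  key <- if (kind == "entrance") backscatter else d
  factor <- interpolate(bcf, block = kind, field_size = fs, key = key)
  structure(
    list(dose_full_backscatter = full,
         bcf_applied = factor,
         dose_expected = full * factor,
         context = list(kind = kind, field_size = fs, depth = d,
                        backscatter_thickness = backscatter, mu = mu,
                        ssd = ssd, machine_id = bcf$machine_id)),
    class = "expected_dose"
  )
}

#' @export
print.expected_dose <- function(x, ...) {
  ctx <- x$context
  cat(sprintf(
    "<expected_dose> %s, fs %g cm, depth %g cm, backscatter %g cm (%g MU)\n",
    ctx$kind, ctx$field_size, ctx$depth, ctx$backscatter_thickness, ctx$mu))
  cat(sprintf("  full backscatter: %.3f cGy\n  BCF applied:      %.4f\n  expected:         %.3f cGy\n",
              x$dose_full_backscatter, x$bcf_applied, x$dose_expected))
  invisible(x)
}
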