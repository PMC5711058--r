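#' Backscatter correction factor from a dose pair
#'
#' BCF is the ratio of the dose measured without (or with partial)
#' backscatter to the dose with full backscatter. Physically BCF <= 1; noise
#' can push a measured ratio marginally above unity, which is tolerated up to
#' 1.01 with a warning. Ratios outside (0.9, 1.01] are implausible for
#' megavoltage entrance/exit geometries and raise an error.
#'
#' @param dose_without Dose without full backscatter (cGy), positive.
#' @param dose_full Dose with full backscatter (cGy), positive.
#' @return The BCF ratio(s), numeric.
#' @export
compute_bcf <- function(dose_without, dose_full) {
  if (any(dose_without <= 0) || any(dose_full <= 0))
    stop("doses must be positive")
  ratio <- dose_without / dose_full
  .check_bcf_values(ratio, "computed")
  ratio
}

# completeness check for one measurement block on a full (fs x key) grid
.block_from_measurements <- function(df, beam, key_col, block_name) {
  fs_grid <- sort(unique(df$field_size_cm))
  key_grid <- sort(unique(df[[key_col]]))
  want <- expand.grid(fs = fs_grid, key = key_grid)
  have <- paste(df$field_size_cm, df[[key_col]])
  missing <- want[!paste(want$fs, want$key) %in% have, , drop = FALSE]
  if (nrow(missing))
    stop("incomplete ", block_name, " measurement grid; missing cells: ",
         paste(sprintf("(%gx%g, %g cm)", missing$fs, missing$fs, missing$key),
               collapse = ", "))
  m <- matrix(NA_real_, length(fs_grid), length(key_grid),
              dimnames = list(format(fs_grid), format(key_grid)))
  full <- dose_full_backscatter(beam, df$field_size_cm, df$depth_cm, df$mu)
  bcf <- df$dose_cgy / full
  m[cbind(match(df$field_size_cm, fs_grid), match(df[[key_col]], key_grid))] <- bcf
  m
}

#' Derive a BCF table from central-axis measurements
#'
#' Splits a measurement set into the entrance block (fixed depth 1.5 cm,
#' variable backscatter thickness) and the exit block (fixed backscatter
#' thickness 1.5 cm, variable depth above 1.5 cm), computes the
#' full-backscatter denominator of every cell with
#' [dose_full_backscatter()], and returns the ratio table. Each block must
#' cover a complete field-size-by-thickness (or depth) grid; missing cells
#' are reported by name.
#'
#' @param measurements A [dose_measurements()] data frame.
#' @param beam The [beam_dataset()] providing PDD/OF denominators.
#' @param entrance_depth Entrance/exit reference depth (cm, default 1.5).
#' @param tpr2010 Beam-quality index recorded in the output table; default
#'   computed from the beam with [tpr20_10()].
#' @param max_bcf Upper plausibility bound for the derived cells. The default
#'   1.02 admits 3-sigma noise excursions of a 0.5%-reproducibility session
#'   above a near-unity factor; cells above 1 still warn.
#' @return A [bcf_table()].
#' @export
build_bcf_table <- function(measurements, beam, entrance_depth = 1.5,
                            tpr2010 = tpr20_10(beam), max_bcf = 1.02) {
  stopifnot(inherits(measurements, "data.frame"),
            inherits(beam, "beam_dataset"))
  df <- as.data.frame(measurements)
  is_ent <- abs(df$depth_cm - entrance_depth) < 1e-9
  is_exit <- abs(df$backscatter_cm - entrance_depth) < 1e-9 &
    df$depth_cm > entrance_depth + 1e-9
  if (!any(is_ent)) stop("no entrance measurements (depth ", entrance_depth,
                         " cm) in the set")
  if (!any(is_exit)) stop("no exit measurements (backscatter ", entrance_depth,
                          " cm, depth > ", entrance_depth, " cm) in the set")
  ent <- .block_from_measurements(df[is_ent, ], beam, "backscatter_cm",
                                  "entrance")
  ext <- .block_from_measurements(df[is_exit, ], beam, "depth_cm", "exit")
  bcf_table(df$machine_id[1], tpr2010, ent, ext, max_bcf = max_bcf)
}

#' Beam-quality index TPR20,10 of a beam dataset
#'
#' Computed from the 10 x 10 PDD curve as the ratio of depth-dose at 20 cm to
#' 10 cm. The package's depth-dose tables carry no inverse-square divergence
#' term (phantom-ratio convention), so this ratio is the tissue-phantom ratio
#' directly.
#'
#' @param beam A [beam_dataset()].
#' @return TPR20,10, dimensionless.
#' @export
tpr20_10 <- function(beam) {
  fs_grid <- vapply(beam$pdd, function(p) p$field_size, numeric(1))
  p10 <- beam$pdd[[which.min(abs(fs_grid - 10))]]
  interpolate(p10, 20) / interpolate(p10, 10)
}

.argcell <- function(m, idx) {
  list(value = m[idx],
       field_size = as.numeric(rownames(m))[row(m)[idx]],
       key = as.numeric(colnames(m))[col(m)[idx]])
}

#' Summary statistics of a BCF table
#'
#' Reports the extrema of each block with the cell they occur at, and the
#' maximum entrance dose reduction `(1 - BCF) * 100` over entrance cells at
#' or above a backscatter-thickness cut (the "negligible beyond this
#' thickness" check). The entrance block is a partial-backscatter ratio
#' rather than a strict no-backscatter BCF, and is labelled as such.
#'
#' @param table A [bcf_table()].
#' @param reduction_threshold_cm Backscatter-thickness cut (cm) for the dose
#'   reduction check; default 11.5.
#' @return An object of class `bcf_summary`: a list with `min_entrance`,
#'   `max_entrance`, `min_exit`, `max_exit` (each `value`/`field_size`/`key`),
#'   `reduction_threshold_cm` and `max_reduction_pct`.
#' @export
summarize_bcf <- function(table, reduction_threshold_cm = 11.5) {
  stopifnot(inherits(table, "bcf_table"))
  ent <- table$entrance; ext <- table$exit
  thick <- as.numeric(colnames(ent))
  sel <- ent[, thick >= reduction_threshold_cm - 1e-9, drop = FALSE]
  if (!ncol(sel)) stop("no entrance columns at or above the threshold")
  structure(
    list(machine_id = table$machine_id,
         entrance_is_partial_backscatter_ratio = TRUE,
         min_entrance = .argcell(ent, which.min(ent)),
         max_entrance = .argcell(ent, which.max(ent)),
         min_exit = .argcell(ext, which.min(ext)),
         max_exit = .argcell(ext, which.max(ext)),
         reduction_threshold_cm = reduction_threshold_cm,
         max_reduction_pct = max((1 - sel) * 100)),
    class = "bcf_summary"
  )
}

#' @export
print.bcf_summary <- function(x, ...) {
  f <- function(c, k) sprintf("%.3f at (%gx%g, %g cm %s)", c$value,
                              c$field_size, c$field_size, c$key, k)
  cat(sprintf("<bcf_summary> %s\n", x$machine_id))
  cat("  entrance (partial-backscatter ratio): min ",
      f(x$min_entrance, "backscatter"), "\n", sep = "")
  cat("  exit: min ", f(x$min_exit, "depth"),
      ", max ", f(x$max_exit, "depth"), "\n", sep = "")
  cat(sprintf("  max entrance dose reduction at backscatter >= %g cm: %.2f%%\n",
              x$reduction_threshold_cm, x$max_reduction_pct))
  invisible(x)
}

.check_same_grid <- function(a, b) {
  same <- function(x, y) length(x) == length(y) &&
    max(abs(as.numeric(x) - as.numeric(y))) < 1e-9
  if (!same(rownames(a$entrance), rownames(b$entrance)) ||
      !same(colnames(a$entrance), colnames(b$entrance)) ||
      !same(rownames(a$exit), rownames(b$exit)) ||
      !same(colnames(a$exit), colnames(b$exit)))
    stop("BCF tables are tabulated on different grids")
}

.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Cross-machine comparison of two BCF tables
#'
#' Mean and population standard deviation of the unsigned per-cell
#' differences, in percent, computed separately for the entrance and exit
#' blocks. Both tables must share the same (field size x thickness/depth)
#' grids.
#'
#' @param a,b [bcf_table()] objects on identical grids.
#' @return A list with elements `entrance` and `exit`, each a named numeric
#'   vector `c(mean_pct, sd_pct)`.
#' @export
compare_bcf_tables <- function(a, b) {
  stopifnot(inherits(a, "bcf_table"), inherits(b, "bcf_table"))
  .check_same_grid(a, b)
  stat <- function(x, y) {
    d <- abs(x - y) * 100
    c(mean_pct = mean(d), sd_pct = .sd_pop(d))
  }
  list(entrance = stat(a$entrance, b$entrance),
       exit = stat(a$exit, b$exit))
}

#' SSD invariance check between two BCF tables
#'
#' The fractional scatter contribution to depth dose is independent of beam
#' divergence, so a BCF table derived at fixed SSD 100 cm should agree with
#' one derived in isocentric (variable-SSD) geometry to within measurement
#' noise. Reports the maximum and population standard deviation of the
#' unsigned per-cell differences, in percent, pooled over both blocks.
#'
#' @param table_fixed_ssd,table_isocentric [bcf_table()] objects on
#'   identical grids.
#' @return Named numeric vector `c(max_diff_pct, sd_pct)`.
#' @export
ssd_invariance_check <- function(table_fixed_ssd, table_isocentric) {
  .check_same_grid(table_fixed_ssd, table_isocentric)
  d <- abs(c(table_fixed_ssd$entrance - table_isocentric$entrance,
             table_fixed_ssd$exit - table_isocentric$exit)) * 100
  c(max_diff_pct = max(d), sd_pct = .sd_pop(d))
}
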