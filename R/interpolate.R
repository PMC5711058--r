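#' Linear interpolation in beam-data tables
#'
#' Linear interpolation in each key dimension, exact at tabulated nodes.
#' Queries outside the tabulated hull raise an error: beam data are never
#' silently extrapolated.
#'
#' @param x A [pdd_curve()], [of_table()], [scan_profile()] or [bcf_table()].
#' @param ... Query keys, passed to the method.
#' @return Interpolated value(s), numeric.
#' @export
interpolate <- function(x, ...) UseMethod("interpolate")

# 1D linear interpolation with hull check; single-node grids only admit
# queries at the node itself
.lin1 <- function(grid, values, q, what) {
  if (any(q < min(grid) - 1e-12 | q > max(grid) + 1e-12))
    stop("query outside tabulated ", what, " range [", min(grid), ", ",
         max(grid), "]: ", paste(format(q[q < min(grid) | q > max(grid)]),
                                 collapse = ", "))
  if (length(grid) == 1L) return(rep_len(values, length(q)))
  q <- pmin(pmax(q, min(grid)), max(grid))
  stats::approx(grid, values, xout = q, method = "linear", ties = "ordered")$y
}

#' @param depth Depth(s) in cm (for `pdd_curve`).
#' @rdname interpolate
#' @export
interpolate.pdd_curve <- function(x, depth, ...) {
  .lin1(x$depths, x$values, depth, "depth")
}

#' @param field_size Field size(s) in cm (for `of_table` and `bcf_table`).
#' @rdname interpolate
#' @export
interpolate.of_table <- function(x, field_size, ...) {
  .lin1(x$field_sizes, x$factors, field_size, "field size")
}

#' @param position Off-axis position(s) in cm (for `scan_profile`).
#' @rdname interpolate
#' @export
interpolate.scan_profile <- function(x, position, ...) {
  .lin1(x$positions, x$values, position, "off-axis position")
}

# bilinear interpolation in a keyed matrix (rows = fs, cols = key)
.lin2 <- function(m, fs, key, what) {
  fs_grid <- as.numeric(rownames(m)); key_grid <- as.numeric(colnames(m))
  # interpolate along columns for each tabulated fs, then across fs
  col_interp <- vapply(seq_len(nrow(m)),
                       function(i) .lin1(key_grid, m[i, ], key, what),
                       numeric(length(key)))
  col_interp <- matrix(col_interp, nrow = length(key))
  vapply(seq_along(key),
         function(j) .lin1(fs_grid, col_interp[j, ], fs[j], "field size"),
         numeric(1))
}

#' @param block `"entrance"` or `"exit"` (for `bcf_table`).
#' @param key Backscatter thickness (entrance block) or depth (exit block),
#'   cm.
#' @details For the exit block, a query at depth 1.5 cm (or between 1.5 and
#'   6.5 cm) uses the entrance factor at backscatter thickness 1.5 cm as the
#'   1.5 cm exit column, since the two geometries coincide there.
#' @rdname interpolate
#' @export
interpolate.bcf_table <- function(x, block = c("entrance", "exit"),
                                  field_size, key, ...) {
  block <- match.arg(block)
  n <- max(length(field_size), length(key))
  field_size <- rep_len(field_size, n); key <- rep_len(key, n)
  m <- x[[block]]
  if (block == "exit" && min(key) < min(as.numeric(colnames(m)))) {
    # prepend the implicit 1.5 cm exit column (= entrance at backscatter 1.5)
    ent_t <- as.numeric(colnames(x$entrance))
    j <- which(abs(ent_t - 1.5) < 1e-9)
    i <- match(as.numeric(rownames(m)), as.numeric(rownames(x$entrance)))
    if (!length(j) || anyNA(i))
      stop("exit query below 6.5 cm needs the entrance block's 1.5 cm column ",
           "on the same field-size grid")
    m <- cbind(x$entrance[i, j[1]], m)
    colnames(m)[1] <- "1.5"
  }
  .lin2(m, field_size, key,
        if (block == "entrance") "backscatter thickness" else "depth")
}
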