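# Delimited-text I/O for beam data. Dialect: comma-separated, "." decimal,
# mandatory header row, UTF-8. File naming inside a beam directory:
#   pdd_<fs>.csv                    depth_cm, pdd_percent
#   of.csv                          field_size_cm, factor
#   profile_<axis>_<fs>_<depth>.csv position_cm, value
#   beam.csv                        machine_id, d_dmax_cgy_per_mu, ssd_cm
# BCF tables use a block format (see read_bcf_table). Measurement sets use
# measurements.csv with columns machine_id, field_size_cm, depth_cm,
# backscatter_cm, dose_cgy (+ optional mu, ssd_cm).

.read_csv <- function(path) {
  utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

.read_pdd_file <- function(path) {
  df <- .read_csv(path)
  if (!all(c("depth_cm", "pdd_percent") %in% names(df)))
    stop("PDD file ", basename(path), " must have columns depth_cm, pdd_percent")
  bad <- which(diff(df$depth_cm) <= 0)
  if (length(bad))
    stop("non-monotone depth grid in ", basename(path), " at row ", bad[1] + 1)
  fs <- as.numeric(sub("^pdd_([0-9.]+)\\.csv$", "\\1", basename(path)))
  if (is.na(fs)) stop("cannot parse field size from file name ", basename(path))
  pdd_curve(fs, df$depth_cm, df$pdd_percent)
}

.read_profile_file <- function(path) {
  df <- .read_csv(path)
  m <- regmatches(basename(path),
                  regexec("^profile_(crossline|inline|diagonal)_([0-9.]+)_([0-9.]+)\\.csv$",
                          basename(path)))[[1]]
  if (length(m) != 4)
    stop("cannot parse axis/field size/depth from file name ", basename(path))
  scan_profile(m[2], depth = as.numeric(m[4]), field_size = as.numeric(m[3]),
               positions = df$position_cm, values = df$value)
}

#' Read a beam dataset from a directory of delimited text files
#'
#' Expects `pdd_<fs>.csv` files (one per field size), `of.csv`, optional
#' `profile_<axis>_<fs>_<depth>.csv` files, and an optional `beam.csv` with
#' the machine id, reference dose at dmax (cGy/MU) and nominal SSD.
#'
#' @param path Directory containing the files.
#' @return A [beam_dataset()].
#' @seealso [write_beam_dataset()]
#' @export
read_beam_dataset <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  pdd_files <- list.files(path, "^pdd_.*\\.csv$", full.names = TRUE)
  if (!length(pdd_files)) stop("no pdd_<fs>.csv files in ", path)
  pdd <- lapply(pdd_files, .read_pdd_file)

  of_path <- file.path(path, "of.csv")
  if (!file.exists(of_path)) stop("of.csv missing in ", path)
  ofd <- .read_csv(of_path)
  if (!any(ofd$field_size_cm == 10))
    stop("reference field size missing from of.csv (no 10 cm row)")
  of <- of_table(ofd$field_size_cm, ofd$factor)

  prof_files <- list.files(path, "^profile_.*\\.csv$", full.names = TRUE)
  profiles <- lapply(prof_files, .read_profile_file)

  machine_id <- "beam"; d_dmax <- 1; ssd <- 100
  meta_path <- file.path(path, "beam.csv")
  if (file.exists(meta_path)) {
    meta <- .read_csv(meta_path)
    machine_id <- as.character(meta$machine_id[1])
    d_dmax <- as.numeric(meta$d_dmax_cgy_per_mu[1])
    ssd <- as.numeric(meta$ssd_cm[1])
  }
  beam_dataset(machine_id, pdd, of, profiles, d_dmax = d_dmax, ssd = ssd)
}

#' Write a beam dataset to a directory of delimited text files
#'
#' PDD values are serialised at 1 decimal (percent scale), output factors and
#' profile values at full precision.
#'
#' @param beam A [beam_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_beam_dataset <- function(beam, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (p in beam$pdd) {
    utils::write.csv(
      data.frame(depth_cm = p$depths, pdd_percent = round(p$values, 1)),
      file.path(path, sprintf("pdd_%g.csv", p$field_size)), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(field_size_cm = beam$of$field_sizes, factor = beam$of$factors),
    file.path(path, "of.csv"), row.names = FALSE)
  for (pr in beam$profiles) {
    utils::write.csv(
      data.frame(position_cm = pr$positions, value = pr$values),
      file.path(path, sprintf("profile_%s_%g_%g.csv",
                              pr$axis, pr$field_size, pr$depth)),
      row.names = FALSE)
  }
  utils::write.csv(
    data.frame(machine_id = beam$machine_id, d_dmax_cgy_per_mu = beam$d_dmax,
               ssd_cm = beam$ssd),
    file.path(path, "beam.csv"), row.names = FALSE)
  invisible(path)
}

.parse_bcf_block <- function(lines, what) {
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  key <- as.numeric(header[-1])
  rows <- do.call(rbind, lapply(cells[-1], function(x) as.numeric(x)))
  fs <- rows[, 1]
  m <- rows[, -1, drop = FALSE]
  if (anyDuplicated(fs) || anyDuplicated(key))
    stop("duplicate (field size, thickness/depth) key in ", what, " BCF block")
  o <- order(fs); ok <- order(key)
  m <- m[o, ok, drop = FALSE]
  dimnames(m) <- list(format(sort(fs)), format(sort(key)))
  m
}

#' Read / write a BCF table
#'
#' The file mirrors the two-block measurement layout: comment-style metadata
#' lines (`#machine_id,<id>` and `#tpr2010,<value>`), then an `#entrance`
#' block (rows = field sizes, columns = backscatter thicknesses at depth
#' 1.5 cm) and an `#exit` block (rows = field sizes, columns = depths at
#' backscatter 1.5 cm, starting at 6.5 cm — the 1.5 cm exit column is by
#' construction identical to the entrance 1.5 cm column and is not stored).
#' Factors are serialised at 3 decimals; write-then-read reproduces a valid
#' table exactly at that precision.
#'
#' @param path File path.
#' @return `read_bcf_table()` returns a [bcf_table()];
#'   `write_bcf_table()` returns `path` invisibly.
#' @export
read_bcf_table <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  machine_id <- "machine"; tpr <- NA_real_
  mline <- grep("^#machine_id,", lines, value = TRUE)
  if (length(mline)) machine_id <- sub("^#machine_id,", "", mline[1])
  tline <- grep("^#tpr2010,", lines, value = TRUE)
  if (length(tline)) tpr <- as.numeric(sub("^#tpr2010,", "", tline[1]))
  ient <- match("#entrance", lines); iext <- match("#exit", lines)
  if (is.na(ient) || is.na(iext) || iext <= ient)
    stop("BCF file must contain #entrance and #exit block markers in order")
  ent <- .parse_bcf_block(lines[(ient + 1):(iext - 1)], "entrance")
  ext <- .parse_bcf_block(lines[(iext + 1):length(lines)], "exit")
  bcf_table(machine_id, tpr, ent, ext)
}

#' @param table A [bcf_table()] (for `write_bcf_table`).
#' @rdname read_bcf_table
#' @export
write_bcf_table <- function(table, path) {
  stopifnot(inherits(table, "bcf_table"))
  fmt_block <- function(m) {
    c(paste(c("field_size_cm", colnames(m)), collapse = ","),
      vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], sprintf("%.3f", m[i, ])), collapse = ",")
      }, ""))
  }
  lines <- c(
    paste0("#machine_id,", table$machine_id),
    paste0("#tpr2010,", format(table$tpr2010)),
    "#entrance", fmt_block(table$entrance),
    "#exit", fmt_block(table$exit))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write central-axis dose measurement sets
#'
#' @param path CSV file with columns `machine_id`, `field_size_cm`,
#'   `depth_cm`, `backscatter_cm`, `dose_cgy` and optional `mu`, `ssd_cm`.
#' @return A [dose_measurements()] data frame.
#' @export
read_measurements <- function(path) {
  df <- .read_csv(path)
  need <- c("machine_id", "field_size_cm", "depth_cm", "backscatter_cm",
            "dose_cgy")
  if (!all(need %in% names(df)))
    stop("measurements file must have columns ", paste(need, collapse = ", "))
  dose_measurements(df$machine_id, df$field_size_cm, df$depth_cm,
                    df$backscatter_cm, df$dose_cgy,
                    mu = if ("mu" %in% names(df)) df$mu else 100,
                    ssd = if ("ssd_cm" %in% names(df)) df$ssd_cm else 100)
}

#' @param measurements A [dose_measurements()] data frame
#'   (for `write_measurements`).
#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(as.data.frame(measurements), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a 2D dose plane
#'
#' Plane CSV: two metadata lines (`#depth_cm,<d>` and `#field_size_cm,<fs>`),
#' then a dense grid with y coordinates as the header row and x coordinates
#' as the first column.
#'
#' @param path File path.
#' @return `read_dose_plane()` returns a [dose_plane()].
#' @export
read_dose_plane <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  depth <- as.numeric(sub("^#depth_cm,", "", grep("^#depth_cm,", lines, value = TRUE)[1]))
  fs <- as.numeric(sub("^#field_size_cm,", "", grep("^#field_size_cm,", lines, value = TRUE)[1]))
  body <- lines[!startsWith(lines, "#")]
  cells <- strsplit(body, ",", fixed = TRUE)
  y <- as.numeric(cells[[1]][-1])
  rows <- do.call(rbind, lapply(cells[-1], as.numeric))
  dose_plane(depth, fs, x_coords = rows[, 1], y_coords = y,
             dose = rows[, -1, drop = FALSE])
}

#' @param plane A [dose_plane()] (for `write_dose_plane`).
#' @rdname read_dose_plane
#' @export
write_dose_plane <- function(plane, path) {
  lines <- c(
    sprintf("#depth_cm,%g", plane$depth),
    sprintf("#field_size_cm,%g", plane$field_size),
    paste(c("x_cm", format(plane$y_coords)), collapse = ","),
    vapply(seq_along(plane$x_coords), function(i) {
      paste(c(format(plane$x_coords[i]),
              sprintf("%.6g", plane$dose[i, ])), collapse = ",")
    }, ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Bundled measured BCF tables
#'
#' Loads the measured backscatter-correction-factor table shipped with the
#' package for one of two clinical 6 MV beams: a Varian Clinac 21EX
#' (TPR20,10 = 0.669) or an Elekta Synergy (TPR20,10 = 0.687). Entrance
#' factors were measured at depth 1.5 cm for backscatter thicknesses
#' 1.5-31.5 cm; exit factors at backscatter 1.5 cm for depths 6.5-31.5 cm;
#' field sizes 5-20 cm.
#'
#' @param machine `"clinac21ex"` or `"synergy"`.
#' @return A [bcf_table()].
#' @examples
#' suppressWarnings(bcf_reference_table("clinac21ex"))$entrance["20", "1.5"]
#' @export
bcf_reference_table <- function(machine = c("clinac21ex", "synergy")) {
  machine <- match.arg(machine)
  path <- system.file("extdata", paste0("bcf_", machine, ".csv"),
                      package = "transitdose", mustWork = TRUE)
  read_bcf_table(path)
}
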