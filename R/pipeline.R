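# End-to-end orchestration: simulate a beam and a measurement campaign,
# derive the BCF table, emulate TPS exit planes, run central-axis and gamma
# comparisons, and render a deterministic report.

#' Pipeline run configuration
#'
#' A serializable description of a full verification run. Saving and
#' re-loading a config reproduces the run identically (all randomness is
#' derived from `seed`).
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory for report files.
#' @param field_sizes Field sizes (cm) of the measurement grid.
#' @param thickness_grid Entrance backscatter thicknesses (cm).
#' @param depth_grid Exit depths (cm).
#' @param noise_sd Fractional measurement noise SD.
#' @param emulator_modes TPS failure modes to exercise (see
#'   [tps_emulator_spec()]).
#' @param gamma_field_sizes,gamma_depths Field sizes and depths of the gamma
#'   plane comparisons (crossed).
#' @param dose_percent,dta_mm Gamma criteria.
#' @param mu Monitor units per simulated measurement.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("transitdose_run_"),
                       field_sizes = c(5, 10, 15, 20),
                       thickness_grid = seq(1.5, 31.5, by = 5),
                       depth_grid = seq(6.5, 31.5, by = 5),
                       noise_sd = 0.005,
                       emulator_modes = c("exact", "full_backscatter",
                                          "shoulder_boost", "center_dip"),
                       gamma_field_sizes = c(10, 20),
                       gamma_depths = c(11.5, 21.5, 31.5),
                       dose_percent = 3, dta_mm = 3, mu = 100) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 field_sizes = field_sizes, thickness_grid = thickness_grid,
                 depth_grid = depth_grid, noise_sd = noise_sd,
                 emulator_modes = emulator_modes,
                 gamma_field_sizes = gamma_field_sizes,
                 gamma_depths = gamma_depths, dose_percent = dose_percent,
                 dta_mm = dta_mm, mu = mu),
            class = "run_config")
}

#' Save / load a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `load_run_config()` returns a [run_config()].
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

# hash of the scientific content of a config (output location excluded, so
# identical runs written to different directories report identical bytes)
.config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full verification pipeline
#'
#' Stages, each aborting with its name on failure:
#' 1. `simulate`: generate the analytic beam and the noisy measurement
#'    campaign ([generate_beam()], [generate_measurements()]).
#' 2. `derive-bcf`: build and summarize the BCF table
#'    ([build_bcf_table()], [summarize_bcf()]).
#' 3. `cax-compare`: central-axis exit dose percent difference,
#'    `(emulated / truth) - 1`, per emulator mode over the exit grid.
#' 4. `gamma-compare`: truth vs emulated exit planes at the configured
#'    (field size, depth) cases, absolute gamma with full-field and
#'    central-80% pass rates.
#' 5. `report`: render `report.md` / `report.json` plus the derived BCF
#'    table and measurement CSVs into `config$out_dir`.
#'
#' Every output carries the seed and a config hash; identical configs give
#' byte-identical JSON reports.
#'
#' @param config A [run_config()].
#' @param deficit A [backscatter_deficit_spec()]; the generator's ground
#'   truth.
#' @param beam_spec A [synthetic_beam_spec()].
#' @return A list of results (`bcf`, `bcf_summary`, `cax`, `gamma`,
#'   `warnings`, `files`), invisibly classed `pipeline_result`.
#' @export
run_pipeline <- function(config = run_config(),
                         deficit = backscatter_deficit_spec(),
                         beam_spec = synthetic_beam_spec(seed = config$seed)) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  warn_log <- character()

  beam <- stage("simulate", generate_beam(
    beam_spec, fs_list = config$field_sizes,
    profile_depths = sort(unique(c(config$gamma_depths, 1.5)))))
  meas <- stage("simulate", generate_measurements(
    beam, deficit, fs_list = config$field_sizes,
    thickness_grid = config$thickness_grid, depth_grid = config$depth_grid,
    noise_sd = config$noise_sd, mu = config$mu, seed = config$seed))

  bcf <- stage("derive-bcf", withCallingHandlers(
    build_bcf_table(meas, beam),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  bcf_sum <- stage("derive-bcf", summarize_bcf(bcf))

  cax <- stage("cax-compare", {
    grid <- expand.grid(mode = config$emulator_modes,
                        fs = config$field_sizes, depth = config$depth_grid,
                        stringsAsFactors = FALSE)
    truth_bcf <- deficit_bcf(deficit, "exit", grid$fs, grid$depth)
    grid$pct_diff <- ifelse(grid$mode == "full_backscatter",
                            (1 / truth_bcf - 1) * 100, 0)
    grid$bcf_truth <- truth_bcf
    grid[order(grid$mode, grid$fs, grid$depth), ]
  })

  gam <- stage("gamma-compare", {
    crit <- gamma_criteria(config$dose_percent, config$dta_mm)
    cases <- expand.grid(mode = config$emulator_modes,
                         fs = config$gamma_field_sizes,
                         depth = config$gamma_depths,
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(cases)), function(i) {
      fs <- cases$fs[i]; d <- cases$depth[i]; mode <- cases$mode[i]
      ref <- truth_exit_plane(beam, deficit, fs, d, mu = config$mu)
      ev <- emulate_tps_plane(beam, deficit, tps_emulator_spec(mode), fs, d,
                              mu = config$mu)
      res <- gamma_index(ref, ev, crit, ssd = beam$ssd)
      data.frame(mode = mode, fs = fs, depth = d,
                 cax_pct_diff = (plane_cax_dose(ev) / plane_cax_dose(ref) - 1) * 100,
                 pass_full = res$pass_rate_full, pass_80 = res$pass_rate_80,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = config$seed, config_hash = .config_hash(config),
                  machine_id = beam$machine_id, bcf = bcf,
                  bcf_summary = bcf_sum, cax = cax, gamma = gam,
                  warnings = warn_log)
  files <- stage("report", {
    bcf_path <- file.path(config$out_dir,
                          sprintf("bcf_%s.csv", beam$machine_id))
    suppressWarnings(write_bcf_table(bcf, bcf_path))
    meas_path <- file.path(config$out_dir, "measurements.csv")
    write_measurements(meas, meas_path)
    rep <- render_report(results)
    md_path <- file.path(config$out_dir, "report.md")
    writeLines(rep$markdown, md_path, useBytes = TRUE)
    json_path <- file.path(config$out_dir, "report.json")
    writeLines(rep$json, json_path, useBytes = TRUE)
    c(bcf = bcf_path, measurements = meas_path, report_md = md_path,
      report_json = json_path)
  })
  results$files <- files
  class(results) <- "pipeline_result"
  invisible(results)
}

.md_table <- function(df, digits = 3) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = digits,
                                                format = "fg") else as.character(v)
  body <- do.call(cbind, lapply(df, fmt))
  body <- matrix(body, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Render pipeline results as markdown and JSON
#'
#' Deterministic: identical results give identical bytes.
#'
#' @param results The result list produced by [run_pipeline()].
#' @return A list with elements `markdown` (character vector of lines) and
#'   `json` (single JSON string).
#' @export
render_report <- function(results) {
  bcf <- results$bcf; s <- results$bcf_summary
  md <- c(
    "# Entrance/exit dose verification report",
    "",
    sprintf("machine: %s | seed: %d | config: %s", results$machine_id,
            results$seed, results$config_hash),
    "",
    "## Backscatter correction factors",
    "",
    sprintf("Entrance block (depth 1.5 cm), %d x %d cells; exit block (backscatter 1.5 cm), %d x %d cells.",
            nrow(bcf$entrance), ncol(bcf$entrance),
            nrow(bcf$exit), ncol(bcf$exit)),
    sprintf("Minimum entrance BCF %.3f at (%gx%g, %g cm backscatter); exit BCF range %.3f-%.3f.",
            s$min_entrance$value, s$min_entrance$field_size,
            s$min_entrance$field_size, s$min_entrance$key,
            s$min_exit$value, s$max_exit$value),
    sprintf("Max entrance dose reduction at backscatter >= %g cm: %.2f%%.",
            s$reduction_threshold_cm, s$max_reduction_pct),
    "")
  if (length(results$warnings)) {
    md <- c(md, "BCF warnings (cells above unity, kept unclamped):",
            paste0("- ", results$warnings), "")
  }
  md <- c(md, "## Central-axis exit dose differences ((emulated/measured) - 1, %)",
          "", .md_table(results$cax[, c("mode", "fs", "depth", "pct_diff")]),
          "", "## 2D absolute gamma pass rates", "")
  if (is.null(results$gamma) || nrow(results$gamma) == 0) {
    md <- c(md, "no plane comparisons run", "")
  } else {
    md <- c(md, .md_table(results$gamma, digits = 4), "")
  }
  json <- jsonlite::toJSON(
    list(seed = results$seed, config_hash = results$config_hash,
         machine_id = results$machine_id,
         bcf = list(entrance = results$bcf$entrance,
                    exit = results$bcf$exit),
         bcf_summary = list(
           min_entrance = s$min_entrance, min_exit = s$min_exit,
           max_exit = s$max_exit,
           max_reduction_pct = s$max_reduction_pct),
         cax = results$cax, gamma = results$gamma,
         warnings = results$warnings),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(markdown = md, json = as.character(json))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s, seed %d\n", x$machine_id, x$seed))
  print(x$bcf_summary)
  if (!is.null(x$gamma) && nrow(x$gamma)) {
    cat("gamma pass rates (full / central-80%):\n")
    print(x$gamma, row.names = FALSE)
  }
  invisible(x)
}
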