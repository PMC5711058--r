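# Analytic 6 MV beam emulation: depth dose with buildup and exponential
# attenuation, error-function penumbra profiles with divergence-scaled field
# edges, a smooth output-factor model, a parametric backscatter-deficit model
# in the measured tables' range, and TPS failure-mode emulators.

#' Synthetic 6 MV beam specification
#'
#' Parameters of the analytic beam model. The depth dose is
#' `PDD(d) ~ (1 - exp(-buildup_rate * (d + shift))) * exp(-mu_eff * d)`, with
#' `shift` chosen in closed form so the maximum falls at `dmax`; there is no
#' inverse-square term (phantom-ratio convention), so the attenuation
#' coefficient maps directly onto the beam-quality index:
#' TPR20,10 ~ exp(-10 * mu_eff). The default `mu_eff = 0.0402` /cm gives
#' TPR20,10 = 0.669 (a Clinac-21EX-like 6 MV beam; use 0.0376 for a
#' Synergy-like 0.687). Attenuation softens slightly with field size
#' (`fs_atten_slope`) so PDD rises with field size, as measured.
#'
#' @param machine_id Machine label.
#' @param mu_eff Effective attenuation coefficient (1/cm) at the 10 x 10
#'   field.
#' @param buildup_rate Buildup rate (1/cm); must leave the dose maximum in
#'   the interior of the depth grid.
#' @param dmax Depth of maximum dose (cm, default 1.5).
#' @param fs_atten_slope Fractional decrease of `mu_eff` per cm of field size
#'   above 10 cm.
#' @param of_params Named vector `c(linear, quad)` of the output-factor model
#'   `OF(fs) = 1 + linear*(fs-10) + quad*(fs-10)^2`.
#' @param penumbra_sigma Penumbra width (cm) of the error-function edge.
#' @param horn_amplitude Relative off-axis horn amplitude at dmax (fades
#'   linearly with depth).
#' @param ssd Source-to-surface distance (cm).
#' @param seed Integer seed for any stochastic use of the spec.
#' @return An object of class `synthetic_beam_spec`.
#' @export
synthetic_beam_spec <- function(machine_id = "synthetic6mv",
                                mu_eff = 0.0402, buildup_rate = 2.8,
                                dmax = 1.5, fs_atten_slope = 0.003,
                                of_params = c(linear = 0.0065, quad = -8e-5),
                                penumbra_sigma = 0.35, horn_amplitude = 0.03,
                                ssd = 100, seed = 1L) {
  stopifnot(mu_eff > 0, buildup_rate > 0, dmax > 0, penumbra_sigma > 0)
  structure(list(machine_id = machine_id, mu_eff = mu_eff,
                 buildup_rate = buildup_rate, dmax = dmax,
                 fs_atten_slope = fs_atten_slope, of_params = of_params,
                 penumbra_sigma = penumbra_sigma,
                 horn_amplitude = horn_amplitude, ssd = ssd,
                 seed = as.integer(seed)),
            class = "synthetic_beam_spec")
}

.depth_dose_raw <- function(spec, fs, d) {
  mu <- spec$mu_eff * (1 - spec$fs_atten_slope * (fs - 10))
  b <- spec$buildup_rate
  shift <- log((b + mu) / mu) / b - spec$dmax
  v <- (1 - exp(-b * (d + shift))) * exp(-mu * d)
  if (any(v <= 0))
    stop("depth-dose model has no interior maximum on this grid ",
         "(increase buildup_rate or the grid start)")
  v
}

.profile_values <- function(spec, fs, depth, positions) {
  w <- fs * (spec$ssd + depth) / (2 * spec$ssd)  # projected field half-width
  s2 <- spec$penumbra_sigma * sqrt(2)
  core <- 0.5 * (pracma::erf((w - positions) / s2) +
                 pracma::erf((w + positions) / s2))
  fade <- max(0, 1 - (depth - spec$dmax) / 30)
  horn <- 1 + spec$horn_amplitude * fade * pmin(abs(positions) / w, 1)^2
  pmax(core * horn, 1e-9)
}

#' Generate an analytic beam dataset
#'
#' Builds a complete [beam_dataset()] from a [synthetic_beam_spec()]: one PDD
#' curve per field size (normalized to 100 at `dmax`), the output-factor
#' table, and crossline/inline/diagonal profiles (flat core, error-function
#' penumbra with the field edge divergence-scaled to each depth, optional
#' off-axis horns) at 0.2 cm resolution.
#'
#' @param spec A [synthetic_beam_spec()].
#' @param fs_list Field sizes (cm, must include 10).
#' @param depth_grid Depth grid for the PDD curves (cm); must contain `dmax`
#'   and extend to at least 31.5 cm.
#' @param profile_depths Depths at which profiles are generated (cm).
#' @param profile_axes Profile axes to generate.
#' @param profile_spacing Profile sample spacing (cm, default 0.2).
#' @param d_dmax Reference dose at dmax, cGy/MU (default 1: a machine
#'   calibrated to 1 cGy/MU).
#' @return A [beam_dataset()].
#' @export
generate_beam <- function(spec = synthetic_beam_spec(),
                          fs_list = c(5, 10, 15, 20),
                          depth_grid = seq(0.25, 33, by = 0.25),
                          profile_depths = c(1.5, seq(6.5, 31.5, by = 5)),
                          profile_axes = c("crossline", "inline"),
                          profile_spacing = 0.2, d_dmax = 1) {
  stopifnot(inherits(spec, "synthetic_beam_spec"))
  if (!any(abs(depth_grid - spec$dmax) < 1e-9))
    depth_grid <- sort(c(depth_grid, spec$dmax))
  pdd <- lapply(fs_list, function(fs) {
    v <- .depth_dose_raw(spec, fs, depth_grid)
    pdd_curve(fs, depth_grid, 100 * v / max(v))
  })
  dfs <- fs_list - 10
  of <- of_table(fs_list,
                 1 + spec$of_params[["linear"]] * dfs +
                   spec$of_params[["quad"]] * dfs^2)
  profiles <- list()
  for (fs in fs_list) {
    for (d in profile_depths) {
      half <- fs * (spec$ssd + d) / (2 * spec$ssd)
      k <- ceiling(1.7 * half / profile_spacing)
      pos <- seq(-k, k) * profile_spacing
      vals <- .profile_values(spec, fs, d, pos)
      for (ax in profile_axes)
        profiles[[length(profiles) + 1L]] <- scan_profile(ax, d, fs, pos, vals)
    }
  }
  beam_dataset(spec$machine_id, pdd, of, profiles, d_dmax = d_dmax,
               ssd = spec$ssd)
}

#' Backscatter deficit model
#'
#' Parametric model of the backscatter dose deficit, the simplest functional
#' forms matching the measured behaviour: the entrance deficit decays
#' exponentially with backscatter thickness,
#' `1 - BCF_ent(fs, t) = (a0 + a1*fs) * exp(-decay * t)`, and the exit
#' deficit grows linearly with depth,
#' `1 - BCF_exit(fs, d) = b0 + b1*fs + slope*d`. Defaults place the implied
#' factors in the measured range 0.96-1.00 for field sizes 5-20 cm and
#' thicknesses/depths 1.5-31.5 cm, without fitting any particular machine.
#'
#' @param entrance_a0,entrance_a1 Entrance amplitude intercept and per-cm
#'   field-size slope.
#' @param entrance_decay Entrance decay rate with backscatter thickness
#'   (1/cm).
#' @param exit_b0,exit_b1 Exit deficit intercept and per-cm field-size slope.
#' @param exit_depth_slope Exit deficit growth per cm depth (1/cm).
#' @return An object of class `backscatter_deficit_spec`.
#' @export
backscatter_deficit_spec <- function(entrance_a0 = 0.0045,
                                     entrance_a1 = 0.00215,
                                     entrance_decay = 0.35,
                                     exit_b0 = -0.0045, exit_b1 = 0.00113,
                                     exit_depth_slope = 0.0006) {
  stopifnot(entrance_decay > 0)
  structure(list(entrance_a0 = entrance_a0, entrance_a1 = entrance_a1,
                 entrance_decay = entrance_decay, exit_b0 = exit_b0,
                 exit_b1 = exit_b1, exit_depth_slope = exit_depth_slope),
            class = "backscatter_deficit_spec")
}

#' Ground-truth BCF implied by a deficit model
#'
#' @param deficit A [backscatter_deficit_spec()].
#' @param kind `"entrance"` or `"exit"`.
#' @param fs Field size (cm).
#' @param key Backscatter thickness (entrance) or depth (exit), cm.
#' @return BCF value(s) in [0.95, 1].
#' @export
deficit_bcf <- function(deficit, kind = c("entrance", "exit"), fs, key) {
  kind <- match.arg(kind)
  def <- if (kind == "entrance") {
    (deficit$entrance_a0 + deficit$entrance_a1 * fs) *
      exp(-deficit$entrance_decay * key)
  } else {
    deficit$exit_b0 + deficit$exit_b1 * fs + deficit$exit_depth_slope * key
  }
  bcf <- 1 - def
  if (any(bcf < 0.95 - 1e-12) || any(bcf > 1 + 1e-12))
    stop("deficit model implies BCF outside [0.95, 1] at the queried cells")
  bcf
}

#' Ground-truth BCF table from a deficit model
#'
#' Tabulates [deficit_bcf()] on the standard measurement grid; the exact
#' table a noiseless measurement campaign would recover.
#'
#' @param deficit A [backscatter_deficit_spec()].
#' @param fs_list Field sizes (cm).
#' @param thickness_grid Entrance backscatter thicknesses (cm).
#' @param depth_grid Exit depths (cm).
#' @param machine_id,tpr2010 Metadata for the table.
#' @return A [bcf_table()].
#' @export
synthetic_bcf_table <- function(deficit, fs_list = c(5, 10, 15, 20),
                                thickness_grid = seq(1.5, 31.5, by = 5),
                                depth_grid = seq(6.5, 31.5, by = 5),
                                machine_id = "synthetic6mv", tpr2010 = 0.669) {
  ent <- outer(fs_list, thickness_grid,
               function(f, t) deficit_bcf(deficit, "entrance", f, t))
  ext <- outer(fs_list, depth_grid,
               function(f, d) deficit_bcf(deficit, "exit", f, d))
  dimnames(ent) <- list(format(fs_list), format(thickness_grid))
  dimnames(ext) <- list(format(fs_list), format(depth_grid))
  bcf_table(machine_id, tpr2010, ent, ext)
}

#' Simulate a central-axis measurement campaign
#'
#' Generates the entrance/exit measurement grid: entrance doses at depth
#' 1.5 cm with backscatter thickness over `thickness_grid`, exit doses at
#' backscatter 1.5 cm with depth over `depth_grid`, for each field size.
#' Every dose is the full-backscatter dose from the beam tables times the
#' deficit-implied BCF times multiplicative Gaussian noise
#' `(1 + e), e ~ N(0, noise_sd)` — `noise_sd = 0.005` reproduces the 0.5%
#' setup reproducibility of repeated solid-phantom measurements. A single
#' seeded random stream makes the set bit-reproducible.
#'
#' @param beam A [beam_dataset()].
#' @param deficit A [backscatter_deficit_spec()].
#' @param fs_list Field sizes (cm).
#' @param thickness_grid Entrance backscatter thicknesses (cm).
#' @param depth_grid Exit depths (cm).
#' @param noise_sd Fractional noise SD (>= 0).
#' @param mu Monitor units per measurement.
#' @param seed Integer seed.
#' @param geometry `"fixed_ssd"` (SSD 100) or `"isocentric"` (detector at
#'   100 cm from source, SSD = 100 - depth). The model's depth dose carries
#'   no divergence term, so the two geometries differ only in the recorded
#'   SSD and the noise draw.
#' @param entrance_depth Entrance/exit reference depth (cm).
#' @return A [dose_measurements()] data frame.
#' @export
generate_measurements <- function(beam, deficit,
                                  fs_list = c(5, 10, 15, 20),
                                  thickness_grid = seq(1.5, 31.5, by = 5),
                                  depth_grid = seq(6.5, 31.5, by = 5),
                                  noise_sd = 0.005, mu = 100, seed = 1L,
                                  geometry = c("fixed_ssd", "isocentric"),
                                  entrance_depth = 1.5) {
  geometry <- match.arg(geometry)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  ent <- expand.grid(fs = fs_list, key = thickness_grid)
  ext <- expand.grid(fs = fs_list, key = depth_grid)
  df <- data.frame(
    field_size = c(ent$fs, ext$fs),
    depth = c(rep(entrance_depth, nrow(ent)), ext$key),
    backscatter = c(ent$key, rep(entrance_depth, nrow(ext))),
    bcf = c(deficit_bcf(deficit, "entrance", ent$fs, ent$key),
            deficit_bcf(deficit, "exit", ext$fs, ext$key)))
  full <- dose_full_backscatter(beam, df$field_size, df$depth, mu)
  set.seed(seed)
  eps <- stats::rnorm(nrow(df), mean = 0, sd = noise_sd)
  ssd <- if (geometry == "isocentric") 100 - df$depth else 100
  dose_measurements(beam$machine_id, df$field_size, df$depth, df$backscatter,
                    dose = full * df$bcf * (1 + eps), mu = mu, ssd = ssd)
}

#' TPS emulator specification
#'
#' Dose-engine failure modes applied to the ground-truth exit plane:
#' * `"exact"` — reproduces the truth plane bit for bit;
#' * `"full_backscatter"` — ignores the missing backscatter at the exit
#'   level, overestimating the central-axis dose by exactly `1/BCF - 1`
#'   (the pencil-beam / AAA-style error);
#' * `"shoulder_boost"` — multiplies the profile shoulders (the in-field
#'   annulus between `annulus[1]` and `annulus[2]` of the projected field
#'   half-width, in the max-norm) by `1 + magnitude` at depths >=
#'   `onset_depth` (the AcurosXB-style shoulder overestimate);
#' * `"center_dip"` — multiplies the inner `center_fraction` of the field by
#'   `1 - magnitude` at depths >= `onset_depth` (the Monte-Carlo-style
#'   central underestimate).
#'
#' @param mode One of the four modes above.
#' @param magnitude Fractional perturbation (default 0.05).
#' @param onset_depth Depth (cm) at which the perturbation switches on.
#' @param annulus Shoulder band as fractions of the field half-width.
#' @param center_fraction Central region half-width fraction for
#'   `"center_dip"`.
#' @return An object of class `tps_emulator_spec`.
#' @export
tps_emulator_spec <- function(mode = c("exact", "full_backscatter",
                                       "shoulder_boost", "center_dip"),
                              magnitude = 0.05, onset_depth = 11.5,
                              annulus = c(0.8, 0.98), center_fraction = 0.4) {
  mode <- match.arg(mode)
  stopifnot(magnitude >= 0, length(annulus) == 2, annulus[1] < annulus[2])
  structure(list(mode = mode, magnitude = magnitude,
                 onset_depth = onset_depth, annulus = annulus,
                 center_fraction = center_fraction),
            class = "tps_emulator_spec")
}

.find_profile <- function(beam, axis, fs, depth) {
  for (p in beam$profiles)
    if (p$axis == axis && abs(p$field_size - fs) < 1e-9 &&
        abs(p$depth - depth) < 1e-9) return(p)
  stop("beam dataset has no ", axis, " profile at fs ", fs, " cm, depth ",
       depth, " cm")
}

#' Ground-truth measured exit dose plane
#'
#' The plane an ideal measurement campaign would reconstruct at the exit
#' level: the beam's crossline/inline profiles at (fs, depth)
#' cross-multiplied and anchored to the central-axis exit dose, i.e. the
#' full-backscatter dose times the deficit-implied exit BCF.
#'
#' @param beam A [beam_dataset()] with profiles at the requested geometry.
#' @param deficit A [backscatter_deficit_spec()].
#' @param fs Field size (cm).
#' @param depth Depth (cm).
#' @param mu Monitor units.
#' @param spacing Plane grid spacing (cm).
#' @return A [dose_plane()].
#' @export
truth_exit_plane <- function(beam, deficit, fs, depth, mu = 100,
                             spacing = 0.2) {
  px <- .find_profile(beam, "crossline", fs, depth)
  py <- .find_profile(beam, "inline", fs, depth)
  bcf <- deficit_bcf(deficit, "exit", fs, depth)
  d_cax <- dose_full_backscatter(beam, fs, depth, mu) * bcf
  synthesize_plane(px, py, d_cax, spacing = spacing, ssd = beam$ssd)
}

#' Emulate a TPS-computed exit dose plane
#'
#' Applies one of the [tps_emulator_spec()] failure modes to the ground-truth
#' exit plane of [truth_exit_plane()].
#'
#' @inheritParams truth_exit_plane
#' @param emu A [tps_emulator_spec()].
#' @return A [dose_plane()].
#' @export
emulate_tps_plane <- function(beam, deficit, emu, fs, depth, mu = 100,
                              spacing = 0.2) {
  stopifnot(inherits(emu, "tps_emulator_spec"))
  plane <- truth_exit_plane(beam, deficit, fs, depth, mu, spacing)
  if (emu$mode == "exact") return(plane)
  if (emu$mode == "full_backscatter") {
    bcf <- deficit_bcf(deficit, "exit", fs, depth)
    plane$dose <- plane$dose / bcf
    return(plane)
  }
  if (depth < emu$onset_depth - 1e-9) return(plane)
  half <- fs * (beam$ssd + depth) / (2 * beam$ssd)
  frac <- outer(abs(plane$x_coords), abs(plane$y_coords), pmax) / half
  if (emu$mode == "shoulder_boost") {
    sel <- frac >= emu$annulus[1] & frac <= emu$annulus[2]
    plane$dose[sel] <- plane$dose[sel] * (1 + emu$magnitude)
  } else {  # center_dip
    sel <- frac <= emu$center_fraction
    plane$dose[sel] <- plane$dose[sel] * (1 - emu$magnitude)
  }
  plane
}
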