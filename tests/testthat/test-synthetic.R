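test_that("the analytic beam reproduces 6 MV commissioning anchors", {
  beam <- test_beam()
  # PDD normalized to 100 exactly at dmax
  for (p in beam$pdd) {
    expect_equal(max(p$values), 100)
    expect_equal(p$dmax, 1.5)
    expect_equal(interpolate(p, 1.5), 100)
  }
  # beam quality in the 6 MV range
  tpr <- tpr20_10(beam)
  expect_gt(tpr, 0.65)
  expect_lt(tpr, 0.70)
  # output factors anchored at the reference field and strictly increasing
  expect_equal(interpolate(beam$of, 10), 1)
  expect_true(all(diff(beam$of$factors) > 0))
  # PDD at depth increases with field size (more phantom scatter)
  pdd20 <- vapply(beam$pdd, function(p) interpolate(p, 20), numeric(1))
  expect_true(all(diff(pdd20) > 0))
})

test_that("generated profiles put the 50% level at the diverged field edge", {
  beam <- test_beam()
  for (case in list(c(10, 11.5), c(20, 31.5), c(5, 1.5))) {
    fs <- case[1]; d <- case[2]
    p <- normalize_profile(transitdose:::.find_profile(beam, "crossline", fs, d))
    edge <- fs * (100 + d) / 200
    r <- uniroot(function(x) interpolate(p, x) - 0.5,
                 c(edge - 1, edge + 1))$root
    expect_lt(abs(r - edge), 0.05)
  }
})

test_that("a generated beam survives the CSV round trip with invariants intact", {
  beam <- test_beam()
  dir <- withr::local_tempdir()
  write_beam_dataset(beam, dir)
  back <- read_beam_dataset(dir)
  expect_s3_class(back, "beam_dataset")
  expect_equal(tpr20_10(back), tpr20_10(beam), tolerance = 1e-3)
})

test_that("measurement campaigns are reproducible and validated", {
  beam <- test_beam()
  def <- test_deficit()
  a <- generate_measurements(beam, def, noise_sd = 0.005, seed = 33)
  b <- generate_measurements(beam, def, noise_sd = 0.005, seed = 33)
  expect_identical(a, b)
  c2 <- generate_measurements(beam, def, noise_sd = 0.005, seed = 34)
  expect_false(identical(a$dose_cgy, c2$dose_cgy))
  expect_equal(nrow(a), 4 * 7 + 4 * 6)
  expect_error(generate_measurements(beam, def, noise_sd = -0.1),
               "non-negative")
})

test_that("the deficit model stays inside its declared BCF band", {
  def <- test_deficit()
  grid <- expand.grid(fs = seq(5, 20, by = 2.5), t = seq(1.5, 31.5, by = 2.5))
  ent <- deficit_bcf(def, "entrance", grid$fs, grid$t)
  expect_true(all(ent >= 0.95 & ent <= 1))
  gx <- expand.grid(fs = seq(5, 20, by = 2.5), d = seq(1.5, 31.5, by = 2.5))
  ext <- deficit_bcf(def, "exit", gx$fs, gx$d)
  expect_true(all(ext >= 0.95 & ext <= 1))
  # a deficit spec pushed outside the band is refused
  expect_error(deficit_bcf(backscatter_deficit_spec(exit_b1 = 0.003),
                           "exit", 20, 31.5), "outside")
})

test_that("TPS emulator modes implement their failure signatures", {
  beam <- test_beam()
  def <- test_deficit()
  fs <- 20; d <- 31.5
  truth <- truth_exit_plane(beam, def, fs, d)

  exact <- emulate_tps_plane(beam, def, tps_emulator_spec("exact"), fs, d)
  expect_identical(exact$dose, truth$dose)

  # full-backscatter overestimation identity: ratio is exactly 1/BCF
  fb <- emulate_tps_plane(beam, def, tps_emulator_spec("full_backscatter"),
                          fs, d)
  bcf <- deficit_bcf(def, "exit", fs, d)
  expect_equal(plane_cax_dose(fb) / plane_cax_dose(truth), 1 / bcf)
  expect_lt(max(abs(fb$dose - truth$dose / bcf)), 1e-12)

  # the identity holds across the whole exit grid
  for (fsi in c(5, 10, 15, 20)) for (di in c(6.5, 21.5, 31.5)) {
    t_i <- truth_exit_plane(beam, def, fsi, di)
    f_i <- emulate_tps_plane(beam, def, tps_emulator_spec("full_backscatter"),
                             fsi, di)
    expect_equal(plane_cax_dose(f_i) / plane_cax_dose(t_i),
                 1 / deficit_bcf(def, "exit", fsi, di))
  }

  # shoulder boost: untouched centre, boosted shoulder band, off below onset
  sb <- emulate_tps_plane(beam, def, tps_emulator_spec("shoulder_boost"),
                          fs, d)
  expect_equal(plane_cax_dose(sb), plane_cax_dose(truth))
  half <- fs * (100 + d) / 200
  i <- which.min(abs(sb$x_coords - 0.9 * half))
  j0 <- which(abs(sb$y_coords) < 1e-12)
  expect_equal(sb$dose[i, j0] / truth$dose[i, j0], 1.05)
  below <- emulate_tps_plane(beam, def,
                             tps_emulator_spec("shoulder_boost",
                                               onset_depth = 40), fs, d)
  expect_identical(below$dose, truth$dose)

  # centre dip: reduced centre, untouched shoulder
  cd <- emulate_tps_plane(beam, def, tps_emulator_spec("center_dip"), fs, d)
  expect_equal(plane_cax_dose(cd) / plane_cax_dose(truth), 0.95)
  expect_equal(cd$dose[i, j0], truth$dose[i, j0])

  expect_error(tps_emulator_spec("nonsense"), "arg")
})

test_that("exact-mode emulation passes gamma everywhere at any criteria", {
  beam <- test_beam()
  def <- test_deficit()
  truth <- truth_exit_plane(beam, def, 10, 21.5)
  exact <- emulate_tps_plane(beam, def, tps_emulator_spec("exact"), 10, 21.5)
  for (crit in list(gamma_criteria(1, 1, subsample_step_mm = 0.3),
                    gamma_criteria(3, 3))) {
    res <- gamma_index(truth, exact, crit)
    expect_equal(res$pass_rate_full, 100)
    expect_equal(res$pass_rate_80, 100)
  }
})
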